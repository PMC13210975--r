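# Readers/writers for the portable formats the toolkit exchanges:
# YOLO-normalized txt and COCO-style JSON annotations, trajectory CSV/JSON,
# JSON/YAML configs, and PNG images (via the optional 'png' package).

## ---- annotations ---------------------------------------------------------

#' Write YOLO-format annotations
#'
#' One line per box: `class_index cx cy w h`, all normalized to \[0, 1\]
#' from 0-based half-open pixel boxes.
#'
#' @param annotations data.frame with `x`, `y`, `w`, `h`, `class`.
#' @param path output txt path.
#' @param image_size `c(width, height)` in pixels.
#' @return The path, invisibly.
#' @export
write_yolo <- function(annotations, path, image_size) {
  cls <- health_classes()
  idx <- cls$index[match(annotations$class, cls$name)]
  if (anyNA(idx)) stop("unknown class in annotations")
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", idx,
                   (annotations$x + annotations$w / 2) / image_size[1],
                   (annotations$y + annotations$h / 2) / image_size[2],
                   annotations$w / image_size[1],
                   annotations$h / image_size[2])
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-format annotations
#'
#' @param path txt path from [write_yolo()].
#' @param image_size `c(width, height)` in pixels.
#' @return data.frame with pixel boxes `x`, `y`, `w`, `h` and `class`.
#' @export
read_yolo <- function(path, image_size) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  cls <- health_classes()
  w <- parts[, 4] * image_size[1]
  h <- parts[, 5] * image_size[2]
  data.frame(x = parts[, 2] * image_size[1] - w / 2,
             y = parts[, 3] * image_size[2] - h / 2,
             w = w, h = h,
             class = cls$name[parts[, 1] + 1L],
             stringsAsFactors = FALSE)
}

#' Write COCO-style JSON annotations
#'
#' Minimal COCO dialect: `images`, `categories` (the four health classes)
#' and `annotations` with `bbox = [x, y, w, h]` in pixels.
#'
#' @param annotations data.frame with `x`, `y`, `w`, `h`, `class`.
#' @param path output JSON path.
#' @param image_size `c(width, height)`.
#' @param image_id image identifier (default 1).
#' @return The path, invisibly.
#' @export
write_coco <- function(annotations, path, image_size, image_id = 1L) {
  cls <- health_classes()
  obj <- list(
    images = list(list(id = image_id, width = image_size[1],
                       height = image_size[2])),
    categories = lapply(seq_len(nrow(cls)), function(i)
      list(id = cls$index[i], name = cls$name[i])),
    annotations = lapply(seq_len(nrow(annotations)), function(i)
      list(id = i, image_id = image_id,
           category_id = cls$index[match(annotations$class[i], cls$name)],
           bbox = c(annotations$x[i], annotations$y[i],
                    annotations$w[i], annotations$h[i]),
           iscrowd = 0L))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-style JSON annotations
#'
#' @param path JSON path from [write_coco()].
#' @return data.frame with `x`, `y`, `w`, `h`, `class`, `image`.
#' @export
read_coco <- function(path) {
  obj <- jsonlite::read_json(path)
  cats <- vapply(obj$categories, function(c_) c_$name, "")
  names(cats) <- vapply(obj$categories, function(c_) as.character(c_$id), "")
  if (!length(obj$annotations))
    return(data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0), class = character(0),
                      image = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(obj$annotations, function(a)
    data.frame(x = a$bbox[[1]], y = a$bbox[[2]], w = a$bbox[[3]],
               h = a$bbox[[4]], class = unname(cats[as.character(a$category_id)]),
               image = a$image_id, stringsAsFactors = FALSE)))
}

## ---- trajectories --------------------------------------------------------

#' Write a health trajectory as CSV
#'
#' Scalar trajectories get columns `time_h`, `health` (plus covariates);
#' grid trajectories one `health_i_j` column per cell.
#'
#' @param traj a [health_trajectory()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (traj$grid) {
    d <- dim(traj$health)
    m <- matrix(traj$health, d[1], d[2] * d[3])
    colnames(m) <- as.vector(outer(seq_len(d[2]), seq_len(d[3]),
                                   function(i, j) sprintf("health_%d_%d", i, j)))
    df <- data.frame(time_h = traj$times, m, check.names = FALSE)
  } else {
    df <- data.frame(time_h = traj$times, health = traj$health)
  }
  if (!is.null(traj$covariates)) df <- cbind(df, traj$covariates)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a health trajectory from CSV
#'
#' @param path CSV path from [write_trajectory_csv()].
#' @return A [health_trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  gcols <- grep("^health_\\d+_\\d+$", names(df), value = TRUE)
  if (length(gcols)) {
    ij <- do.call(rbind, lapply(strsplit(sub("^health_", "", gcols), "_"),
                                as.integer))
    Hg <- max(ij[, 1]); Wg <- max(ij[, 2])
    arr <- array(0, c(nrow(df), Hg, Wg))
    for (k in seq_along(gcols)) arr[, ij[k, 1], ij[k, 2]] <- df[[gcols[k]]]
    health_trajectory(df$time_h, arr)
  } else {
    cov_cols <- setdiff(names(df), c("time_h", "health"))
    health_trajectory(df$time_h, df$health,
                      covariates = if (length(cov_cols)) df[cov_cols])
  }
}

## ---- config --------------------------------------------------------------

#' Read a JSON or YAML configuration file
#'
#' YAML requires the optional `yaml` package; JSON always works.
#'
#' @param path config file path (extension decides the parser).
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

## ---- images --------------------------------------------------------------

#' Read/write PNG images
#'
#' Thin wrappers over the optional `png` package, exchanging `[H, W, 3]`
#' arrays in \[0, 1\].
#'
#' @param path PNG path.
#' @param image `[H, W, 3]` array for writing.
#' @return `read_image`: the array; `write_image`: the path, invisibly.
#' @export
read_image <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("image I/O requires the 'png' package")
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("image I/O requires the 'png' package")
  png::writePNG(image, path)
  invisible(path)
}
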