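# Detection-metric utilities, robustness scoring, compound multi-task loss,
# deployment energy/endurance arithmetic, confusion utilities and the
# experiment runner tying the modules into reproducible pipelines.

## ---- detection metrics ---------------------------------------------------

.box_iou <- function(a, b) {
  # boxes are (x, y, w, h), 0-based half-open
  ax2 <- a[1] + a[3]; ay2 <- a[2] + a[4]
  bx2 <- b[1] + b[3]; by2 <- b[2] + b[4]
  iw <- max(0, min(ax2, bx2) - max(a[1], b[1]))
  ih <- max(0, min(ay2, by2) - max(a[2], b[2]))
  inter <- iw * ih
  un <- a[3] * a[4] + b[3] * b[4] - inter
  if (un <= 0) 0 else inter / un
}

# all-points interpolated area under the precision-recall curve
.pr_area <- function(tp_flags, n_gt) {
  if (n_gt == 0 || length(tp_flags) == 0) return(0)
  tp <- cumsum(tp_flags)
  fp <- cumsum(!tp_flags)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # precision envelope (monotone non-increasing from the right)
  for (i in rev(seq_along(precision))[-1])
    precision[i] <- max(precision[i], precision[i + 1])
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * precision)
}

#' Average precision and mAP for detections
#'
#' Greedy confidence-ordered matching: each detection matches the
#' highest-IoU unmatched ground truth of its class at IoU >= threshold.
#' AP is the all-points interpolated area under the precision-recall
#' curve; mAP averages over the four health classes (classes with no
#' ground truth and no detections are skipped in the mean).
#'
#' @param detections data.frame with `x`, `y`, `w`, `h`, `class`,
#'   `confidence` (optionally `image`, to scope matching per image).
#' @param annotations data.frame with `x`, `y`, `w`, `h`, `class`
#'   (optionally `image`).
#' @param iou_threshold matching threshold in (0, 1\] (default 0.5).
#' @return List with `per_class` (named AP vector) and `mAP`.
#' @export
average_precision <- function(detections, annotations, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1) stop("invalid IoU threshold")
  cls <- health_classes()$name
  if (nrow(detections) > 0 && is.null(detections$image)) detections$image <- 1L
  if (nrow(annotations) > 0 && is.null(annotations$image)) annotations$image <- 1L
  ap <- stats::setNames(rep(NA_real_, length(cls)), cls)
  for (cl in cls) {
    gt <- annotations[annotations$class == cl, , drop = FALSE]
    det <- detections[detections$class == cl, , drop = FALSE]
    if (nrow(gt) == 0 && nrow(det) == 0) next
    if (nrow(det) == 0) { ap[cl] <- 0; next }
    det <- det[order(-det$confidence), , drop = FALSE]
    matched <- rep(FALSE, nrow(gt))
    tp <- logical(nrow(det))
    for (i in seq_len(nrow(det))) {
      cand <- which(!matched & gt$image == det$image[i])
      if (length(cand)) {
        ious <- vapply(cand, function(j)
          .box_iou(as.numeric(det[i, c("x", "y", "w", "h")]),
                   as.numeric(gt[j, c("x", "y", "w", "h")])), 0)
        best <- which.max(ious)
        if (ious[best] >= iou_threshold) {
          tp[i] <- TRUE
          matched[cand[best]] <- TRUE
        }
      }
    }
    ap[cl] <- .pr_area(tp, nrow(gt))
  }
  present <- !is.na(ap)
  list(per_class = ap, mAP = if (any(present)) mean(ap[present]) else NA_real_)
}

#' Normalized relative robustness score
#'
#' `1 - (clear_model - degraded_model) / (clear_baseline -
#' degraded_baseline)`: 1 means the model does not degrade with turbidity,
#' 0 means it degrades exactly like the baseline. Scale-invariant in the
#' four AP inputs.
#'
#' @param clear_ap_model,degraded_ap_model model APs under clear and
#'   degraded water.
#' @param clear_ap_baseline,degraded_ap_baseline baseline APs.
#' @return Robustness score (unbounded below for models worse than the
#'   baseline).
#' @export
robustness_score <- function(clear_ap_model, degraded_ap_model,
                             clear_ap_baseline, degraded_ap_baseline) {
  d_base <- clear_ap_baseline - degraded_ap_baseline
  if (d_base == 0) stop("zero baseline degradation: score undefined")
  1 - (clear_ap_model - degraded_ap_model) / d_base
}

## ---- compound loss -------------------------------------------------------

#' Compound detection + forecasting loss
#'
#' `l_detection + w_f * l_forecast`, the multi-task objective balancing
#' spatial detection against temporal forecasting (default forecast
#' weight 0.5).
#'
#' @param l_detection,l_forecast finite component losses.
#' @param w_f nonnegative forecast weight (default 0.5).
#' @return Scalar loss.
#' @export
compound_loss <- function(l_detection, l_forecast, w_f = 0.5) {
  if (w_f < 0) stop("w_f must be nonnegative")
  if (!all(is.finite(c(l_detection, l_forecast)))) stop("losses must be finite")
  l_detection + w_f * l_forecast
}

## ---- deployment arithmetic -----------------------------------------------

#' Energy per inference
#'
#' `E = P * t` in joules, also reported in milliwatt-hours.
#'
#' @param power_w device power draw in watts (> 0).
#' @param latency_s per-frame latency in seconds (> 0).
#' @return List with `joules` and `mwh`.
#' @export
energy_per_inference <- function(power_w, latency_s) {
  if (power_w <= 0 || latency_s <= 0) stop("power and latency must be positive")
  j <- power_w * latency_s
  list(joules = j, mwh = j / 3.6)
}

#' Deployment specification for an AUV platform
#'
#' @param device_power_w compute device power (watts).
#' @param latency_s per-frame latency (seconds).
#' @param fps sustained monitoring frame rate (>= 0).
#' @param battery_wh battery capacity (watt-hours).
#' @param base_power_w navigation/propulsion baseline power (watts).
#' @return An object of class `deployment_spec`. Defaults are the
#'   reference constants: 25 W device, 15.6 ms latency, 30 FPS, 1.5 kWh
#'   battery, 200 W baseline.
#' @export
deployment_spec <- function(device_power_w = 25, latency_s = 0.0156,
                            fps = 30, battery_wh = 1500, base_power_w = 200) {
  if (any(c(device_power_w, latency_s, battery_wh, base_power_w) <= 0))
    stop("deployment constants must be positive")
  if (fps < 0) stop("fps must be nonnegative")
  structure(list(device_power_w = device_power_w, latency_s = latency_s,
                 fps = fps, battery_wh = battery_wh,
                 base_power_w = base_power_w), class = "deployment_spec")
}

#' AUV endurance arithmetic
#'
#' Average compute power = energy-per-inference x FPS; total system power
#' = baseline + compute; endurance = battery / total (Wh / W = h).
#'
#' @param spec a [deployment_spec()].
#' @return List with `energy_j`, `compute_power_w`, `total_power_w`,
#'   `hours`.
#' @export
auv_endurance <- function(spec = deployment_spec()) {
  stopifnot(inherits(spec, "deployment_spec"))
  e <- energy_per_inference(spec$device_power_w, spec$latency_s)$joules
  compute <- e * spec$fps
  total <- spec$base_power_w + compute
  list(energy_j = e, compute_power_w = compute, total_power_w = total,
       hours = spec$battery_wh / total)
}

## ---- confusion utilities -------------------------------------------------

#' Confusion matrix over the four health classes
#'
#' Rows are predicted classes, columns are true classes.
#'
#' @param predictions,truths health-class labels of equal length.
#' @return 4x4 integer matrix with class-name dimnames.
#' @export
confusion_matrix <- function(predictions, truths) {
  if (length(predictions) != length(truths)) stop("length mismatch")
  cls <- health_classes()$name
  predictions <- .check_labels(predictions)
  truths <- .check_labels(truths)
  m <- matrix(0L, 4, 4, dimnames = list(predicted = cls, true = cls))
  for (i in seq_along(predictions))
    m[predictions[i], truths[i]] <- m[predictions[i], truths[i]] + 1L
  m
}

#' Per-class recall and precision from a confusion matrix
#'
#' With rows = predicted and columns = true: recall is the diagonal over
#' the column sum, precision the diagonal over the row sum. Classes with
#' no samples give NaN.
#'
#' @param m a 4x4 matrix from [confusion_matrix()].
#' @return data.frame with `class`, `recall`, `precision`.
#' @export
per_class_recall_precision <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
  data.frame(class = rownames(m),
             recall = diag(m) / colSums(m),
             precision = diag(m) / rowSums(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

## ---- experiment runner ---------------------------------------------------

.require_keys <- function(config, keys) {
  miss <- setdiff(keys, names(config))
  if (length(miss))
    stop("experiment config missing required key(s): ",
         paste(miss, collapse = ", "))
}

#' Run a named experiment pipeline
#'
#' Executes one of the canned desk-scale pipelines end to end from a
#' config list and a master seed, returning a JSON-serializable report
#' recording seeds, parameters and metric values.
#'
#' Pipelines:
#' \describe{
#'   \item{`turbidity-robustness`}{generates seeded scenes, degrades them
#'     at the three NTU bands, and reports contrast and finest-HH energy
#'     statistics plus the MSE improvement from suppressive gating.}
#'   \item{`forecasting-comparison`}{trains the SSM forecaster and the
#'     ConvLSTM baseline identically on synthetic trajectories and
#'     reports per-model MAE at the configured horizon.}
#'   \item{`calibration-study`}{trains prototypes on Gaussian-blob
#'     embeddings and reports ECE and silhouette.}
#' }
#'
#' @param config named list; must contain `pipeline` and `seed`, plus
#'   pipeline-specific keys (all have defaults). May also be a path to a
#'   JSON or YAML file.
#' @return A report list (class `experiment_report`).
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  .require_keys(config, c("pipeline", "seed"))
  seed <- as.integer(config$seed)
  report <- list(pipeline = config$pipeline, seed = seed,
                 r_version = as.character(getRversion()),
                 package_version = as.character(utils::packageVersion("coralspectra")),
                 config = config)
  if (config$pipeline == "turbidity-robustness") {
    n <- config$n_scenes %||% 5L
    ntus <- config$ntus %||% c(1, 4, 8)
    contrast <- matrix(0, n, length(ntus))
    hh_frac <- matrix(0, n, length(ntus))
    mse_gain <- numeric(n)
    for (i in seq_len(n)) {
      sc <- generate_scene(seed = split_seed(seed, i), size = config$size %||% 96L)
      gray0 <- apply(sc$image, c(1, 2), mean)
      for (j in seq_along(ntus)) {
        deg <- simulate_turbidity(sc$image, ntus[j], seed = split_seed(seed, 100L + i))
        gray <- apply(deg, c(1, 2), mean)
        contrast[i, j] <- stats::sd(gray)
        hh_frac[i, j] <- subband_energy_fraction(decompose(gray), "HH", 1L)
      }
      deg8 <- simulate_turbidity(sc$image, 8, seed = split_seed(seed, 100L + i))
      gray8 <- apply(deg8, c(1, 2), mean)
      gp <- gate_params(alpha = 0, beta = 1, gamma = 0, delta = 1,
                        weights = replicate(2, {
                          I <- matrix(100, 1, 1)   # saturating logits
                          list(LL = I, LH = I, HL = I, HH = I)
                        }, simplify = FALSE))
      filt <- wio_filter(gray8, gp)$values[1, , ]
      mse_gain[i] <- mean((gray8 - gray0)^2) - mean((filt - gray0)^2)
    }
    report$metrics <- list(
      ntus = ntus,
      mean_contrast = colMeans(contrast),
      mean_finest_hh_fraction = colMeans(hh_frac),
      mean_mse_improvement = mean(mse_gain))
  } else if (config$pipeline == "forecasting-comparison") {
    n <- config$n_trajectories %||% 40L
    spd <- config$steps_per_day %||% 2
    dur <- config$duration_weeks %||% 12
    trajs <- lapply(seq_len(n), function(i) {
      kind <- c("stable", "decay", "recovery")[((i - 1L) %% 3L) + 1L]
      generate_trajectory(
        scenario_spec(kind, duration_weeks = dur, noise_sd = 0.02,
                      seed = split_seed(seed, i)), steps_per_day = spd)
    })
    n_train <- floor(0.7 * n)
    horizon <- config$horizon_weeks %||% 4
    mk <- function(model) {
      model <- train_forecaster(model, trajs[seq_len(n_train)])
      preds <- truth <- numeric(0)
      spw <- 7 * spd
      for (traj in trajs[(n_train + 1L):n]) {
        s <- .traj_series(traj)
        win <- health_trajectory(traj$times[seq_len(model$input_steps)],
                                 s[seq_len(model$input_steps)])
        fc <- forecast(model, win)
        preds <- c(preds, fc$predicted[fc$horizon_weeks == horizon])
        truth <- c(truth, s[model$input_steps + horizon * spw])
      }
      mae(preds, truth)
    }
    report$metrics <- list(
      horizon_weeks = horizon,
      mae_ssm = mk(ssm_forecaster(input_weeks = 4, steps_per_day = spd,
                                  latent_dim = config$latent_dim %||% 16,
                                  seed = seed)),
      mae_convlstm = mk(convlstm_forecaster(input_weeks = 4, steps_per_day = spd,
                                            hidden_channels = config$latent_dim %||% 16,
                                            seed = seed)))
  } else if (config$pipeline == "calibration-study") {
    n_per <- config$n_per_class %||% 30L
    d <- config$dim %||% 8L
    blobs <- .with_seed(seed, {
      cls <- health_classes()$name
      centers <- matrix(stats::rnorm(4 * d, sd = 2), 4, d)
      X <- do.call(rbind, lapply(1:4, function(c_)
        matrix(stats::rnorm(n_per * d, sd = 0.6), n_per, d) +
          matrix(centers[c_, ], n_per, d, byrow = TRUE)))
      list(X = X, y = rep(cls, each = n_per))
    })
    bank <- initialize_prototypes(prototype_bank(d), blobs$X, blobs$y)
    res <- lapply(seq_len(nrow(blobs$X)), function(i) classify(blobs$X[i, ], bank))
    conf <- vapply(res, `[[`, 0, "confidence")
    pred <- vapply(res, `[[`, "", "class")
    report$metrics <- list(
      accuracy = mean(pred == blobs$y),
      ece = expected_calibration_error(conf, pred == blobs$y),
      silhouette = silhouette_score(blobs$X, blobs$y))
  } else {
    stop("unknown pipeline name: ", config$pipeline)
  }
  structure(report, class = "experiment_report")
}

#' Write an experiment report as JSON
#'
#' @param report an `experiment_report` from [run_experiment()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
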