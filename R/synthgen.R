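# Synthetic-data generation: physically motivated turbidity degradation,
# spectral augmentation, four-class reef scenes with annotations, and the
# canonical health-trajectory scenarios used as fixtures everywhere else.

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Deterministic seed splitter
#'
#' Fans a master seed out to per-item seeds; results stay below 2^31.
#'
#' @param master integer master seed.
#' @param index nonnegative integer item index.
#' @return Integer seed.
#' @export
split_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729 + 17) %%
               2147483629)
}

## ---- turbidity -----------------------------------------------------------

#' Canonical turbidity levels
#'
#' Named NTU bands: clear 0-2, medium 2-5, high 5-10.
#'
#' @return data.frame with `name`, `ntu_low`, `ntu_high`.
#' @export
turbidity_levels <- function() {
  data.frame(name = c("clear", "medium", "high"),
             ntu_low = c(0, 2, 5), ntu_high = c(2, 5, 10),
             stringsAsFactors = FALSE)
}

# attenuation constant: chosen so NTU 10 gives transmission ~0.2
# (visibly severe but not black): c = log(5) / 10 per NTU
.TURBIDITY_ATTEN <- log(5) / 10
# bluish-green airlight: red attenuates fastest under water
.AIRLIGHT <- c(0.15, 0.52, 0.62)
.GRAIN_SD <- 0.038

# 3x3 box blur, zero padding
.box_blur3 <- function(m) .conv2d_same(m, matrix(1 / 9, 3, 3))

#' Simulate water turbidity on a clean scene
#'
#' Forward scattering model `I = J * t + A * (1 - t)` with transmission
#' `t = exp(-c * ntu)` (c = log(5)/10, so NTU 10 leaves ~20% transmission)
#' and a bluish-green airlight `A`, plus seeded zero-mean high-pass
#' backscatter grain whose standard deviation grows with `1 - t` (marine
#' snow is high-frequency). `ntu = 0` is the identity; output is clipped
#' to \[0, 1\].
#'
#' @param image `[H, W, 3]` array in \[0, 1\].
#' @param ntu nonnegative turbidity in NTU.
#' @param seed integer seed for the grain.
#' @return Degraded `[H, W, 3]` array.
#' @export
simulate_turbidity <- function(image, ntu, seed = 1L) {
  if (ntu < 0) stop("ntu must be nonnegative")
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L))
    stop("image must be an [H, W, 3] array")
  if (ntu == 0) return(image)
  t_tr <- exp(-.TURBIDITY_ATTEN * ntu)
  out <- image
  .with_seed(seed, {
    H <- dim(image)[1]; W <- dim(image)[2]
    # broadband backscatter: one high-pass grain field shared by all
    # channels (suspended particles scatter across the spectrum)
    noise <- matrix(stats::rnorm(H * W), H, W)
    grain <- (noise - .box_blur3(noise)) * .GRAIN_SD * (1 - t_tr)
    for (ch in 1:3) {
      # forward scattering blurs the scene as transmission drops
      J <- t_tr * image[, , ch] + (1 - t_tr) * .box_blur3(image[, , ch])
      out[, , ch] <- J * t_tr + .AIRLIGHT[ch] * (1 - t_tr) + grain
    }
  })
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Spectral augmentation by HH-coefficient scaling
#'
#' Decomposes each channel, multiplies every HH sub-band by `scale`, and
#' reconstructs. Random draws (when `scale` is NULL) are uniform in
#' \[0.5, 2.0\], emulating variation in water clarity. `scale = 1` is the
#' identity.
#'
#' @param image `[H, W, 3]` array (or matrix / feature_map).
#' @param scale multiplier in (0, 10\]; NULL draws uniformly from
#'   \[0.5, 2\].
#' @param basis,levels wavelet settings (see [decompose()]).
#' @param seed seed for the random draw.
#' @return Augmented image of the same shape/class.
#' @export
spectral_augment <- function(image, scale = NULL, basis = "db4", levels = 2L,
                             seed = 1L) {
  if (is.null(scale)) scale <- .with_seed(seed, stats::runif(1, 0.5, 2.0))
  if (scale <= 0 || scale > 10) stop("scale outside (0, 10]")
  scale_one <- function(m) {
    sub <- decompose(m, basis = basis, levels = levels)
    for (l in seq_along(sub$levels)) sub$levels[[l]]$HH <- sub$levels[[l]]$HH * scale
    reconstruct(sub)$values[1, , ]
  }
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L) {
    out <- image
    for (ch in 1:3) out[, , ch] <- scale_one(image[, , ch])
    return(out)
  }
  v <- .as_fm_values(image)
  out <- v
  for (ch in seq_len(dim(v)[1])) out[ch, , ] <- scale_one(v[ch, , ])
  if (inherits(image, "feature_map")) feature_map(out, image$level_id)
  else if (is.matrix(image)) out[1, , ] else out
}

## ---- reef scenes ---------------------------------------------------------

.CLASS_COLORS <- list(
  "Healthy" = c(0.80, 0.42, 0.18),      # saturated warm coral
  "Sub-healthy" = c(0.74, 0.46, 0.22),
  "Bleached" = c(0.60, 0.55, 0.45),
  "Dead" = c(0.38, 0.44, 0.36)          # grey-green overgrowth
)
.PALE <- c(0.93, 0.91, 0.84)

#' Generate a synthetic reef scene with annotations
#'
#' Renders textured elliptical coral blobs on a smooth seabed background.
#' Class morphology is measurable: Healthy blobs keep saturated colour,
#' Sub-healthy blobs carry pale discoloration patches covering under 30%
#' of the blob, Bleached blobs are 30-90% pale, Dead blobs get grey-green
#' overgrowth texture. Boxes are 0-based, half-open pixel rectangles.
#'
#' @param n_corals number of blobs (>= 0).
#' @param class_mix named numeric vector of class probabilities summing to
#'   1 (default uniform over the four classes).
#' @param size image side in pixels (>= 64).
#' @param turbidity NULL (clean), a level name (`"clear"`, `"medium"`,
#'   `"high"`; the band midpoint NTU is used), or a numeric NTU.
#' @param seed integer seed; scenes are bit-reproducible per seed.
#' @return List with `image` (`[size, size, 3]`) and `annotations`
#'   (data.frame `x`, `y`, `w`, `h`, `class`, `occluded`, `pale_fraction`).
#' @export
generate_scene <- function(n_corals = 6L, class_mix = NULL, size = 128L,
                           turbidity = NULL, seed = 1L) {
  if (n_corals < 0) stop("n_corals must be >= 0")
  size <- as.integer(size)
  if (size < 64L) stop("size must be >= 64")
  cls <- health_classes()$name
  if (is.null(class_mix)) class_mix <- stats::setNames(rep(0.25, 4), cls)
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (!all(names(class_mix) %in% cls)) stop("class_mix names must be health classes")

  res <- .with_seed(seed, {
    # seabed: bluish sand with smoothed noise
    base <- c(0.32, 0.42, 0.48)
    img <- array(0, c(size, size, 3))
    tex <- matrix(stats::rnorm(size * size, sd = 1), size, size)
    for (i in 1:3) tex <- .box_blur3(tex)
    for (ch in 1:3) img[, , ch] <- pmin(pmax(base[ch] + 0.09 * tex, 0), 1)

    ann <- data.frame(x = integer(0), y = integer(0), w = integer(0),
                      h = integer(0), class = character(0),
                      occluded = logical(0), pale_fraction = numeric(0),
                      stringsAsFactors = FALSE)
    if (n_corals > 0) {
      labels <- sample(names(class_mix), n_corals, replace = TRUE,
                       prob = class_mix)
      xs <- matrix(rep(seq_len(size), each = size), size, size)  # xs[i,j] = j
      ys <- t(xs)                                                # ys[i,j] = i
      for (b in seq_len(n_corals)) {
        lab <- labels[b]
        cx <- stats::runif(1, size * 0.15, size * 0.85)
        cy <- stats::runif(1, size * 0.15, size * 0.85)
        rx <- stats::runif(1, size * 0.06, size * 0.14)
        ry <- stats::runif(1, size * 0.06, size * 0.14)
        th <- stats::runif(1, 0, pi)
        dx <- (xs - cx); dy <- (ys - cy)
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        mask <- (u / rx)^2 + (v / ry)^2 <= 1
        npx <- sum(mask)
        if (npx == 0) next
        colr <- .CLASS_COLORS[[lab]]
        # per-pixel texture inside the blob
        jitter <- matrix(stats::rnorm(size * size, sd = 0.04), size, size)
        pale_target <- switch(lab,
          "Healthy" = 0,
          "Sub-healthy" = stats::runif(1, 0.10, 0.28),
          "Bleached" = stats::runif(1, 0.35, 0.85),
          "Dead" = 0)
        pale_mask <- matrix(FALSE, size, size)
        if (pale_target > 0) {
          # pale patches: threshold a smoothed noise field inside the blob
          field <- matrix(stats::rnorm(size * size), size, size)
          for (i in 1:2) field <- .box_blur3(field)
          vals <- field[mask]
          thr <- stats::quantile(vals, 1 - pale_target)
          pale_mask[mask] <- field[mask] >= thr
        }
        for (ch in 1:3) {
          layer <- img[, , ch]
          layer[mask] <- pmin(pmax(colr[ch] + jitter[mask], 0), 1)
          if (lab == "Dead") {
            overg <- matrix(stats::rnorm(size * size, sd = 0.08), size, size)
            layer[mask] <- pmin(pmax(layer[mask] + overg[mask], 0), 1)
          }
          layer[pale_mask] <- pmin(pmax(.PALE[ch] +
                                          jitter[pale_mask] * 0.5, 0), 1)
          img[, , ch] <- layer
        }
        cols_in <- which(apply(mask, 2, any)); rows_in <- which(apply(mask, 1, any))
        ann <- rbind(ann, data.frame(
          x = min(cols_in) - 1L, y = min(rows_in) - 1L,
          w = max(cols_in) - min(cols_in) + 1L,
          h = max(rows_in) - min(rows_in) + 1L,
          class = lab, occluded = FALSE,
          pale_fraction = if (npx > 0) sum(pale_mask[mask]) / npx else 0,
          stringsAsFactors = FALSE))
      }
    }
    # antialias the composed scene (two passes): captured imagery is never
    # pixel-sharp, and this keeps the clean scene's detail-band energy low
    for (ch in 1:3) img[, , ch] <- .box_blur3(.box_blur3(img[, , ch]))
    list(image = img, annotations = ann)
  })
  if (!is.null(turbidity)) {
    ntu <- if (is.character(turbidity)) {
      tl <- turbidity_levels()
      row <- tl[tl$name == turbidity, ]
      if (nrow(row) == 0) stop("unknown turbidity level '", turbidity, "'")
      (row$ntu_low + row$ntu_high) / 2
    } else as.numeric(turbidity)
    res$image <- simulate_turbidity(res$image, ntu, seed = split_seed(seed, 999L))
  }
  res
}

## ---- trajectories --------------------------------------------------------

#' Scenario specification for trajectory generation
#'
#' Canonical reef-health scenarios: `stable` (constant 0.95), `decay`
#' (exponential 0.95 -> 0.10 over the stated duration), `recovery` (decay
#' to a 0.30 dip, then logistic recovery to 0.60 over the final three
#' weeks) and `heterogeneous` (a spatial grid whose regions decay at
#' different drawn rates).
#'
#' @param kind scenario kind.
#' @param start,end,dip health levels in \[0, 1\].
#' @param duration_weeks positive duration.
#' @param noise_sd i.i.d. Gaussian observation noise (default 0).
#' @param seed integer seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("stable", "decay", "recovery", "heterogeneous"),
                          start = 0.95, end = NULL, dip = 0.30,
                          duration_weeks = 4, noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(end))
    end <- switch(kind, stable = start, decay = 0.10, recovery = 0.60,
                  heterogeneous = 0.10)
  lv <- c(start, end, dip)
  if (any(lv < 0 | lv > 1)) stop("health levels must be in [0, 1]")
  if (duration_weeks <= 0) stop("duration must be positive")
  structure(list(kind = kind, start = start, end = end, dip = dip,
                 duration_weeks = duration_weeks, noise_sd = noise_sd,
                 seed = seed), class = "scenario_spec")
}

# decay rate reaching within 0.5% of the start-end gap by t_end (hours)
.decay_rate <- function(start, plateau, t_end) log((start - plateau) / 0.005) / t_end

#' Generate a canonical health trajectory
#'
#' See [scenario_spec()] for the scenario shapes. Noise is i.i.d.
#' Gaussian, added after the deterministic curve and clipped to \[0, 1\];
#' generation is bit-reproducible under the spec's seed.
#'
#' @param spec a [scenario_spec()].
#' @param steps_per_day temporal resolution (default 24).
#' @param grid_size optional `c(H, W)`; required for `heterogeneous`,
#'   which returns a per-cell health grid.
#' @return A [health_trajectory()]; `meta` records the generator
#'   parameters (`k`, `p`, `h0` for decay-type curves).
#' @export
generate_trajectory <- function(spec, steps_per_day = 24, grid_size = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  t_end <- spec$duration_weeks * 7 * 24                      # hours
  dt <- 24 / steps_per_day
  times <- seq(0, t_end, by = dt)
  Tn <- length(times)
  meta <- list(kind = spec$kind, noise_sd = spec$noise_sd)
  curve <- switch(spec$kind,
    stable = rep(spec$start, Tn),
    decay = {
      k <- .decay_rate(spec$start, spec$end, t_end)
      meta$k <- k; meta$p <- spec$end; meta$h0 <- spec$start
      spec$end + (spec$start - spec$end) * exp(-k * times)
    },
    recovery = {
      rec_weeks <- min(3, spec$duration_weeks)
      t_dip <- t_end - rec_weeks * 7 * 24
      if (t_dip <= 0) t_dip <- t_end / 4
      k <- .decay_rate(spec$start, spec$dip, t_dip)
      meta$k <- k
      phase1 <- spec$dip + (spec$start - spec$dip) * exp(-k * times)
      r <- 2 * log((spec$end - spec$dip) / 0.005 - 1) / (t_end - t_dip)
      phase2 <- spec$dip + (spec$end - spec$dip) *
        .sigmoid(r * (times - (t_dip + t_end) / 2))
      ifelse(times <= t_dip, phase1, pmax(phase2, spec$dip))
    },
    heterogeneous = NULL,
    stop("invalid scenario kind"))
  if (spec$kind == "heterogeneous") {
    if (is.null(grid_size)) grid_size <- c(4L, 4L)
    Hg <- grid_size[1]; Wg <- grid_size[2]
    base_k <- .decay_rate(spec$start, spec$end, t_end)
    arr <- .with_seed(spec$seed, {
      kcell <- matrix(base_k * exp(stats::rnorm(Hg * Wg, sd = 0.5)), Hg, Wg)
      a <- array(0, c(Tn, Hg, Wg))
      for (i in seq_len(Hg)) for (j in seq_len(Wg))
        a[, i, j] <- spec$end + (spec$start - spec$end) * exp(-kcell[i, j] * times)
      clean <- a
      if (spec$noise_sd > 0)
        a <- a + array(stats::rnorm(length(a), sd = spec$noise_sd), dim(a))
      a[a < 0] <- 0; a[a > 1] <- 1
      attr(a, "curve") <- clean
      a
    })
    meta$k <- base_k
    meta$curve <- apply(attr(arr, "curve"), 1L, mean)
    attr(arr, "curve") <- NULL
    return(health_trajectory(times, arr, meta = meta))
  }
  h <- .with_seed(spec$seed, {
    if (spec$noise_sd > 0) curve + stats::rnorm(Tn, sd = spec$noise_sd) else curve
  })
  h[h < 0] <- 0; h[h > 1] <- 1
  meta$curve <- pmin(pmax(curve, 0), 1)       # noise-free ground truth
  health_trajectory(times, h, meta = meta)
}

#' Generate a temporally split trajectory dataset
#'
#' Generates full multi-week trajectories over a mix of all four scenario
#' kinds and splits each into non-overlapping temporal windows: training
#' windows cover early degradation (weeks 0-1), validation the
#' intermediate phase (weeks 1-2), and test the late phase (weeks 2 to the
#' end) — test phases are never seen in training.
#'
#' @param n_sequences number of base trajectories (>= 3).
#' @param split_mode currently `"temporal"`.
#' @param seed master seed (fanned out per trajectory via [split_seed()]).
#' @param steps_per_day resolution (default 2, the field capture rate).
#' @param duration_weeks full trajectory length (default 4).
#' @param noise_sd observation noise (default 0.02).
#' @return List with `train`, `val`, `test` (lists of trajectories) and
#'   `full` (the unsplit trajectories).
#' @export
generate_sequence_dataset <- function(n_sequences, split_mode = "temporal",
                                      seed = 1L, steps_per_day = 2,
                                      duration_weeks = 4, noise_sd = 0.02) {
  if (n_sequences < 3) stop("need at least 3 sequences")
  if (split_mode != "temporal") stop("unknown split mode: ", split_mode)
  kinds <- c("stable", "decay", "recovery", "heterogeneous")
  full <- vector("list", n_sequences)
  for (i in seq_len(n_sequences)) {
    kind <- kinds[((i - 1L) %% 4L) + 1L]
    sp <- scenario_spec(kind, duration_weeks = duration_weeks,
                        noise_sd = noise_sd, seed = split_seed(seed, i))
    full[[i]] <- generate_trajectory(sp, steps_per_day = steps_per_day,
                                     grid_size = if (kind == "heterogeneous") c(4L, 4L))
  }
  window <- function(traj, w_lo, w_hi) {
    lo <- w_lo * 7 * 24; hi <- w_hi * 7 * 24
    idx <- which(traj$times >= lo & traj$times < hi)
    h <- if (traj$grid) traj$health[idx, , , drop = FALSE] else traj$health[idx]
    health_trajectory(traj$times[idx], h,
                      meta = c(traj$meta, list(phase_weeks = c(w_lo, w_hi))))
  }
  list(train = lapply(full, window, 0, 1),
       val = lapply(full, window, 1, 2),
       test = lapply(full, window, 2, duration_weeks + 1e-9),
       full = full)
}

#' Random temporal dropout
#'
#' Masks each step independently with probability `p` (masked health set
#' to `NA`); the mask is recorded in `meta$dropout_mask`.
#'
#' @param traj a [health_trajectory()].
#' @param p dropout probability in \[0, 1).
#' @param seed integer seed.
#' @return The masked trajectory.
#' @export
temporal_dropout <- function(traj, p = 0.1, seed = 1L) {
  if (p < 0 || p >= 1) stop("p must be in [0, 1)")
  Tn <- length(traj$times)
  mask <- .with_seed(seed, stats::runif(Tn) < p)
  if (traj$grid) traj$health[mask, , ] <- NA_real_ else traj$health[mask] <- NA_real_
  traj$meta$dropout_mask <- mask
  traj
}
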