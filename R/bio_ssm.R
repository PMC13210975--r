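# Continuous health forecasting: latent encoding, a diagonal selective
# state-space scan (linear time in sequence length), ridge-trained
# multi-horizon forecast heads, a ConvLSTM baseline, biological-plausibility
# metrics and Monte-Carlo-dropout uncertainty.

## ---- trajectory container ------------------------------------------------

#' Health trajectory
#'
#' A time series of health indices in \[0, 1\]: either a scalar per step or
#' a spatial grid per step (array `[T, Hg, Wg]`). Times are hours and must
#' be strictly increasing.
#'
#' @param times_h strictly increasing numeric timestamps (hours).
#' @param health numeric vector in \[0, 1\] (length `T`) or array
#'   `[T, Hg, Wg]`.
#' @param covariates optional `T x k` matrix of environmental covariates
#'   (temperature, radiation, current, nutrients).
#' @param meta optional named list of generator metadata.
#' @return An object of class `health_trajectory`.
#' @export
health_trajectory <- function(times_h, health, covariates = NULL, meta = list()) {
  if (any(diff(times_h) <= 0)) stop("times must be strictly increasing")
  is_grid <- is.array(health) && length(dim(health)) == 3L
  Tn <- if (is_grid) dim(health)[1] else length(health)
  if (Tn != length(times_h)) stop("health length must match times")
  if (any(health < 0 | health > 1, na.rm = TRUE))
    stop("health values must lie in [0, 1]")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != Tn) stop("covariates rows must match times")
  }
  structure(list(times = times_h, health = health, covariates = covariates,
                 grid = is_grid, meta = meta),
            class = "health_trajectory")
}

#' @export
print.health_trajectory <- function(x, ...) {
  cat(sprintf("<health_trajectory: %d steps over %.1f days%s>\n",
              length(x$times), diff(range(x$times)) / 24,
              if (x$grid) sprintf(", %dx%d grid", dim(x$health)[2], dim(x$health)[3]) else ""))
  invisible(x)
}

# scalar health series of a trajectory (spatial mean for grids)
.traj_series <- function(traj) {
  if (inherits(traj, "health_trajectory")) {
    if (traj$grid) apply(traj$health, 1L, mean) else traj$health
  } else as.numeric(traj)
}

## ---- latent encoding -----------------------------------------------------

#' Seeded per-step linear encoder
#'
#' The 1x1 (per-step) projection from observed values into the latent
#' space consumed by the scan. Weights are drawn once from a seeded
#' Gaussian; the encoder has no temporal extent, so permuting time steps
#' permutes outputs identically.
#'
#' @param d_in input dimension per step.
#' @param latent_dim latent dimension `D`.
#' @param seed integer seed.
#' @param bias include a bias term (default TRUE).
#' @return List with weight `W` (`D x d_in`) and bias `b`.
#' @export
latent_encoder <- function(d_in, latent_dim, seed = 1L, bias = TRUE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  list(W = matrix(stats::rnorm(latent_dim * d_in, sd = 1 / sqrt(d_in)),
                  latent_dim, d_in),
       b = if (bias) stats::rnorm(latent_dim, sd = 0.1) else rep(0, latent_dim))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Encode a sequence into latents
#'
#' Applies the per-step linear encoder to each time step.
#'
#' @param x numeric vector (one value per step) or `T x d_in` matrix.
#' @param encoder a [latent_encoder()].
#' @return `T x D` latent matrix.
#' @export
encode_latent <- function(x, encoder) {
  X <- if (is.null(dim(x))) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
  if (nrow(X) == 0L) stop("empty sequence")
  if (ncol(X) != ncol(encoder$W)) stop("input dimension mismatch")
  sweep(X %*% t(encoder$W), 2L, encoder$b, "+")
}

## ---- selective scan ------------------------------------------------------

#' Selective state-space scan parameters
#'
#' A diagonal discretized linear state space with input-dependent step
#' size (the selective gate). Each latent channel `d` carries one state
#' with continuous decay rate `a_d > 0`; decay rates are log-spaced so the
#' bank spans fast to slow timescales. Per step, `delta_t,d =
#' softplus(w_dt_d * x_t,d + b_dt_d)` and zero-order hold gives
#' `Abar = exp(-delta * a)`, `Bbar = (1 - Abar) / a * b_in`, with readout
#' `y = c * h + skip * x`.
#'
#' @param latent_dim number of channels `D`.
#' @param seed integer seed for the input/output projections.
#' @param a_min,a_max decay-rate range (must be positive for stability).
#' @return An object of class `ssm_params`.
#' @export
ssm_params <- function(latent_dim, seed = 1L, a_min = 0.01, a_max = 1.0) {
  if (a_min <= 0 || a_max <= 0) stop("unstable parameterization: decay rates must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  D <- latent_dim
  structure(list(
    a = exp(seq(log(a_min), log(a_max), length.out = D)),
    b_in = stats::rnorm(D, sd = 1),
    c_out = stats::rnorm(D, sd = 1),
    skip = stats::rnorm(D, sd = 0.5),
    w_dt = stats::rnorm(D, sd = 0.5),
    b_dt = rep(0.5, D)
  ), class = "ssm_params")
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Selective state-space scan
#'
#' Causal linear-time recurrence over a `T x D` latent sequence: the output
#' at step `t` depends only on inputs at steps `<= t`, and the arithmetic
#' cost is proportional to `T`.
#'
#' @param latents `T x D` matrix from [encode_latent()].
#' @param params an [ssm_params()] with matching `D`.
#' @param return_state also return the state trajectory `H` (`T x D`).
#' @return `T x D` output matrix (or `list(y, h)` when `return_state`).
#' @export
selective_scan <- function(latents, params, return_state = FALSE) {
  stopifnot(inherits(params, "ssm_params"))
  X <- as.matrix(latents)
  if (!all(is.finite(X))) stop("latents must be finite")
  D <- length(params$a)
  if (ncol(X) != D) stop("latent dimension mismatch")
  if (any(params$a <= 0)) stop("unstable parameterization: decay rates must be positive")
  Tn <- nrow(X)
  Y <- matrix(0, Tn, D)
  Hs <- if (return_state) matrix(0, Tn, D)
  h <- rep(0, D)
  for (t in seq_len(Tn)) {
    x <- X[t, ]
    delta <- .softplus(params$w_dt * x + params$b_dt)
    Abar <- exp(-delta * params$a)
    Bbar <- (1 - Abar) / params$a * params$b_in
    h <- Abar * h + Bbar * x
    Y[t, ] <- params$c_out * h + params$skip * x
    if (return_state) Hs[t, ] <- h
  }
  if (return_state) list(y = Y, h = Hs) else Y
}

## ---- forecaster ----------------------------------------------------------

#' Configure a state-space health forecaster
#'
#' A toy-scale forecaster: per-step encoder, selective scan, and one ridge
#' readout head per horizon trained on the scan's final-step features. The
#' documented full-scale latent dimension is 256; the default here is a
#' CPU-friendly 24.
#'
#' @param input_weeks history window fed to the model, in weeks.
#' @param horizons_weeks forecast horizons in weeks (ascending; default
#'   `c(1, 2, 4)`).
#' @param steps_per_day temporal resolution (default 24, i.e. 672 steps =
#'   4 weeks).
#' @param latent_dim latent dimension `D` (default 24).
#' @param dropout_p dropout probability used by [mc_dropout_forecast()].
#' @param seed integer seed for the random projections.
#' @return An object of class `ssm_forecaster`.
#' @export
ssm_forecaster <- function(input_weeks = 4, horizons_weeks = c(1, 2, 4),
                           steps_per_day = 24, latent_dim = 24,
                           dropout_p = 0.1, seed = 1L) {
  if (is.unsorted(horizons_weeks)) stop("horizons must be ascending")
  structure(list(
    input_steps = as.integer(round(input_weeks * 7 * steps_per_day)),
    horizons_weeks = horizons_weeks,
    steps_per_day = steps_per_day,
    latent_dim = latent_dim,
    dropout_p = dropout_p,
    seed = seed,
    encoder = latent_encoder(1L, latent_dim, seed = seed),
    params = ssm_params(latent_dim, seed = seed),
    readout = NULL
  ), class = c("ssm_forecaster", "health_forecaster"))
}

# features summarizing an input window: the final latent state (the
# ConvLSTM baseline symmetrically uses its final hidden state)
.ssm_features <- function(model, series) {
  Z <- encode_latent(series, model$encoder)
  selective_scan(Z, model$params, return_state = TRUE)$h[length(series), ]
}

.forecaster_features <- function(model, series) {
  if (inherits(model, "ssm_forecaster")) .ssm_features(model, series)
  else .convlstm_features(model, series)
}

.ridge_fit <- function(X, y, lambda = 1e-2) {
  Xc <- cbind(1, X)
  A <- crossprod(Xc) + lambda * diag(ncol(Xc))
  A[1, 1] <- A[1, 1] - lambda          # do not penalize the intercept
  drop(solve(A, crossprod(Xc, y)))
}

#' Train a forecaster on trajectories
#'
#' Slides one window per trajectory (the first `input_steps` observations)
#' and ridge-regresses the health value at each horizon onto the model's
#' recurrent features. Both the state-space forecaster and the ConvLSTM
#' baseline are trained through this identical routine, so comparisons
#' differ only in the recurrence.
#'
#' @param model an [ssm_forecaster()] or [convlstm_forecaster()].
#' @param trajectories list of [health_trajectory()] objects, each long
#'   enough for the window plus the largest horizon.
#' @param lambda ridge penalty (default 1e-2).
#' @return The model with fitted readout heads.
#' @export
train_forecaster <- function(model, trajectories, lambda = 1e-2) {
  steps_per_week <- 7 * model$steps_per_day
  need <- model$input_steps + max(model$horizons_weeks) * steps_per_week
  feats <- list(); targets <- list()
  for (traj in trajectories) {
    s <- .traj_series(traj)
    if (length(s) < need) stop("trajectory shorter than window + horizon (",
                               length(s), " < ", need, ")")
    win <- s[seq_len(model$input_steps)]
    feats[[length(feats) + 1L]] <- .forecaster_features(model, win)
    targets[[length(targets) + 1L]] <-
      s[model$input_steps + model$horizons_weeks * steps_per_week]
  }
  X <- do.call(rbind, feats)
  Yt <- do.call(rbind, targets)
  model$readout <- lapply(seq_along(model$horizons_weeks),
                          function(j) .ridge_fit(X, Yt[, j], lambda))
  names(model$readout) <- paste0("week", model$horizons_weeks)
  model
}

.predict_heads <- function(model, feats, last_value = 0.5) {
  if (is.null(model$readout)) {
    # untrained: persistence on the last observed value, clamped
    return(rep(min(max(last_value, 0), 1), length(model$horizons_weeks)))
  }
  vapply(model$readout, function(beta) {
    min(max(sum(beta * c(1, feats)), 0), 1)
  }, 0)
}

#' Multi-horizon health forecast
#'
#' Predicts the health index at each configured horizon from the last
#' `input_steps` observations of the trajectory (grids are reduced to
#' their spatial mean). Predictions are clamped to \[0, 1\]. The result
#' carries a degenerate (zero-width) uncertainty; use
#' [mc_dropout_forecast()] for calibrated intervals.
#'
#' @param model a (trained) forecaster.
#' @param traj a [health_trajectory()] with at least one week of history
#'   (and at least `input_steps` observations).
#' @return An object of class `forecast_result`: a data.frame with columns
#'   `horizon_weeks`, `predicted`, `mean`, `std`, `interval_low`,
#'   `interval_high`.
#' @export
forecast <- function(model, traj) {
  s <- .traj_series(traj)
  min_hist <- 7L * model$steps_per_day           # one week of steps
  if (length(s) < min_hist)
    stop("history shorter than the one-week minimum (", length(s),
         " < ", min_hist, " steps)")
  if (length(s) < model$input_steps)
    stop("history shorter than the model's input window")
  win <- s[seq(length(s) - model$input_steps + 1L, length(s))]
  pred <- .predict_heads(model, .forecaster_features(model, win),
                         last_value = win[length(win)])
  structure(data.frame(horizon_weeks = model$horizons_weeks,
                       predicted = pred, mean = pred, std = 0,
                       interval_low = pred, interval_high = pred),
            class = c("forecast_result", "data.frame"))
}

#' Monte-Carlo-dropout forecast with uncertainty
#'
#' Keeps dropout active at inference: recurrent features are masked i.i.d.
#' with probability `p` (inverted dropout scaling) on each of `passes`
#' stochastic forward passes. Reports the predictive mean, standard
#' deviation and the 95% interval `mean +/- 1.96 * std` per horizon.
#' With `p = 0` every pass is identical and the interval collapses onto
#' the deterministic forecast.
#'
#' @param model a trained forecaster.
#' @param traj a [health_trajectory()].
#' @param passes number of stochastic passes (default 30, must be >= 2).
#' @param p dropout probability in \[0, 1).
#' @param seed integer seed for reproducible masks.
#' @return A `forecast_result` data.frame.
#' @export
mc_dropout_forecast <- function(model, traj, passes = 30L, p = model$dropout_p,
                                seed = 1L) {
  if (p < 0 || p >= 1) stop("dropout p must be in [0, 1)")
  passes <- as.integer(passes)
  if (passes < 2L) stop("need at least two passes")
  s <- .traj_series(traj)
  win <- s[seq(length(s) - model$input_steps + 1L, length(s))]
  feats <- .forecaster_features(model, win)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  preds <- matrix(0, passes, length(model$horizons_weeks))
  for (i in seq_len(passes)) {
    f <- if (p > 0) feats * (stats::runif(length(feats)) >= p) / (1 - p) else feats
    preds[i, ] <- .predict_heads(model, f, last_value = win[length(win)])
  }
  mu <- colMeans(preds)
  sd_ <- apply(preds, 2L, stats::sd)
  structure(data.frame(horizon_weeks = model$horizons_weeks,
                       predicted = mu, mean = mu, std = sd_,
                       interval_low = mu - 1.96 * sd_,
                       interval_high = mu + 1.96 * sd_),
            class = c("forecast_result", "data.frame"))
}

## ---- forecast loss and curriculum ----------------------------------------

#' Forecast loss with spatial smoothness regularization
#'
#' Mean squared prediction error plus `smooth_weight` times the mean
#' squared spatial first difference of the prediction (both grid axes),
#' reflecting the gradual spatial character of biological degradation.
#' Scalar predictions incur no smoothness penalty.
#'
#' @param predicted,true numeric vectors, matrices or `[T, H, W]` arrays of
#'   matching shape.
#' @param smooth_weight nonnegative smoothness weight (default 0.1).
#' @return Nonnegative scalar.
#' @export
forecast_loss <- function(predicted, true, smooth_weight = 0.1) {
  if (!identical(dim(predicted), dim(true)) ||
      length(predicted) != length(true)) stop("shape mismatch")
  if (smooth_weight < 0) stop("smooth_weight must be nonnegative")
  mse <- mean((predicted - true)^2)
  pen <- 0
  grids <- if (is.matrix(predicted)) list(predicted)
           else if (is.array(predicted) && length(dim(predicted)) == 3L)
             lapply(seq_len(dim(predicted)[1]), function(t) predicted[t, , ])
           else NULL
  if (!is.null(grids)) {
    diffs <- unlist(lapply(grids, function(g) {
      c(if (nrow(g) > 1) as.numeric(diff(g)) else numeric(0),
        if (ncol(g) > 1) as.numeric(t(diff(t(g)))) else numeric(0))
    }))
    if (length(diffs)) pen <- mean(diffs^2)
  }
  mse + smooth_weight * pen
}

#' Curriculum forecast horizon
#'
#' Linear-in-epoch schedule over thirds of training: the horizon grows
#' 1 -> 2 -> 4 weeks, starting at one week and ending at four.
#'
#' @param epoch 0-based epoch index.
#' @param total_epochs schedule length (default 300).
#' @return Horizon in weeks (1, 2 or 4).
#' @export
curriculum_horizon <- function(epoch, total_epochs = 300L) {
  if (epoch < 0) stop("epoch must be >= 0")
  frac <- if (total_epochs <= 1) 1 else epoch / (total_epochs - 1)
  if (frac < 1 / 3) 1 else if (frac < 2 / 3) 2 else 4
}

## ---- ConvLSTM baseline ---------------------------------------------------

# direct 2-D convolution with zero 'same' padding; fine at toy grid sizes
.conv2d_same <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  xp <- matrix(0, H + 2L * ph, W + 2L * pw)
  xp[ph + seq_len(H), pw + seq_len(W)] <- x
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    out <- out + k[i, j] * xp[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W)]
  }
  out
}

#' ConvLSTM cell
#'
#' A gated convolutional recurrence (input, forget, output, candidate
#' gates, each a convolution over the stacked input and hidden channels).
#' The full-scale comparator configuration is 40x40 grids with 64 hidden
#' channels; defaults here are toy-sized.
#'
#' @param in_channels,hidden_channels channel counts.
#' @param grid `c(H, W)` spatial size.
#' @param kernel odd kernel size (default 3).
#' @param seed integer seed for weight init.
#' @return An object of class `convlstm_cell`.
#' @export
convlstm_cell <- function(in_channels = 1L, hidden_channels = 4L,
                          grid = c(1L, 1L), kernel = 3L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 2L)
  nch <- in_channels + hidden_channels
  mk <- function() {
    lapply(seq_len(hidden_channels), function(o)
      lapply(seq_len(nch), function(i)
        matrix(stats::rnorm(kernel * kernel, sd = 1 / sqrt(nch * kernel * kernel)),
               kernel, kernel)))
  }
  Wi <- mk(); Wf <- mk(); Wo <- mk(); Wg <- mk()
  # center-tap matrices give a fast vector path on 1x1 grids
  ctr <- (kernel + 1L) %/% 2L
  tapmat <- function(Wl) t(vapply(Wl, function(row)
    vapply(row, function(k) k[ctr, ctr], 0), numeric(nch)))
  structure(list(in_channels = in_channels, hidden_channels = hidden_channels,
                 grid = as.integer(grid), kernel = as.integer(kernel),
                 Wi = Wi, Wf = Wf, Wo = Wo, Wg = Wg,
                 Wi_mat = tapmat(Wi), Wf_mat = tapmat(Wf),
                 Wo_mat = tapmat(Wo), Wg_mat = tapmat(Wg),
                 bi = stats::rnorm(hidden_channels, sd = 0.1),
                 bf = rep(1, hidden_channels),   # forget-gate bias init
                 bo = stats::rnorm(hidden_channels, sd = 0.1),
                 bg = stats::rnorm(hidden_channels, sd = 0.1)),
            class = "convlstm_cell")
}

#' Zero ConvLSTM state
#'
#' @param cell a [convlstm_cell()].
#' @return List of hidden `h` and cell `c` arrays `[hidden, H, W]`.
#' @export
convlstm_state <- function(cell) {
  z <- array(0, c(cell$hidden_channels, cell$grid[1], cell$grid[2]))
  list(h = z, c = z)
}

#' One ConvLSTM step
#'
#' Standard gated convolutional recurrence:
#' `i,f,o = sigmoid(conv([x; h]))`, `g = tanh(conv([x; h]))`,
#' `c <- f * c + i * g`, `h <- o * tanh(c)`.
#'
#' @param x_t input array `[in_channels, H, W]` (a matrix is one channel).
#' @param state list `h`/`c` from [convlstm_state()] or a previous step.
#' @param cell a [convlstm_cell()].
#' @return List with output `y` (the new hidden state) and `state`.
#' @export
convlstm_step <- function(x_t, state, cell) {
  if (is.matrix(x_t)) x_t <- array(x_t, c(1L, nrow(x_t), ncol(x_t)))
  if (length(x_t) == 1L && cell$grid[1] == 1L && cell$grid[2] == 1L)
    x_t <- array(x_t, c(1L, 1L, 1L))
  dx <- dim(x_t)
  if (dx[1] != cell$in_channels || dx[2] != cell$grid[1] || dx[3] != cell$grid[2])
    stop("input shape does not match cell configuration")
  if (cell$grid[1] == 1L && cell$grid[2] == 1L) {
    # vector fast path: a 1x1 grid reduces every convolution to its
    # center tap
    sv <- c(as.numeric(x_t), as.numeric(state$h))
    i_g <- .sigmoid(cell$Wi_mat %*% sv + cell$bi)
    f_g <- .sigmoid(cell$Wf_mat %*% sv + cell$bf)
    o_g <- .sigmoid(cell$Wo_mat %*% sv + cell$bo)
    g_g <- tanh(cell$Wg_mat %*% sv + cell$bg)
    c_new <- array(f_g * as.numeric(state$c) + i_g * g_g,
                   c(cell$hidden_channels, 1L, 1L))
    h_new <- array(as.numeric(o_g) * tanh(c_new), dim(c_new))
    return(list(y = h_new, state = list(h = h_new, c = c_new)))
  }
  stacked <- array(0, c(cell$in_channels + cell$hidden_channels,
                        cell$grid[1], cell$grid[2]))
  stacked[seq_len(cell$in_channels), , ] <- x_t
  stacked[cell$in_channels + seq_len(cell$hidden_channels), , ] <- state$h
  gate <- function(Wlist, b, act) {
    out <- array(0, c(cell$hidden_channels, cell$grid[1], cell$grid[2]))
    for (o in seq_len(cell$hidden_channels)) {
      acc <- matrix(b[o], cell$grid[1], cell$grid[2])
      for (i in seq_len(dim(stacked)[1]))
        acc <- acc + .conv2d_same(matrix(stacked[i, , ], cell$grid[1]),
                                  Wlist[[o]][[i]])
      out[o, , ] <- act(acc)
    }
    out
  }
  i_g <- gate(cell$Wi, cell$bi, .sigmoid)
  f_g <- gate(cell$Wf, cell$bf, .sigmoid)
  o_g <- gate(cell$Wo, cell$bo, .sigmoid)
  g_g <- gate(cell$Wg, cell$bg, tanh)
  c_new <- f_g * state$c + i_g * g_g
  h_new <- o_g * tanh(c_new)
  list(y = h_new, state = list(h = h_new, c = c_new))
}

#' Configure a ConvLSTM baseline forecaster
#'
#' Same interface, readout and training routine as [ssm_forecaster()];
#' only the recurrence differs. Scalar trajectories run on a 1x1 grid.
#'
#' @inheritParams ssm_forecaster
#' @param hidden_channels hidden channels (sized to match the SSM's
#'   feature count by default).
#' @return An object of class `convlstm_forecaster`.
#' @export
convlstm_forecaster <- function(input_weeks = 4, horizons_weeks = c(1, 2, 4),
                                steps_per_day = 24, hidden_channels = 24,
                                dropout_p = 0.1, seed = 1L) {
  if (is.unsorted(horizons_weeks)) stop("horizons must be ascending")
  structure(list(
    input_steps = as.integer(round(input_weeks * 7 * steps_per_day)),
    horizons_weeks = horizons_weeks,
    steps_per_day = steps_per_day,
    hidden_channels = hidden_channels,
    dropout_p = dropout_p,
    seed = seed,
    cell = convlstm_cell(1L, hidden_channels, grid = c(1L, 1L),
                         kernel = 1L, seed = seed),
    readout = NULL
  ), class = c("convlstm_forecaster", "health_forecaster"))
}

.convlstm_features <- function(model, series) {
  st <- convlstm_state(model$cell)
  Tn <- length(series)
  hs <- matrix(0, Tn, model$hidden_channels)
  for (t in seq_len(Tn)) {
    res <- convlstm_step(array(series[t], c(1L, 1L, 1L)), st, model$cell)
    st <- res$state
    hs[t, ] <- as.numeric(res$y)
  }
  hs[Tn, ]
}

## ---- metrics -------------------------------------------------------------

#' Forecast error metrics
#'
#' Standard mean absolute error, root mean squared error and coefficient
#' of determination. `mae(x, y) <= rmse(x, y)` always holds.
#'
#' @param pred,true numeric vectors of equal length.
#' @return Scalar metric value.
#' @export
mae <- function(pred, true) {
  if (length(pred) != length(true)) stop("length mismatch")
  mean(abs(pred - true))
}

#' @rdname mae
#' @export
rmse <- function(pred, true) {
  if (length(pred) != length(true)) stop("length mismatch")
  sqrt(mean((pred - true)^2))
}

#' @rdname mae
#' @export
r2 <- function(pred, true) {
  if (length(pred) != length(true)) stop("length mismatch")
  if (length(true) < 2L) stop("need at least two observations")
  ss_tot <- sum((true - mean(true))^2)
  if (ss_tot == 0) stop("r2 undefined for zero-variance truth")
  1 - sum((true - pred)^2) / ss_tot
}

#' Temporal smoothness
#'
#' Mean absolute first difference of a health series; 0 for a constant
#' trajectory, |s| for a linear ramp of slope `s` per step.
#'
#' @param x numeric vector or [health_trajectory()].
#' @return Nonnegative scalar.
#' @export
smoothness <- function(x) {
  s <- .traj_series(x)
  if (length(s) < 2L) stop("need at least two steps")
  mean(abs(diff(s)))
}

#' Gradient stability
#'
#' Variance ratio of temporal gradients, `var(diff(pred)) /
#' var(diff(true))`; values near one indicate the prediction fluctuates
#' like the truth (consistent with gradual degradation).
#'
#' @param pred,true numeric vectors of equal length (>= 3).
#' @return Nonnegative scalar.
#' @export
gradient_stability <- function(pred, true) {
  if (length(pred) != length(true)) stop("length mismatch")
  vt <- stats::var(diff(true))
  if (!is.finite(vt) || vt == 0) stop("zero-variance truth gradients")
  stats::var(diff(pred)) / vt
}

#' Horizon-specific forecast accuracy
#'
#' Fraction of predictions within the deployment error tolerance of the
#' horizon: +/-0.10 at 1 week, +/-0.15 at 2 weeks, +/-0.20 at 4 weeks.
#'
#' @param pred,true numeric vectors of equal length.
#' @param horizon_weeks 1, 2 or 4.
#' @return Fraction in \[0, 1\].
#' @export
horizon_accuracy <- function(pred, true, horizon_weeks) {
  tol <- switch(as.character(horizon_weeks),
                "1" = 0.10, "2" = 0.15, "4" = 0.20,
                stop("unknown horizon: ", horizon_weeks))
  if (length(pred) != length(true)) stop("length mismatch")
  mean(abs(pred - true) <= tol)
}

#' Fit an exponential decay to a health trajectory
#'
#' Least-squares fit of `h(t) = p + (h0 - p) * exp(-k * t)` with `t` in
#' hours relative to the first observation. Near-constant series return
#' `k = 0`, `p = h0 = mean`. Non-convergent fits fall back to a
#' Nelder-Mead search and are flagged via the `converged` field.
#'
#' @param traj a [health_trajectory()] (or numeric vector with unit-hour
#'   spacing) of at least 5 points.
#' @return List with `k` (per hour), `p`, `h0`, `converged` and `rss`.
#' @export
fit_decay <- function(traj) {
  if (inherits(traj, "health_trajectory")) {
    t_h <- traj$times - traj$times[1]
    h <- .traj_series(traj)
  } else {
    h <- as.numeric(traj)
    t_h <- seq_along(h) - 1
  }
  if (length(h) < 5L) stop("need at least 5 points")
  if (stats::sd(h) < 1e-9) {
    return(list(k = 0, p = mean(h), h0 = mean(h), converged = TRUE, rss = 0))
  }
  p0 <- min(h); h00 <- h[1]
  # crude rate guess from the time to cover half the gap
  gap <- h00 - p0
  idx <- which(h - p0 <= gap / 2)[1]
  k0 <- if (is.na(idx) || t_h[idx] == 0) 1 / max(t_h) else log(2) / t_h[idx]
  df <- data.frame(t = t_h, h = h)
  fit <- tryCatch(
    stats::nls(h ~ p + (h0 - p) * exp(-k * t), data = df,
               start = list(k = k0, p = p0, h0 = h00),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    return(list(k = unname(co["k"]), p = unname(co["p"]), h0 = unname(co["h0"]),
                converged = TRUE, rss = sum(stats::resid(fit)^2)))
  }
  obj <- function(par) sum((h - (par[2] + (par[3] - par[2]) * exp(-exp(par[1]) * t_h)))^2)
  op <- stats::optim(c(log(k0), p0, h00), obj, method = "Nelder-Mead",
                     control = list(maxit = 2000))
  list(k = exp(op$par[1]), p = op$par[2], h0 = op$par[3],
       converged = op$convergence == 0, rss = op$value)
}

## ---- operation counting --------------------------------------------------

#' Multiply-accumulate count estimate
#'
#' Closed-form per-sequence MAC estimates for the two temporal models,
#' used only for scaling properties (both are linear in `T`; the ConvLSTM
#' costs more at the default full-scale configurations).
#'
#' @param model_kind `"ssm"` or `"convlstm"`.
#' @param T_steps sequence length.
#' @param config optional list. For `"ssm"`: `latent_dim` (default 256),
#'   `d_in` (default 1). For `"convlstm"`: `hidden_channels` (64),
#'   `in_channels` (64), `kernel` (3), `grid` (`c(40, 40)`).
#' @return Estimated MAC count (numeric).
#' @export
operation_count <- function(model_kind, T_steps, config = list()) {
  if (T_steps < 0) stop("T must be nonnegative")
  if (model_kind == "ssm") {
    D <- config$latent_dim %||% 256
    d_in <- config$d_in %||% 1
    # per step: encode (D*d_in) + delta/decay/state/readout (~6 MACs/channel)
    T_steps * (D * d_in + 6 * D)
  } else if (model_kind == "convlstm") {
    hc <- config$hidden_channels %||% 64
    ic <- config$in_channels %||% 64
    k <- config$kernel %||% 3
    g <- config$grid %||% c(40, 40)
    T_steps * 4 * k^2 * (ic + hc) * hc * g[1] * g[2]
  } else stop("unknown model kind: ", model_kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
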