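test_that("encode_latent is a per-step map with the length contract", {
  enc <- latent_encoder(1, 6, seed = 2)
  for (Tn in c(1, 56, 672)) {
    Z <- encode_latent(runif(Tn), enc)
    expect_equal(dim(Z), c(Tn, 6))
  }
  # zero input, zero bias: zero latents
  enc0 <- latent_encoder(1, 6, seed = 2, bias = FALSE)
  expect_equal(max(abs(encode_latent(rep(0, 10), enc0))), 0)
  # permuting steps permutes outputs identically
  set.seed(4)
  x <- runif(20)
  p <- sample(20)
  expect_equal(encode_latent(x, enc)[p, ], encode_latent(x[p], enc))
  expect_error(encode_latent(numeric(0), enc), "empty")
})

test_that("selective_scan equals the naive sequential recurrence", {
  set.seed(31)
  for (i in 1:100) {
    Tn <- sample(4:256, 1)
    D <- sample(2:6, 1)
    params <- ssm_params(D, seed = 300 + i)
    X <- matrix(rnorm(Tn * D), Tn, D)
    expect_lt(max(abs(selective_scan(X, params) - oracle_scan(X, params))),
              1e-6)
  }
})

test_that("impulse response decays with the discretized rate", {
  params <- ssm_params(1, seed = 1)
  params$w_dt <- 0; params$b_dt <- 0.7; params$a <- 0.3
  params$b_in <- 1; params$c_out <- 1; params$skip <- 0
  Tn <- 40
  X <- matrix(c(1, rep(0, Tn - 1)), Tn, 1)
  y <- selective_scan(X, params)[, 1]
  abar <- exp(-log(1 + exp(0.7)) * 0.3)
  # after the impulse the output is a clean geometric decay
  expect_lt(max(abs(y[3:Tn] / y[2:(Tn - 1)] - abar)), 1e-8)
  expect_lt(max(abs(y - y[2] * abar^(seq_len(Tn) - 2))[-1]), 1e-8)
})

test_that("selective_scan is causal and rejects bad parameterizations", {
  params <- ssm_params(3, seed = 9)
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3)
  Y <- selective_scan(X, params)
  X2 <- X; X2[12, ] <- X2[12, ] + 1
  Y2 <- selective_scan(X2, params)
  expect_equal(Y2[1:11, ], Y[1:11, ])
  expect_gt(max(abs(Y2[12:20, ] - Y[12:20, ])), 0)
  # zero input, zero bias path
  p0 <- params; p0$b_dt <- rep(0, 3)
  expect_equal(max(abs(selective_scan(matrix(0, 5, 3), p0))), 0)
  expect_error(ssm_params(3, a_min = -1), "unstable")
  bad <- params; bad$a <- c(-0.1, 0.2, 0.3)
  expect_error(selective_scan(X, bad), "unstable")
})

test_that("forecast clamps to [0,1], needs history, and orders horizons", {
  spd <- 2
  m <- ssm_forecaster(input_weeks = 1, steps_per_day = spd, latent_dim = 4,
                      seed = 5)
  tr <- generate_trajectory(scenario_spec("stable", noise_sd = 0.02, seed = 3),
                            steps_per_day = spd)
  fc <- forecast(m, tr)      # untrained: persistence, still in [0, 1]
  expect_true(all(fc$predicted >= 0 & fc$predicted <= 1))
  expect_equal(fc$horizon_weeks, c(1, 2, 4))
  expect_true(all(fc$interval_low <= fc$mean & fc$mean <= fc$interval_high))
  short <- health_trajectory(seq(0, 24, by = 12), c(0.9, 0.9, 0.9))
  expect_error(forecast(m, short), "one-week minimum")
})

test_that("forecast_loss combines MSE with the spatial smoothness penalty", {
  truth <- matrix(0.5, 2, 2)
  expect_equal(forecast_loss(truth, truth, 1), 0)
  # exact checkerboard prediction: pure smoothness penalty, hand value 4
  cb <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(forecast_loss(cb, cb, smooth_weight = 1), 4)
  expect_equal(forecast_loss(cb, cb, smooth_weight = 0.25), 1)
  # off-by-epsilon constant prediction: eps^2 (no penalty on scalars)
  expect_equal(forecast_loss(rep(0.52, 5), rep(0.5, 5), 1), 0.02^2,
               tolerance = 1e-12)
  expect_error(forecast_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("curriculum horizon grows 1 -> 2 -> 4 and is monotone", {
  expect_equal(curriculum_horizon(0, 300), 1)
  expect_equal(curriculum_horizon(299, 300), 4)
  h <- vapply(0:299, curriculum_horizon, 0, total_epochs = 300)
  expect_true(all(diff(h) >= 0))
  expect_setequal(unique(h), c(1, 2, 4))
})

test_that("convlstm_step matches hand-rolled scalar gate arithmetic", {
  cell <- convlstm_cell(1, 1, grid = c(1, 1), kernel = 1, seed = 4)
  st <- convlstm_state(cell)
  x <- 0.37
  r <- convlstm_step(x, st, cell)
  sg <- function(v) 1 / (1 + exp(-v))
  wi <- cell$Wi[[1]][[1]][1, 1]; wf <- cell$Wf[[1]][[1]][1, 1]
  wo <- cell$Wo[[1]][[1]][1, 1]; wg <- cell$Wg[[1]][[1]][1, 1]
  i_ <- sg(wi * x + cell$bi); f_ <- sg(wf * x + cell$bf)
  o_ <- sg(wo * x + cell$bo); g_ <- tanh(wg * x + cell$bg)
  c_ <- f_ * 0 + i_ * g_
  expect_equal(as.numeric(r$y), o_ * tanh(c_), tolerance = 1e-12)
  expect_equal(as.numeric(r$state$c), c_, tolerance = 1e-12)
  # zero input, zero state, zero biases: zero output
  cell0 <- cell
  cell0$bi <- cell0$bf <- cell0$bo <- cell0$bg <- 0
  r0 <- convlstm_step(0, convlstm_state(cell0), cell0)
  expect_equal(as.numeric(r0$y), 0)
  expect_error(convlstm_step(array(0, c(2, 1, 1)), st, cell), "shape")
})

test_that("the general-grid ConvLSTM path agrees with the 1x1 fast path", {
  # 1x1 grid with kernel 3: fast path uses the center tap; force the
  # general path by faking a 2x2 grid of constant input and compare the
  # center behaviour qualitatively via the 1-channel gate equations
  cell <- convlstm_cell(1, 2, grid = c(3, 3), kernel = 3, seed = 11)
  st <- convlstm_state(cell)
  set.seed(2)
  x <- matrix(rnorm(9), 3, 3)
  r <- convlstm_step(x, st, cell)
  expect_equal(dim(r$y), c(2, 3, 3))
  expect_true(all(is.finite(r$y)))
  expect_true(all(abs(r$y) <= 1))     # |o * tanh(c)| <= 1
  # determinism given weights
  r2 <- convlstm_step(x, st, cell)
  expect_identical(r$y, r2$y)
})

test_that("error metrics follow their definitions", {
  x <- c(0.1, 0.5, 0.9, 0.4)
  expect_equal(mae(x, x), 0)
  expect_equal(rmse(x, x), 0)
  expect_equal(r2(x, x), 1)
  expect_equal(mae(x + 0.05, x), 0.05)
  expect_equal(rmse(x + 0.05, x), 0.05, tolerance = 1e-12)
  set.seed(6)
  p <- runif(30); t_ <- runif(30)
  expect_equal(mae(p, t_), sum(abs(p - t_)) / 30, tolerance = 1e-12)
  expect_equal(rmse(p, t_), sqrt(sum((p - t_)^2) / 30), tolerance = 1e-12)
  expect_equal(r2(p, t_), 1 - sum((t_ - p)^2) / sum((t_ - mean(t_))^2),
               tolerance = 1e-12)
  expect_lte(mae(p, t_), rmse(p, t_))
  expect_error(r2(p, rep(0.5, 30)), "zero-variance")
  expect_error(mae(1:3, 1:4), "mismatch")
})

test_that("smoothness and gradient stability follow their definitions", {
  expect_equal(smoothness(rep(0.4, 10)), 0)
  expect_equal(smoothness(seq(0, 1, length.out = 11)), 0.1, tolerance = 1e-12)
  set.seed(19)
  x <- runif(40)
  expect_equal(smoothness(x), mean(abs(diff(x))), tolerance = 1e-12)
  expect_equal(gradient_stability(x, x), 1)
  expect_equal(gradient_stability(x + 0.3, x), 1, tolerance = 1e-12)
  base <- sin(seq(0, 4, length.out = 50))
  expect_equal(gradient_stability(2 * base, base), 4, tolerance = 1e-12)
  expect_error(gradient_stability(x, rep(0.2, 40)), "zero-variance")
  expect_error(smoothness(0.5), "two steps")
})

test_that("horizon accuracy applies the deployment tolerances", {
  t_ <- rep(0.5, 10)
  expect_equal(horizon_accuracy(t_, t_, 1), 1)
  expect_equal(horizon_accuracy(t_ + 0.12, t_, 1), 0)    # tol 0.10
  expect_equal(horizon_accuracy(t_ + 0.12, t_, 2), 1)    # tol 0.15
  expect_equal(horizon_accuracy(t_ + 0.18, t_, 4), 1)    # tol 0.20
  expect_error(horizon_accuracy(t_, t_, 3), "unknown horizon")
})

test_that("fit_decay recovers generator parameters and handles edge cases", {
  tr <- generate_trajectory(scenario_spec("decay", noise_sd = 0),
                            steps_per_day = 24)
  fit <- fit_decay(tr)
  expect_true(fit$converged)
  expect_lt(abs(fit$k - tr$meta$k) / tr$meta$k, 1e-4)
  expect_lt(abs(fit$p - tr$meta$p) / tr$meta$p, 1e-4)
  expect_lt(abs(fit$h0 - tr$meta$h0) / tr$meta$h0, 1e-4)
  expect_lt(fit$rss, 1e-8)
  cst <- fit_decay(health_trajectory(0:9, rep(0.8, 10)))
  expect_equal(cst$k, 0)
  expect_equal(cst$p, 0.8)
  expect_error(fit_decay(c(0.9, 0.8, 0.7)), "at least 5")
})

test_that("mc_dropout_forecast is seeded, degenerate at p = 0, and widens with p", {
  spd <- 2
  trajs <- lapply(1:8, function(i)
    generate_trajectory(scenario_spec("decay", duration_weeks = 12,
                                      noise_sd = 0.02, seed = i),
                        steps_per_day = spd))
  m <- train_forecaster(ssm_forecaster(input_weeks = 4, steps_per_day = spd,
                                       latent_dim = 8, seed = 2), trajs)
  # evaluate on a window from the same regime the readout was fitted on
  full <- trajs[[1]]
  tr <- health_trajectory(full$times[1:m$input_steps],
                          full$health[1:m$input_steps])
  f0 <- mc_dropout_forecast(m, tr, passes = 10, p = 0, seed = 1)
  det <- forecast(m, tr)
  expect_equal(f0$predicted, det$predicted, tolerance = 1e-12)
  expect_equal(f0$std, rep(0, 3))
  f1 <- mc_dropout_forecast(m, tr, passes = 20, p = 0.1, seed = 9)
  f1b <- mc_dropout_forecast(m, tr, passes = 20, p = 0.1, seed = 9)
  expect_identical(f1, f1b)
  expect_true(all(f1$interval_high - f1$interval_low >= 0))
  # widths non-decreasing in p on average over seeds
  width <- function(p) mean(vapply(1:10, function(s) {
    f <- mc_dropout_forecast(m, tr, passes = 20, p = p, seed = s)
    mean(f$interval_high - f$interval_low)
  }, 0))
  w <- vapply(c(0, 0.1, 0.3), width, 0)
  expect_true(all(diff(w) > 0))
  expect_error(mc_dropout_forecast(m, tr, passes = 1), "two passes")
  expect_error(mc_dropout_forecast(m, tr, p = 1), "dropout p")
})

test_that("operation counts are linear in T with ConvLSTM above the scan", {
  expect_equal(operation_count("ssm", 0), 0)
  expect_equal(operation_count("convlstm", 0), 0)
  for (kind in c("ssm", "convlstm")) {
    c1 <- operation_count(kind, 336)
    c2 <- operation_count(kind, 672)
    expect_equal(c2, 2 * c1)
  }
  expect_gt(operation_count("convlstm", 672) / operation_count("ssm", 672), 1)
  expect_error(operation_count("transformer", 10), "unknown model kind")
})
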