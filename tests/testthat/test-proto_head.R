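test_that("supcon_loss matches closed forms and the brute-force oracle", {
  # four identical unit vectors, two per class: every ratio is 1/3
  E <- matrix(rep(c(1, 0, 0), each = 4), 4, 3)
  lab <- c("Healthy", "Healthy", "Dead", "Dead")
  expect_equal(supcon_loss(E, lab, tau = 0.37), log(3), tolerance = 1e-12)

  # two antipodal pairs, tau = 0.1, against the double-loop oracle
  E2 <- rbind(c(1, 0), c(1, 0), c(-1, 0), c(-1, 0))
  lab2 <- c("Healthy", "Healthy", "Bleached", "Bleached")
  expect_lt(abs(supcon_loss(E2, lab2, tau = 0.1) -
                  oracle_supcon(E2, lab2, 0.1)), 1e-10)

  # random seeded batches
  set.seed(77)
  for (i in 1:50) {
    N <- sample(c(8, 16, 32), 1)
    Z <- matrix(rnorm(N * 8), N, 8)
    lab <- sample(rep(health_classes()$name, length.out = N))
    expect_equal(supcon_loss(Z, lab, tau = 0.1),
                 oracle_supcon(Z, lab, 0.1), tolerance = 1e-6)
  }
})

test_that("supcon_loss is invariant under global rotations", {
  set.seed(13)
  Z <- matrix(rnorm(16 * 6), 16, 6)
  lab <- rep(health_classes()$name, each = 4)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  expect_lt(abs(supcon_loss(Z %*% Q, lab) - supcon_loss(Z, lab)), 1e-6)
})

test_that("supcon_loss enforces its preconditions", {
  Z <- matrix(rnorm(8), 4, 2)
  expect_error(supcon_loss(Z, c("Healthy", "Healthy", "Dead", "Bleached")),
               "positive")
  expect_error(supcon_loss(Z, rep("Healthy", 4), tau = 0), "tau")
  expect_error(supcon_loss(Z[1, , drop = FALSE], "Healthy"), "at least two")
})

test_that("prototype updates follow the momentum recursion", {
  b <- prototype_bank(2)
  b <- initialize_prototypes(b, diag(4) %*% matrix(rnorm(8), 4, 2),
                             health_classes()$name)
  b$mu["Healthy", ] <- c(1, 0)
  b2 <- update_prototypes(b, matrix(c(0, 1), 1, 2), "Healthy", m = 0.5)
  expect_equal(unname(b2$mu["Healthy", ]), c(0.5, 0.5))
  expect_equal(unname(b2$update_count["Healthy"]),
               unname(b$update_count["Healthy"]) + 1L)
  # absent classes untouched
  expect_equal(b2$mu["Dead", ], b$mu["Dead", ])
  expect_equal(b2$update_count["Dead"], b$update_count["Dead"])
  # m = 1 lands on the batch mean
  b3 <- update_prototypes(b, rbind(c(2, 2), c(4, 4)), rep("Healthy", 2), m = 1)
  expect_equal(unname(b3$mu["Healthy", ]), c(3, 3))
  expect_error(update_prototypes(b, matrix(0, 1, 2), "Healthy", m = 0),
               "momentum")
  expect_error(update_prototypes(b, matrix(0, 1, 2), "Algae"), "unknown")
})

test_that("prototypes converge geometrically to a stationary class mean", {
  b <- prototype_bank(3)
  b <- initialize_prototypes(b, rbind(c(5, 5, 5), c(1, 0, 0), c(0, 1, 0),
                                      c(0, 0, 1)), health_classes()$name)
  mu_star <- c(-1, 2, 0.5)
  m <- 0.3
  err0 <- sqrt(sum((b$mu["Healthy", ] - mu_star)^2))
  for (t in 1:12) {
    b <- update_prototypes(b, matrix(mu_star, 1), "Healthy", m = m)
    expect_equal(sqrt(sum((b$mu["Healthy", ] - mu_star)^2)),
                 err0 * (1 - m)^t, tolerance = 1e-10)
  }
})

test_that("classify returns nearest prototype with margin confidence", {
  b <- prototype_bank(2)
  b <- initialize_prototypes(
    b, rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)), health_classes()$name)
  # exact prototype hit: confidence 1
  r <- classify(c(1, 0), b)
  expect_equal(r$class, "Healthy")
  expect_equal(r$confidence, 1)
  # equidistant between Healthy and Sub-healthy: lower index wins, conf 0
  r2 <- classify(c(1, 1) / sqrt(2), b)
  expect_equal(r2$class, "Healthy")
  expect_equal(r2$index, 0)
  expect_equal(r2$confidence, 0, tolerance = 1e-12)
  # hand-computed margin for (0.8, 0.6)
  z <- c(0.8, 0.6)
  d1 <- sqrt(sum((z - c(1, 0))^2)); d2 <- sqrt(sum((z - c(0, 1))^2))
  r3 <- classify(z, b)
  expect_equal(r3$class, "Healthy")
  expect_equal(r3$confidence, (d2 - d1) / (d2 + d1), tolerance = 1e-12)
  # uninitialized bank errors
  expect_error(classify(c(1, 0), prototype_bank(2)), "initialized")
})

test_that("detection_loss is the stated weighted sum", {
  expect_equal(detection_loss(1, 1, 1), 2.0)
  expect_equal(detection_loss(0, 0, 0), 0)
  expect_equal(detection_loss(2, 0.5, 1), 2.85)
  expect_error(loss_weights(lambda2 = -0.1), "nonnegative")
  expect_error(detection_loss(Inf, 0, 0), "finite")
})

test_that("expected_calibration_error reproduces hand-computed binnings", {
  expect_equal(expected_calibration_error(rep(1, 10), rep(TRUE, 10)), 0)
  expect_equal(expected_calibration_error(rep(1, 10),
                                          rep(c(TRUE, FALSE), 5)), 0.5)
  # 2-bin hand case: bin (0,.5]: conf .2 .4 .4, acc 2/3; bin (.5,1]: conf
  # .9 .8 .6 .7 .9 .95 .85, acc 5/7
  conf <- c(0.2, 0.4, 0.4, 0.9, 0.8, 0.6, 0.7, 0.9, 0.95, 0.85)
  corr <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  lo <- abs(2 / 3 - mean(c(.2, .4, .4)))
  hi <- abs(5 / 7 - mean(c(.9, .8, .6, .7, .9, .95, .85)))
  expect_equal(expected_calibration_error(conf, corr, 2),
               0.3 * lo + 0.7 * hi, tolerance = 1e-12)
  expect_error(expected_calibration_error(c(0.5), c(TRUE, FALSE)), "mismatch")
})

test_that("silhouette_score matches closed forms and the O(N^2) oracle", {
  # duplicated points per class: a = 0, score 1
  X <- rbind(c(0, 0), c(0, 0), c(3, 0), c(3, 0))
  lab <- c("Healthy", "Healthy", "Dead", "Dead")
  expect_equal(silhouette_score(X, lab), 1)
  # all identical: convention 0
  expect_equal(silhouette_score(matrix(1, 4, 2), lab), 0)
  expect_error(silhouette_score(X, rep("Healthy", 4)), "single class")
  set.seed(101)
  for (i in 1:5) {
    b <- make_blobs(seed = 200 + i, n_per = 8, d = 4)
    expect_equal(silhouette_score(b$X, b$y),
                 oracle_silhouette(b$X, b$y), tolerance = 1e-8)
  }
})

test_that("centroid_distances is symmetric with zero diagonal", {
  X <- rbind(c(1, 0), c(1, 0), c(-1, 0), c(-1, 0))
  lab <- c("Healthy", "Healthy", "Dead", "Dead")
  d <- centroid_distances(X, lab)
  expect_equal(unname(d["Healthy", "Dead"]), 2)
  expect_equal(diag(d), c(Healthy = 0, Dead = 0))
  b <- make_blobs(seed = 7, n_per = 6, d = 3)
  d2 <- centroid_distances(b$X, b$y)
  expect_equal(d2, t(d2))
  # direct mean-then-distance check for one pair
  mu_h <- colMeans(b$X[b$y == "Healthy", ])
  mu_b <- colMeans(b$X[b$y == "Bleached", ])
  expect_equal(unname(d2["Healthy", "Bleached"]),
               sqrt(sum((mu_h - mu_b)^2)), tolerance = 1e-12)
})
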