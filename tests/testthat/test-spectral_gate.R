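test_that("decompose matches the convolution oracle and conserves energy", {
  set.seed(11)
  x <- array(rnorm(3 * 32 * 32), c(3, 32, 32))
  sub <- decompose(feature_map(x), "db4", 2)
  # level 1 against the independent loop-based filter bank, per channel
  for (ch in 1:3) {
    o <- oracle_dwt2(x[ch, , ], oracle_db4_lo)
    for (nm in c("LL", "LH", "HL", "HH"))
      expect_lt(max(abs(sub$levels[[1]][[nm]][ch, , ] - o[[nm]])), 1e-8)
    # level 2 = oracle applied to the oracle's own LL
    o2 <- oracle_dwt2(o$LL, oracle_db4_lo)
    for (nm in c("LL", "LH", "HL", "HH"))
      expect_lt(max(abs(sub$levels[[2]][[nm]][ch, , ] - o2[[nm]])), 1e-8)
  }
  expect_equal(subband_total_energy(sub), sum(x^2), tolerance = 1e-10)
})

test_that("constant maps put all energy in LL; checkerboards in HH", {
  cm <- decompose(matrix(3.7, 16, 16), "db4", 2)
  for (l in 1:2) for (nm in c("LH", "HL", "HH"))
    expect_lt(max(abs(cm$levels[[l]][[nm]])), 1e-10)
  expect_equal(subband_energy_fraction(cm, "LL", 2), 1, tolerance = 1e-12)
  expect_equal(subband_energy_fraction(cm, "HH", 1), 0, tolerance = 1e-12)

  cb <- outer(1:16, 1:16, function(i, j) (-1)^(i + j))
  sub <- decompose(cb, "db4", 2)
  hh <- subband_energy_fraction(sub, "HH", 1)
  ll <- subband_energy_fraction(sub, "LL", 1)
  # cross-checked against the oracle decomposition
  o <- oracle_dwt2(cb, oracle_db4_lo)
  tot <- sum(unlist(lapply(o, function(m) sum(m^2))))
  expect_equal(hh, sum(o$HH^2) / tot, tolerance = 1e-10)
  expect_gt(hh, ll)
})

test_that("energy fractions over a level's four bands sum to one", {
  set.seed(5)
  sub <- decompose(matrix(runif(24 * 40), 24, 40), "db2", 2)
  for (l in 1:2) {
    tot <- sum(vapply(c("LL", "LH", "HL", "HH"),
                      function(b) subband_energy_fraction(sub, b, l), 0))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
  expect_error(subband_energy_fraction(sub, "XX", 1), "unknown band")
  expect_error(subband_energy_fraction(sub, "LL", 5), "unknown level")
})

test_that("perfect reconstruction holds across shapes, bases and seeds", {
  set.seed(42)
  for (i in 1:100) {
    nr <- sample(16:40, 1); nc <- sample(16:40, 1)
    basis <- sample(c("db4", "db2", "haar"), 1)
    x <- matrix(rnorm(nr * nc), nr, nc)
    rec <- reconstruct(decompose(x, basis, sample(1:2, 1)))$values[1, , ]
    expect_lt(max(abs(rec - x)), 1e-5 * max(abs(x)))
  }
})

test_that("decompose rejects bad input", {
  expect_error(decompose(matrix(1, 16, 16), "nosuchwavelet"), "unsupported")
  expect_error(decompose(matrix(1, 8, 8), "db4", 4), "too small")
  expect_error(feature_map(matrix(1, 4, 4)), "at least 8x8")
  expect_error(feature_map(matrix(c(NA, 1), 8, 8)), "finite")
})

test_that("soft_gate applies the elementwise factors of the gating equations", {
  HH <- matrix(c(1, 2, -1, 0), 2, 2)
  z <- matrix(0, 2, 2)
  sub <- make_subband(z, z, z, HH)
  gp <- gate_params(levels = 1, channels = 1, alpha = 0, beta = 0.5,
                    gamma = 0, delta = 0)
  out <- soft_gate(sub, gp)
  sig <- 1 / (1 + exp(-HH))
  expect_equal(out$levels[[1]]$HH[1, , ], HH * (1 - 0.5 * sig),
               tolerance = 1e-12)
  # enhancement side: LH scaled by 1 + gamma * sigmoid
  LH <- matrix(c(0.5, -2, 3, 1), 2, 2)
  sub2 <- make_subband(z, LH, z, z)
  gp2 <- gate_params(levels = 1, channels = 1, alpha = 0, beta = 0,
                     gamma = 0.8, delta = 0)
  out2 <- soft_gate(sub2, gp2)
  expect_equal(out2$levels[[1]]$LH[1, , ],
               LH * (1 + 0.8 / (1 + exp(-LH))), tolerance = 1e-12)
})

test_that("zero gates are the identity and saturated gates hit their bound", {
  set.seed(3)
  x <- matrix(rnorm(32 * 32), 32, 32)
  gp0 <- gate_params(2, 1, alpha = 0, beta = 0, gamma = 0, delta = 0)
  expect_lt(max(abs(wio_filter(x, gp0)$values[1, , ] - x)), 1e-6)

  # saturating logits: W = big weight drives sigmoid to 1 where coef > 0
  HH <- matrix(abs(rnorm(4)) + 0.5, 2, 2)
  z <- matrix(0, 2, 2)
  sub <- make_subband(z, z, z, HH)
  gp <- gate_params(1, 1, alpha = 0, beta = 0.7, gamma = 0, delta = 0,
                    weights = list(list(LL = matrix(1e4), LH = matrix(1e4),
                                        HL = matrix(1e4), HH = matrix(1e4))))
  out <- soft_gate(sub, gp)
  expect_equal(out$levels[[1]]$HH[1, , ], HH * 0.3, tolerance = 1e-6)
})

test_that("gate parameters are clamped, validated, and respect shapes", {
  gp <- gate_params(2, 1, alpha = 1.7, beta = -0.4)
  expect_equal(gp$alpha, c(1, 1))
  expect_equal(gp$beta, c(0, 0))
  expect_error(gate_params(2, 1, alpha = NaN), "non-finite")
  sub <- decompose(matrix(1, 16, 16), "db4", 2)
  expect_error(soft_gate(sub, gate_params(1, 1)), "level")
  expect_error(soft_gate(sub, gate_params(2, 3)), "channels")
})

test_that("increasing beta never increases HH magnitudes (monotone suppression)", {
  set.seed(8)
  for (i in 1:10) {
    x <- matrix(rnorm(16 * 16), 16, 16)
    sub <- decompose(x, "db4", 2)
    betas <- sort(runif(3))
    prev <- NULL
    for (b in betas) {
      out <- soft_gate(sub, gate_params(2, 1, alpha = 0, beta = b,
                                        gamma = 0, delta = 0))
      mag <- abs(c(out$levels[[1]]$HH, out$levels[[2]]$HH))
      if (!is.null(prev)) expect_true(all(mag <= prev + 1e-12))
      prev <- mag
    }
  }
})

test_that("suppressive-only gating never increases total coefficient energy", {
  set.seed(9)
  for (i in 1:10) {
    sub <- decompose(matrix(rnorm(24 * 24), 24, 24), "db4", 2)
    out <- soft_gate(sub, gate_params(2, 1, alpha = 0, beta = runif(1),
                                      gamma = 0, delta = runif(1)))
    expect_lte(subband_total_energy(out), subband_total_energy(sub) + 1e-12)
  }
})

test_that("zeroing the finest HH of a noisy image moves it toward the clean one", {
  set.seed(14)
  clean <- outer(seq(0, 1, length.out = 32), seq(1, 0, length.out = 32))
  noise <- matrix(rnorm(32 * 32), 32, 32)
  noise <- noise - coralspectra:::.box_blur3(noise)   # high-frequency
  noisy <- clean + 0.1 * noise
  sub <- decompose(noisy, "db4", 2)
  sub$levels[[1]]$HH[] <- 0
  rec <- reconstruct(sub)$values[1, , ]
  expect_lt(mean((rec - clean)^2), mean((noisy - clean)^2))
})

test_that("wio_filter is not linear once gates engage", {
  set.seed(21)
  x <- matrix(rnorm(16 * 16), 16, 16)
  gp <- gate_params(2, 1)       # defaults alpha 0.5, beta 0.7
  f1 <- wio_filter(x, gp)$values
  f2 <- wio_filter(2 * x, gp)$values
  expect_gt(max(abs(f2 - 2 * f1)), 1e-4)
})

test_that("multi-channel gating mixes channels through the 1x1 blocks", {
  set.seed(30)
  x <- array(rnorm(2 * 16 * 16), c(2, 16, 16))
  W <- matrix(c(0, 5, 5, 0), 2, 2)     # logits come from the other channel
  gp <- gate_params(1, 2, alpha = 0, beta = 1, gamma = 0, delta = 0,
                    weights = list(list(LL = W, LH = W, HL = W, HH = W)))
  sub <- decompose(feature_map(x), "db4", 1)
  out <- soft_gate(sub, gp)
  hh <- sub$levels[[1]]$HH
  logits_ch1 <- 5 * hh[2, , ]
  expect_equal(out$levels[[1]]$HH[1, , ],
               hh[1, , ] * (1 - 1 / (1 + exp(-logits_ch1))),
               tolerance = 1e-10)
})
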