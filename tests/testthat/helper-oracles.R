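# Independent brute-force oracles. These deliberately use explicit loops
# and definitions written from scratch, separate from the package's
# vectorized implementations.

# Daubechies-4 low-pass taps (same published constants, independent code path)
oracle_db4_lo <- c(-0.010597401784997278, 0.032883011666982945,
                   0.030841381835986965, -0.18703481171888114,
                   -0.02798376941698385, 0.6308807679295904,
                   0.7148465705525415, 0.23037781330885523)
oracle_hi <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

# periodized 1-D analysis by direct convolution loops
oracle_dwt1 <- function(x, h) {
  n <- length(x)
  g <- oracle_hi(h)
  half <- n %/% 2
  a <- d <- numeric(half)
  for (k in seq_len(half)) {
    for (m in seq_along(h)) {
      idx <- ((2 * (k - 1) + m - 1) %% n) + 1
      a[k] <- a[k] + h[m] * x[idx]
      d[k] <- d[k] + g[m] * x[idx]
    }
  }
  list(a = a, d = d)
}

# separable 2-D single-level DWT by looping rows then columns
oracle_dwt2 <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  rowt <- matrix(0, nr, nc)           # transform along columns of each row? no:
  # transform each column (length nr), stacking [approx; detail]
  for (j in seq_len(nc)) {
    r <- oracle_dwt1(m[, j], h)
    rowt[, j] <- c(r$a, r$d)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    r <- oracle_dwt1(rowt[i, ], h)
    out[i, ] <- c(r$a, r$d)
  }
  hr <- nr %/% 2; hc <- nc %/% 2
  list(LL = out[1:hr, 1:hc], LH = out[1:hr, hc + 1:hc],
       HL = out[hr + 1:hr, 1:hc], HH = out[hr + 1:hr, hc + 1:hc])
}

# supervised contrastive loss by an explicit double loop
oracle_supcon <- function(Z, labels, tau) {
  Z <- Z / sqrt(rowSums(Z^2))
  N <- nrow(Z)
  total <- 0
  for (i in seq_len(N)) {
    pos <- setdiff(which(labels == labels[i]), i)
    stopifnot(length(pos) > 0)
    denom <- 0
    for (a in setdiff(seq_len(N), i))
      denom <- denom + exp(sum(Z[i, ] * Z[a, ]) / tau)
    li <- 0
    for (p in pos)
      li <- li - log(exp(sum(Z[i, ] * Z[p, ]) / tau) / denom)
    total <- total + li / length(pos)
  }
  total / N
}

# silhouette by explicit loops over samples and classes
oracle_silhouette <- function(X, labels) {
  N <- nrow(X)
  dmat <- matrix(0, N, N)
  for (i in 1:N) for (j in 1:N)
    dmat[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(N)
  for (i in 1:N) {
    own <- which(labels == labels[i] & seq_len(N) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(dmat[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(dmat[i, labels == cl]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# naive sequential state-space recurrence, channel by channel
oracle_scan <- function(X, params) {
  Tn <- nrow(X); D <- ncol(X)
  Y <- matrix(0, Tn, D)
  for (d in seq_len(D)) {
    h <- 0
    for (t in seq_len(Tn)) {
      x <- X[t, d]
      delta <- log(1 + exp(params$w_dt[d] * x + params$b_dt[d]))
      ab <- exp(-delta * params$a[d])
      bb <- (1 - ab) / params$a[d] * params$b_in[d]
      h <- ab * h + bb * x
      Y[t, d] <- params$c_out[d] * h + params$skip[d] * x
    }
  }
  Y
}

# average precision by independent PR bookkeeping (naive, <= few boxes)
oracle_ap_class <- function(det_conf, det_tp, n_gt) {
  ord <- order(-det_conf)
  tp_flags <- det_tp[ord]
  recalls <- precisions <- numeric(length(tp_flags))
  tp <- fp <- 0
  for (i in seq_along(tp_flags)) {
    if (tp_flags[i]) tp <- tp + 1 else fp <- fp + 1
    recalls[i] <- tp / n_gt
    precisions[i] <- tp / (tp + fp)
  }
  area <- 0
  r_prev <- 0
  for (i in seq_along(recalls)) {
    p_max <- max(precisions[i:length(precisions)])
    area <- area + (recalls[i] - r_prev) * p_max
    r_prev <- recalls[i]
  }
  area
}

# seeded Gaussian blobs for the four classes
make_blobs <- function(seed, n_per = 12, d = 8, sd = 0.6, center_sd = 2) {
  cls <- health_classes()$name
  set.seed(seed)
  centers <- matrix(rnorm(4 * d, sd = center_sd), 4, d)
  X <- do.call(rbind, lapply(1:4, function(c_)
    matrix(rnorm(n_per * d, sd = sd), n_per, d) +
      matrix(centers[c_, ], n_per, d, byrow = TRUE)))
  list(X = X, y = rep(cls, each = n_per))
}

# hand-made single-level subband_set wrapper for gating tests
make_subband <- function(LL, LH, HL, HH, basis = "db4") {
  as3 <- function(m) array(m, c(1L, nrow(m), ncol(m)))
  structure(list(
    levels = list(list(LL = as3(LL), LH = as3(LH), HL = as3(HL),
                       HH = as3(HH), pre_shape = 2L * dim(LL))),
    basis_name = basis, original_shape = 2L * dim(LL), n_channels = 1L,
    level_id = "test"), class = "subband_set")
}
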