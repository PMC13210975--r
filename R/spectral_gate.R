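# Wavelet decomposition, learnable soft gating of sub-bands, and inverse
# reconstruction: the spectral-filtering neck that separates structure-
# dominated low-frequency coral morphology from turbidity-induced
# high-frequency noise in feature maps.

## ---- wavelet filter bank -------------------------------------------------

# Orthonormal Daubechies scaling filters (decomposition low-pass taps).
# The high-pass is the quadrature mirror g[m] = (-1)^m h[L-1-m].
.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db1  = c(0.7071067811865476, 0.7071067811865476),
  db2  = c(-0.12940952255092145, 0.22414386804185735,
           0.836516303737469, 0.48296291314469025),
  db4  = c(-0.010597401784997278, 0.032883011666982945,
           0.030841381835986965, -0.18703481171888114,
           -0.02798376941698385, 0.6308807679295904,
           0.7148465705525415, 0.23037781330885523)
)

.get_filter <- function(basis) {
  h <- .wavelet_filters[[tolower(basis)]]
  if (is.null(h)) {
    stop("unsupported wavelet basis '", basis, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "))
  }
  g <- rev(h) * rep_len(c(1, -1), length(h))
  list(lo = h, hi = g)
}

# Periodized analysis matrix for an even signal length n: the first n/2 rows
# are even circular shifts of the low-pass filter, the last n/2 of the
# high-pass. Rows are orthonormal, so the inverse is the transpose and both
# energy conservation and perfect reconstruction hold to machine precision.
.dwt_matrix <- function(n, basis) {
  if (n %% 2L != 0L) stop("internal: .dwt_matrix needs even length")
  f <- .get_filter(basis)
  L <- length(f$lo)
  W <- matrix(0, n, n)
  half <- n %/% 2L
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
    for (m in seq_len(L)) {
      W[k, idx[m]] <- W[k, idx[m]] + f$lo[m]
      W[half + k, idx[m]] <- W[half + k, idx[m]] + f$hi[m]
    }
  }
  W
}

# cache transform matrices: (n, basis) pairs recur constantly
.dwt_cache <- new.env(parent = emptyenv())
.dwt_matrix_cached <- function(n, basis) {
  key <- paste0(basis, "_", n)
  W <- .dwt_cache[[key]]
  if (is.null(W)) {
    W <- .dwt_matrix(n, basis)
    .dwt_cache[[key]] <- W
  }
  W
}

## ---- feature maps --------------------------------------------------------

#' Feature map container
#'
#' Wraps a real-valued `channels x height x width` array, the unit on which
#' the spectral filter operates. A plain matrix is treated as a single
#' channel.
#'
#' @param values numeric array `[C, H, W]` (or an `H x W` matrix).
#' @param level_id pyramid-level tag, e.g. `"P3"`..`"P7"` or `"image"`.
#' @return An object of class `feature_map`.
#' @export
feature_map <- function(values, level_id = "image") {
  if (is.matrix(values)) values <- array(values, c(1L, nrow(values), ncol(values)))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a [channels x height x width] array")
  if (!all(is.finite(values))) stop("feature map values must be finite")
  d <- dim(values)
  if (d[2] < 8L || d[3] < 8L)
    stop("feature map must be at least 8x8 (got ", d[2], "x", d[3], ")")
  structure(list(values = values, level_id = level_id), class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_map %s: %d channel(s), %d x %d>\n",
              x$level_id, d[1], d[2], d[3]))
  invisible(x)
}

.as_fm_values <- function(fm) {
  if (inherits(fm, "feature_map")) return(fm$values)
  if (is.matrix(fm)) return(array(fm, c(1L, nrow(fm), ncol(fm))))
  if (is.array(fm) && length(dim(fm)) == 3L) return(fm)
  stop("expected a feature_map, matrix or 3-d array")
}

## ---- decomposition -------------------------------------------------------

# pad a matrix to even dims by replicating the last row/column
.pad_even <- function(m) {
  if (nrow(m) %% 2L == 1L) m <- rbind(m, m[nrow(m), , drop = FALSE])
  if (ncol(m) %% 2L == 1L) m <- cbind(m, m[, ncol(m), drop = FALSE])
  m
}

# single-level 2-D periodized DWT of one matrix -> list(LL, LH, HL, HH)
.dwt2_once <- function(m, basis) {
  Wr <- .dwt_matrix_cached(nrow(m), basis)   # acts on columns (rows of image)
  Wc <- .dwt_matrix_cached(ncol(m), basis)
  C <- Wr %*% m %*% t(Wc)
  hr <- nrow(m) %/% 2L
  hc <- ncol(m) %/% 2L
  list(LL = C[seq_len(hr), seq_len(hc), drop = FALSE],
       LH = C[seq_len(hr), hc + seq_len(hc), drop = FALSE],
       HL = C[hr + seq_len(hr), seq_len(hc), drop = FALSE],
       HH = C[hr + seq_len(hr), hc + seq_len(hc), drop = FALSE])
}

.idwt2_once <- function(LL, LH, HL, HH, basis, out_shape) {
  C <- rbind(cbind(LL, LH), cbind(HL, HH))
  Wr <- .dwt_matrix_cached(nrow(C), basis)
  Wc <- .dwt_matrix_cached(ncol(C), basis)
  m <- t(Wr) %*% C %*% Wc
  m[seq_len(out_shape[1]), seq_len(out_shape[2]), drop = FALSE]
}

#' Multi-level wavelet decomposition of a feature map
#'
#' Performs a separable 2-D discrete wavelet transform per channel, with
#' periodized (circular) boundary handling so the transform is exactly
#' orthonormal: coefficient energy equals input energy and reconstruction is
#' exact to machine precision. Odd dimensions are edge-replicated to even
#' before each level and cropped on the inverse. Every level records all
#' four sub-band grids (`LL`, `LH`, `HL`, `HH`); the `LL` of a non-final
#' level is the input to the next level and is kept for diagnostics.
#'
#' @param fm a [feature_map()] (or matrix / 3-d array).
#' @param basis wavelet name: `"db4"` (default), `"db2"`, `"haar"`/`"db1"`.
#' @param levels decomposition depth, a positive integer (default 2).
#' @return An object of class `subband_set`.
#' @seealso [reconstruct()], [soft_gate()], [subband_energy_fraction()]
#' @export
decompose <- function(fm, basis = "db4", levels = 2L) {
  v <- .as_fm_values(fm)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  f <- .get_filter(basis)  # validates basis
  d <- dim(v)
  min_len <- length(f$lo)
  # each level halves the grid; require every level to be at least as wide
  # as the filter so periodization stays meaningful
  sz <- c(d[2], d[3])
  for (l in seq_len(levels)) {
    sz <- ceiling(sz / 2)
    if (any(sz < max(2L, min_len %/% 2L)))
      stop("grid ", d[2], "x", d[3], " too small for a ", levels,
           "-level '", basis, "' decomposition")
  }
  out_levels <- vector("list", levels)
  cur <- lapply(seq_len(d[1]), function(ch) v[ch, , ])
  for (l in seq_len(levels)) {
    pre_shape <- dim(if (is.matrix(cur[[1]])) cur[[1]] else as.matrix(cur[[1]]))
    bands <- lapply(cur, function(m) .dwt2_once(.pad_even(as.matrix(m)), basis))
    stack <- function(name) {
      b1 <- bands[[1]][[name]]
      a <- array(0, c(d[1], nrow(b1), ncol(b1)))
      for (ch in seq_len(d[1])) a[ch, , ] <- bands[[ch]][[name]]
      a
    }
    out_levels[[l]] <- list(LL = stack("LL"), LH = stack("LH"),
                            HL = stack("HL"), HH = stack("HH"),
                            pre_shape = pre_shape)
    cur <- lapply(bands, `[[`, "LL")
  }
  structure(list(levels = out_levels, basis_name = basis,
                 original_shape = c(d[2], d[3]), n_channels = d[1],
                 level_id = if (inherits(fm, "feature_map")) fm$level_id else "image"),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set: %d level(s), basis %s, %d channel(s), original %d x %d>\n",
              length(x$levels), x$basis_name, x$n_channels,
              x$original_shape[1], x$original_shape[2]))
  invisible(x)
}

#' Inverse wavelet reconstruction
#'
#' Rebuilds the feature map from a [decompose()]d (optionally
#' [soft_gate()]d) sub-band set. Only the deepest `LL` enters the inverse
#' transform; shallower `LL` grids are diagnostic records of the forward
#' pass. Output is cropped to the recorded original shape.
#'
#' @param sub a `subband_set`.
#' @return A [feature_map()] with the original shape.
#' @export
reconstruct <- function(sub) {
  stopifnot(inherits(sub, "subband_set"))
  nl <- length(sub$levels)
  nc <- sub$n_channels
  for (l in seq_len(nl)) {
    lv <- sub$levels[[l]]
    ref <- dim(lv$LL)
    for (nm in c("LH", "HL", "HH"))
      if (!identical(dim(lv[[nm]]), ref))
        stop("inconsistent sub-band shapes at level ", l)
  }
  cur <- lapply(seq_len(nc), function(ch) sub$levels[[nl]]$LL[ch, , ])
  for (l in rev(seq_len(nl))) {
    lv <- sub$levels[[l]]
    cur <- lapply(seq_len(nc), function(ch) {
      .idwt2_once(as.matrix(cur[[ch]]), lv$LH[ch, , ], lv$HL[ch, , ],
                  lv$HH[ch, , ], sub$basis_name, lv$pre_shape)
    })
  }
  out <- array(0, c(nc, sub$original_shape[1], sub$original_shape[2]))
  for (ch in seq_len(nc)) {
    m <- cur[[ch]]
    out[ch, , ] <- m[seq_len(sub$original_shape[1]),
                     seq_len(sub$original_shape[2])]
  }
  feature_map(out, level_id = sub$level_id)
}

## ---- gating --------------------------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Soft-gate parameters
#'
#' Per-level scalar gains `alpha` (LL enhancement), `beta` (HH suppression),
#' `gamma` (LH enhancement) and `delta` (HL suppression), each clamped to
#' \[0, 1\], plus one `channels x channels` 1x1 mixing weight block per band
#' per level feeding the sigmoid gate logits. Defaults follow the
#' best-performing gate setting (`alpha = 0.5`, `beta = 0.7`); `gamma` and
#' `delta` default to `alpha` and `beta` since enhancement bands (LL, LH)
#' and suppression bands (HL, HH) are paired.
#'
#' @param levels number of decomposition levels.
#' @param channels number of feature channels.
#' @param alpha,beta,gamma,delta scalars or length-`levels` vectors in
#'   \[0, 1\]; values outside are clamped.
#' @param weights optional list (length `levels`) of lists with elements
#'   `LL`, `LH`, `HL`, `HH`, each a `channels x channels` matrix. Default:
#'   identity mixing.
#' @return An object of class `gate_params`.
#' @export
gate_params <- function(levels = 2L, channels = 1L,
                        alpha = 0.5, beta = 0.7,
                        gamma = alpha, delta = beta,
                        weights = NULL) {
  levels <- as.integer(levels)
  expand <- function(x, nm) {
    if (!all(is.finite(x))) stop("non-finite gate parameter ", nm)
    x <- rep_len(x, levels)
    pmin(pmax(x, 0), 1)
  }
  if (is.null(weights)) {
    weights <- replicate(levels, {
      I <- diag(1, channels)
      list(LL = I, LH = I, HL = I, HH = I)
    }, simplify = FALSE)
  }
  if (length(weights) != levels) stop("need one weight block set per level")
  for (lv in weights) for (nm in c("LL", "LH", "HL", "HH")) {
    Wb <- lv[[nm]]
    if (!is.matrix(Wb) || nrow(Wb) != channels || ncol(Wb) != channels)
      stop("weight block ", nm, " must be a ", channels, "x", channels, " matrix")
    if (!all(is.finite(Wb))) stop("non-finite weights in band ", nm)
  }
  structure(list(alpha = expand(alpha, "alpha"), beta = expand(beta, "beta"),
                 gamma = expand(gamma, "gamma"), delta = expand(delta, "delta"),
                 weights = weights, levels = levels, channels = channels),
            class = "gate_params")
}

# apply the 1x1 channel-mixing block to a [C,h,w] band -> gate logits [C,h,w]
.mix_channels <- function(band, Wb) {
  d <- dim(band)
  flat <- matrix(band, d[1], d[2] * d[3])   # channels x pixels
  array(Wb %*% flat, d)
}

#' Soft-gate wavelet sub-bands
#'
#' Applies the learnable multiplicative gates: enhancement bands are scaled
#' by `1 + gain * sigmoid(W * band)` (LL with `alpha`, LH with `gamma`),
#' suppression bands by `1 - gain * sigmoid(W * band)` (HH with `beta`, HL
#' with `delta`). Gate logits come from a 1x1 channel-mixing block per band
#' per level, so the factor is per-channel, per-element. The LL gate acts at
#' the deepest level only, since only that grid enters [reconstruct()].
#'
#' @param sub a `subband_set` from [decompose()].
#' @param params a [gate_params()] with matching levels and channels.
#' @return A gated `subband_set` with identical shapes.
#' @export
soft_gate <- function(sub, params) {
  stopifnot(inherits(sub, "subband_set"), inherits(params, "gate_params"))
  nl <- length(sub$levels)
  if (params$levels != nl)
    stop("gate_params has ", params$levels, " level(s), sub-band set has ", nl)
  if (params$channels != sub$n_channels)
    stop("gate_params channels (", params$channels,
         ") do not match sub-band channels (", sub$n_channels, ")")
  out <- sub
  for (l in seq_len(nl)) {
    lv <- sub$levels[[l]]
    Wl <- params$weights[[l]]
    gate_up <- function(band, gain, Wb)
      band * (1 + gain * .sigmoid(.mix_channels(band, Wb)))
    gate_dn <- function(band, gain, Wb)
      band * (1 - gain * .sigmoid(.mix_channels(band, Wb)))
    if (l == nl)
      out$levels[[l]]$LL <- gate_up(lv$LL, params$alpha[l], Wl$LL)
    out$levels[[l]]$LH <- gate_up(lv$LH, params$gamma[l], Wl$LH)
    out$levels[[l]]$HL <- gate_dn(lv$HL, params$delta[l], Wl$HL)
    out$levels[[l]]$HH <- gate_dn(lv$HH, params$beta[l], Wl$HH)
  }
  out
}

#' Wavelet soft-gated spectral filter
#'
#' Composition [decompose()] -> [soft_gate()] -> [reconstruct()]: the
#' content-aware spectral denoiser. With all gains zero it is the identity.
#'
#' @inheritParams decompose
#' @param params a [gate_params()]; defaults to the package defaults for
#'   the input's channel count.
#' @return A filtered [feature_map()] of the same shape.
#' @export
wio_filter <- function(fm, params = NULL, basis = "db4", levels = 2L) {
  v <- .as_fm_values(fm)
  if (is.null(params)) params <- gate_params(levels = levels, channels = dim(v)[1])
  reconstruct(soft_gate(decompose(fm, basis = basis, levels = levels), params))
}

## ---- diagnostics ---------------------------------------------------------

#' Sub-band energy fraction
#'
#' Fraction of a level's coefficient energy (sum of squares over the four
#' sub-bands of that level) held by one band. Fractions over `LL`, `LH`,
#' `HL`, `HH` at a level sum to one. Rising `HH` fractions at the finest
#' level are the spectral signature of turbidity.
#'
#' @param sub a `subband_set`.
#' @param band one of `"LL"`, `"LH"`, `"HL"`, `"HH"`.
#' @param level level index (1 = finest).
#' @return A fraction in \[0, 1\].
#' @export
subband_energy_fraction <- function(sub, band, level = 1L) {
  stopifnot(inherits(sub, "subband_set"))
  level <- as.integer(level)
  if (level < 1L || level > length(sub$levels))
    stop("unknown level ", level, "; set has ", length(sub$levels))
  if (!band %in% c("LL", "LH", "HL", "HH")) stop("unknown band '", band, "'")
  lv <- sub$levels[[level]]
  e <- vapply(c("LL", "LH", "HL", "HH"), function(nm) sum(lv[[nm]]^2), 0)
  tot <- sum(e)
  if (tot == 0) return(if (band == "LL") 1 else 0)
  unname(e[band] / tot)
}

#' Total coefficient energy of a sub-band set
#'
#' Sum of squared coefficients over the deepest `LL` plus all detail bands
#' (the coefficients that enter reconstruction). For the orthonormal
#' periodized transform this equals the input energy.
#'
#' @param sub a `subband_set`.
#' @return Nonnegative scalar.
#' @export
subband_total_energy <- function(sub) {
  nl <- length(sub$levels)
  e <- sum(sub$levels[[nl]]$LL^2)
  for (l in seq_len(nl))
    for (nm in c("LH", "HL", "HH")) e <- e + sum(sub$levels[[l]][[nm]]^2)
  e
}
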