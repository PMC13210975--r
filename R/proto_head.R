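# Supervised contrastive loss, momentum prototype bank, nearest-prototype
# classification with margin confidence, and the calibration/separability
# diagnostics used to audit the fine-grained health classifier.

#' Coral health classes
#'
#' The four-state health taxonomy with fixed ordering (the index is the
#' tie-break order) and ecological intervention priorities.
#'
#' @return A data.frame with columns `name`, `index` (0-based) and
#'   `intervention_priority`.
#' @export
health_classes <- function() {
  data.frame(
    name = c("Healthy", "Sub-healthy", "Bleached", "Dead"),
    index = 0:3,
    intervention_priority = c("None", "High priority (reversible)",
                              "Active intervention", "Monitoring only"),
    stringsAsFactors = FALSE
  )
}

.check_labels <- function(labels) {
  cls <- health_classes()$name
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    if (any(labels < 0 | labels > 3 | labels != floor(labels)))
      stop("numeric labels must be class indices 0..3")
    labels <- cls[labels + 1L]
  }
  bad <- setdiff(unique(labels), cls)
  if (length(bad))
    stop("unknown health class label(s): ", paste(bad, collapse = ", "))
  labels
}

.l2_normalize <- function(M) {
  n <- sqrt(rowSums(M^2))
  if (any(n == 0)) stop("cannot normalize a zero embedding")
  M / n
}

## ---- supervised contrastive loss -----------------------------------------

#' Supervised contrastive loss
#'
#' Temperature-scaled contrastive objective on unit-normalized embeddings:
#' each anchor is pulled toward same-label embeddings (its positives) and
#' pushed from all others. The anchor is excluded from the denominator
#' (standard convention). Every anchor must have at least one positive.
#'
#' @param embeddings numeric matrix, one embedding per row (rows are
#'   L2-normalized internally).
#' @param labels health-class labels, one per row.
#' @param tau temperature, a positive scalar (default 0.10).
#' @return Nonnegative scalar loss.
#' @export
supcon_loss <- function(embeddings, labels, tau = 0.10) {
  embeddings <- as.matrix(embeddings)
  N <- nrow(embeddings)
  if (N < 2L) stop("need at least two embeddings")
  if (length(labels) != N) stop("labels length must match rows")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a positive scalar")
  labels <- .check_labels(labels)
  Z <- .l2_normalize(embeddings)
  S <- (Z %*% t(Z)) / tau
  same <- outer(labels, labels, "==")
  diag(same) <- FALSE
  npos <- rowSums(same)
  if (any(npos == 0))
    stop("anchor(s) without a positive: every label must occur at least twice")
  # log-sum-exp over a != i, numerically stabilized
  off <- S
  diag(off) <- -Inf
  mx <- apply(off, 1L, max)
  lse <- mx + log(rowSums(exp(off - mx)))
  logprob <- S - lse            # log p(i, a), anchor column excluded via mask
  per_anchor <- -rowSums(logprob * same) / npos
  mean(per_anchor)
}

## ---- prototype bank ------------------------------------------------------

#' Create a prototype bank
#'
#' One embedding-space centroid per health class, updated by a momentum
#' scheme and used for nearest-prototype classification. Prototypes start
#' uninitialized; seed them from class-wise feature averages with
#' [initialize_prototypes()] (or a full-coverage [update_prototypes()]
#' call with `m = 1`).
#'
#' @param dim embedding dimension.
#' @param momentum default update momentum `m` in (0, 1\] (default 0.1; a
#'   small momentum keeps prototypes stable while adapting gradually).
#' @return An object of class `prototype_bank`.
#' @export
prototype_bank <- function(dim, momentum = 0.1) {
  if (momentum <= 0 || momentum > 1) stop("momentum must be in (0, 1]")
  cls <- health_classes()$name
  mu <- matrix(NA_real_, length(cls), dim, dimnames = list(cls, NULL))
  structure(list(mu = mu, momentum = momentum,
                 update_count = stats::setNames(integer(length(cls)), cls)),
            class = "prototype_bank")
}

#' @export
print.prototype_bank <- function(x, ...) {
  cat(sprintf("<prototype_bank: dim %d, momentum %.3g, updates [%s]>\n",
              ncol(x$mu), x$momentum,
              paste(x$update_count, collapse = ", ")))
  invisible(x)
}

#' Initialize prototypes from class-wise feature averages
#'
#' @param bank a [prototype_bank()].
#' @param embeddings matrix of embeddings (rows).
#' @param labels labels covering all four classes.
#' @return The initialized bank.
#' @export
initialize_prototypes <- function(bank, embeddings, labels) {
  labels <- .check_labels(labels)
  missing <- setdiff(health_classes()$name, unique(labels))
  if (length(missing))
    stop("initialization needs every class; missing: ",
         paste(missing, collapse = ", "))
  update_prototypes(bank, embeddings, labels, m = 1)
}

#' Momentum update of class prototypes
#'
#' For each class present in the batch, `mu_c <- (1 - m) mu_c + m * mean` of
#' that class's embeddings; absent classes are untouched. With `m = 1` the
#' prototype equals the batch class mean. Uninitialized prototypes of
#' present classes are set directly to the batch mean.
#'
#' @param bank a [prototype_bank()].
#' @param embeddings matrix of embeddings (rows).
#' @param labels labels, one per row.
#' @param m momentum in (0, 1\]; defaults to the bank's momentum.
#' @return The updated bank.
#' @export
update_prototypes <- function(bank, embeddings, labels, m = bank$momentum) {
  stopifnot(inherits(bank, "prototype_bank"))
  if (!is.numeric(m) || length(m) != 1L || m <= 0 || m > 1)
    stop("momentum m must be in (0, 1]")
  embeddings <- as.matrix(embeddings)
  labels <- .check_labels(labels)
  if (nrow(embeddings) != length(labels)) stop("labels length must match rows")
  if (ncol(embeddings) != ncol(bank$mu))
    stop("embedding dimension does not match bank")
  for (cl in unique(labels)) {
    mu_batch <- colMeans(embeddings[labels == cl, , drop = FALSE])
    if (anyNA(bank$mu[cl, ])) {
      bank$mu[cl, ] <- mu_batch
    } else {
      bank$mu[cl, ] <- (1 - m) * bank$mu[cl, ] + m * mu_batch
    }
    bank$update_count[cl] <- bank$update_count[cl] + 1L
  }
  bank
}

#' Nearest-prototype classification with margin confidence
#'
#' Assigns the class of the nearest prototype in the normalized embedding
#' space. Confidence is the relative margin `(d2 - d1) / (d2 + d1)` between
#' the two smallest prototype distances: 1 when the embedding coincides
#' with a prototype, 0 on the decision boundary. Distance ties are broken
#' by the lower class index, with confidence 0.
#'
#' @param embedding numeric vector (or one-row matrix).
#' @param bank an initialized [prototype_bank()].
#' @return List with `class` (name), `index` (0-based) and `confidence`.
#' @export
classify <- function(embedding, bank) {
  stopifnot(inherits(bank, "prototype_bank"))
  if (anyNA(bank$mu)) stop("prototype bank is not fully initialized")
  z <- as.numeric(embedding)
  if (length(z) != ncol(bank$mu)) stop("embedding dimension mismatch")
  zn <- z / sqrt(sum(z^2))
  Pn <- .l2_normalize(bank$mu)
  d <- sqrt(rowSums((Pn - matrix(zn, nrow(Pn), length(zn), byrow = TRUE))^2))
  ord <- order(d)                       # stable: ties keep class order
  d1 <- unname(d[ord[1]]); d2 <- unname(d[ord[2]])
  conf <- if (d1 + d2 == 0) 0 else (d2 - d1) / (d2 + d1)
  cls <- health_classes()
  list(class = rownames(bank$mu)[ord[1]],
       index = cls$index[match(rownames(bank$mu)[ord[1]], cls$name)],
       confidence = conf)
}

## ---- joint detection loss ------------------------------------------------

#' Loss weights for the joint detection objective
#'
#' Defaults: `lambda1 = 1.0` (localization), `lambda2 = 0.3`
#' (cross-entropy), `lambda3 = 0.7` (supervised contrastive),
#' `tau = 0.10` (contrastive temperature).
#'
#' @param lambda1,lambda2,lambda3 nonnegative weights.
#' @param tau positive temperature.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 1.0, lambda2 = 0.3, lambda3 = 0.7,
                         tau = 0.10) {
  if (any(c(lambda1, lambda2, lambda3) < 0)) stop("weights must be nonnegative")
  if (tau <= 0) stop("tau must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 tau = tau), class = "loss_weights")
}

#' Joint detection loss
#'
#' `lambda1 * l_loc + lambda2 * l_ce + lambda3 * l_supcon`. The
#' localization term enters as a supplied scalar (the box-regression loss
#' of the host detector).
#'
#' @param l_loc,l_ce,l_supcon finite component losses.
#' @param w a [loss_weights()].
#' @return Scalar loss.
#' @export
detection_loss <- function(l_loc, l_ce, l_supcon, w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  comps <- c(l_loc, l_ce, l_supcon)
  if (!all(is.finite(comps))) stop("component losses must be finite")
  w$lambda1 * l_loc + w$lambda2 * l_ce + w$lambda3 * l_supcon
}

## ---- diagnostics ---------------------------------------------------------

#' Expected calibration error
#'
#' Confidences are binned into `n_bins` equal-width bins on \[0, 1\]; the
#' ECE is the sample-weighted mean of |bin accuracy - bin mean confidence|.
#' Empty bins contribute nothing.
#'
#' @param confidences numeric vector in \[0, 1\].
#' @param correct_flags logical (or 0/1) vector of the same length.
#' @param n_bins number of bins (default 10).
#' @return Value in \[0, 1\].
#' @export
expected_calibration_error <- function(confidences, correct_flags,
                                       n_bins = 10L) {
  if (length(confidences) != length(correct_flags)) stop("length mismatch")
  if (any(confidences < 0 | confidences > 1)) stop("confidences must be in [0, 1]")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  correct <- as.numeric(correct_flags)
  # bin i covers ((i-1)/B, i/B]; confidence 0 goes to bin 1
  bin <- pmax(1L, ceiling(confidences * n_bins))
  n <- length(confidences)
  ece <- 0
  for (b in unique(bin)) {
    idx <- bin == b
    ece <- ece + sum(idx) / n * abs(mean(correct[idx]) - mean(confidences[idx]))
  }
  ece
}

#' Silhouette score of labelled embeddings
#'
#' Mean over samples of `(b - a) / max(a, b)` where `a` is the mean
#' distance to same-class samples and `b` the smallest mean distance to
#' another class. Samples in singleton classes score 0; if `a = b = 0`
#' the sample scores 0.
#'
#' @param embeddings numeric matrix (rows are samples).
#' @param labels class labels (at least two classes present).
#' @return Value in \[-1, 1\].
#' @export
silhouette_score <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  N <- nrow(embeddings)
  if (N < 2L) stop("need at least two samples")
  labels <- as.character(labels)
  ulab <- unique(labels)
  if (length(ulab) < 2L) stop("silhouette undefined for a single class")
  D <- as.matrix(stats::dist(embeddings))
  s <- numeric(N)
  for (i in seq_len(N)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / n_own           # excludes self (D[i,i] = 0)
    b <- min(vapply(setdiff(ulab, labels[i]),
                    function(cl) mean(D[i, labels == cl]), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Train a linear embedding projection (desk-scale)
#'
#' Optimizes a small linear projection of labelled embeddings either with
#' cross-entropy alone (`mode = "ce"`: a multinomial-logistic head on the
#' projected features) or with the joint objective `lambda2 * CE +
#' lambda3 * SupCon` (`mode = "ce_supcon"`), the desk-scale analogue of
#' training the detection head with and without the contrastive term.
#' Gradients are numerical (the parameter count is tiny), descent is plain
#' gradient descent, and everything is seeded, so runs are reproducible.
#'
#' @param embeddings `N x D` input feature matrix.
#' @param labels health-class labels (every class at least twice).
#' @param mode `"ce"` or `"ce_supcon"`.
#' @param proj_dim projected dimension (default 4).
#' @param steps gradient steps (default 40).
#' @param lr learning rate (default 0.5).
#' @param w a [loss_weights()] supplying `lambda2`, `lambda3`, `tau`.
#' @param seed integer seed for the initialization.
#' @return List with the projection `W`, projected (L2-normalized)
#'   `embeddings`, and the final `loss`.
#' @export
train_embedding_projection <- function(embeddings, labels,
                                       mode = c("ce_supcon", "ce"),
                                       proj_dim = 4L, steps = 40L, lr = 0.5,
                                       w = loss_weights(), seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(embeddings)
  labels <- .check_labels(labels)
  cls <- sort(unique(labels))
  y <- match(labels, cls)
  D <- ncol(X); K <- length(cls)
  n_par <- D * proj_dim + proj_dim * K + K
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  par <- stats::rnorm(n_par, sd = 0.3)
  unpack <- function(par) {
    W <- matrix(par[seq_len(D * proj_dim)], D, proj_dim)
    M <- matrix(par[D * proj_dim + seq_len(proj_dim * K)], proj_dim, K)
    b <- par[D * proj_dim + proj_dim * K + seq_len(K)]
    list(W = W, M = M, b = b)
  }
  loss_fn <- function(par) {
    p <- unpack(par)
    P <- X %*% p$W
    logits <- sweep(P %*% p$M, 2L, p$b, "+")
    mx <- apply(logits, 1L, max)
    ce <- mean(mx + log(rowSums(exp(logits - mx))) -
                 logits[cbind(seq_along(y), y)])
    if (mode == "ce") return(ce)
    sc <- supcon_loss(P, labels, tau = w$tau)
    w$lambda2 * ce + w$lambda3 * sc
  }
  eps <- 1e-4
  for (s in seq_len(steps)) {
    g <- vapply(seq_len(n_par), function(j) {
      pp <- par; pp[j] <- pp[j] + eps
      pm <- par; pm[j] <- pm[j] - eps
      (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    }, 0)
    par <- par - lr * g
  }
  p <- unpack(par)
  proj <- .l2_normalize(X %*% p$W)
  list(W = p$W, embeddings = proj, loss = loss_fn(par))
}

#' Pairwise class-centroid distances
#'
#' Euclidean distances between class centroids in the raw embedding space.
#'
#' @param embeddings numeric matrix (rows are samples).
#' @param labels labels; every requested class must have at least one
#'   sample.
#' @return Symmetric matrix with zero diagonal, one row/column per class
#'   present (ordered by the canonical class order when labels are health
#'   classes).
#' @export
centroid_distances <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  labels <- as.character(labels)
  cls <- health_classes()$name
  ulab <- if (all(unique(labels) %in% cls)) intersect(cls, unique(labels)) else unique(labels)
  if (length(ulab) < 2L) stop("need at least two classes")
  cent <- t(vapply(ulab, function(cl) {
    colMeans(embeddings[labels == cl, , drop = FALSE])
  }, numeric(ncol(embeddings))))
  as.matrix(stats::dist(cent))
}
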