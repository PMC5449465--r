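# The state-dependent decoder: PCA dimensionality reduction followed by
# multiclass linear discriminant analysis with a shrinkage-regularized
# pooled covariance, winner-take-all posterior thresholding, and the
# posterior-weighted force readout.

#' Fit a state-dependent spike-count decoder
#'
#' Centers the trial-by-feature activity matrix, reduces it to its first
#' \code{k} principal components, and fits a multiclass linear discriminant
#' (shared pooled covariance, shrunk toward a scaled identity with a
#' Ledoit-Wolf coefficient) on the component scores. Posteriors follow
#' Bayes' rule under the class-conditional Gaussian model with empirical
#' class priors.
#'
#' @param x \code{M x F} activity matrix or a \code{"state_activity"}
#'   dataset (whose labels are then used).
#' @param labels Class labels aligned with rows of \code{x}.
#' @param k Number of principal components to retain
#'   (\code{1 <= k <= rank(x)}).
#' @param p_thr Winner-take-all posterior threshold in \code{[0, 1]};
#'   \code{1} disables thresholding.
#' @param variant,signal Optional tags recording which feature variant the
#'   decoder was fit on.
#' @return An object of class \code{"sd_decoder"}.
#' @export
sd_decoder <- function(x, labels = NULL, k, p_thr = 1,
                       variant = NULL, signal = NULL) {
  if (inherits(x, "state_activity")) {
    labels <- labels %||% x$labels
    variant <- variant %||% x$variant
    signal <- signal %||% x$signal
    x <- x$A
  }
  x <- as.matrix(x)
  m <- nrow(x)
  if (is.null(labels) || length(labels) != m)
    stop("'labels' must align with the rows of 'x'")
  classes <- sort(unique(labels))
  cnt <- table(factor(labels, levels = classes))
  if (m < 2L || any(cnt < 2L))
    stop("need at least 2 training trials per class")
  if (p_thr < 0 || p_thr > 1) stop("'p_thr' must lie in [0, 1]")
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sv <- svd(xc)
  tol <- max(sv$d) * 1e-9
  rank <- sum(sv$d > tol)
  if (rank == 0L) stop("activity matrix has rank 0")
  if (k < 1L || k > rank)
    stop(sprintf("'k' must lie in 1..rank (rank = %d)", rank))
  loadings <- sv$v[, seq_len(k), drop = FALSE]       # F x k, orthonormal cols
  scores <- xc %*% loadings
  lda <- lda_fit(scores, labels, classes)
  structure(list(center = center, loadings = loadings, k = as.integer(k),
                 rank = rank, lda = lda, p_thr = p_thr,
                 classes = classes, n_features = ncol(x),
                 variant = variant, signal = signal),
            class = "sd_decoder")
}

# Multiclass LDA on score space: class means, pooled MLE covariance with a
# small fixed shrinkage toward the scaled identity (regularized
# discriminant analysis, gamma = 0.01), empirical priors. The pooled
# covariance carries the decoder's state-discounting ability -- the
# correlations between pre-stimulus state features and response features
# are exactly what lets the discriminant subtract state-induced
# variability -- so the regularizer must perturb it as little as
# conditioning allows; gamma = 0.01 keeps the estimate invertible even at
# full PCA rank while changing well-determined directions by ~1%.
lda_fit <- function(h, labels, classes, gamma = 0.01) {
  h <- as.matrix(h)
  n <- nrow(h); k <- ncol(h)
  means <- matrix(0, length(classes), k)
  resid <- h
  for (j in seq_along(classes)) {
    idx <- labels == classes[j]
    means[j, ] <- colMeans(h[idx, , drop = FALSE])
    resid[idx, ] <- sweep(h[idx, , drop = FALSE], 2L, means[j, ])
  }
  s <- crossprod(resid) / n
  mu_t <- mean(diag(s))
  if (mu_t <= 0) mu_t <- .Machine$double.eps
  sigma <- (1 - gamma) * s + diag(gamma * mu_t, k)
  ch <- tryCatch(chol(sigma),
                 error = function(e) chol(sigma + diag(1e-6 * mu_t, k)))
  priors <- as.numeric(table(factor(labels, levels = classes))) / n
  list(means = means, chol = ch, priors = priors, shrinkage = gamma,
       classes = classes)
}

# Gaussian posteriors for rows of h (n x k) under a fitted LDA.
lda_posterior <- function(lda, h) {
  h <- matrix(h, ncol = nrow(lda$chol))
  d <- length(lda$classes)
  logp <- matrix(0, nrow(h), d)
  for (j in seq_len(d)) {
    z <- backsolve(lda$chol, t(sweep(h, 2L, lda$means[j, ])),
                   transpose = TRUE)
    logp[, j] <- log(lda$priors[j]) - 0.5 * colSums(z^2)
  }
  logp <- logp - apply(logp, 1L, max)
  p <- exp(logp)
  p / rowSums(p)
}

#' @export
print.sd_decoder <- function(x, ...) {
  cat(sprintf("State-dependent decoder (%s%s): %d features -> %d PCs, %d classes\n",
              x$variant %||% "untagged",
              if (!is.null(x$signal)) paste0(", ", x$signal) else "",
              x$n_features, x$k, length(x$classes)))
  cat(sprintf("  WTA threshold %.2f, LDA shrinkage %.3f, priors %s\n",
              x$p_thr, x$lda$shrinkage,
              paste(sprintf("%.2f", x$lda$priors), collapse = "/")))
  invisible(x)
}

#' @export
summary.sd_decoder <- function(object, ...) {
  print(object)
  cat("  class means (score space):\n")
  print(round(object$lda$means, 3))
  invisible(object)
}

#' @export
coef.sd_decoder <- function(object, ...) object$loadings

#' Posterior stimulus probabilities for new activity vectors
#'
#' Projects centered activity onto the retained principal axes and
#' evaluates the LDA class posteriors; optionally applies the
#' winner-take-all threshold.
#'
#' @param object A fitted \code{"sd_decoder"}.
#' @param newdata Feature vector, matrix (rows = trials), or
#'   \code{"state_activity"} dataset.
#' @param type \code{"posterior"} (raw), \code{"wta"} (thresholded), or
#'   \code{"class"} (predicted labels).
#' @param ... Unused.
#' @return Posterior matrix (trials x classes) or label vector.
#' @export
predict.sd_decoder <- function(object, newdata,
                               type = c("posterior", "wta", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "state_activity")) newdata <- newdata$A
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$n_features)
    stop(sprintf("feature length %d does not match model (%d)",
                 ncol(newdata), object$n_features))
  h <- sweep(newdata, 2L, object$center) %*% object$loadings
  p <- lda_posterior(object$lda, h)
  colnames(p) <- object$classes
  switch(type,
         posterior = p,
         wta = apply_wta(p, object$p_thr),
         class = object$classes[max.col(p, ties.method = "first")])
}

#' Winner-take-all posterior thresholding
#'
#' If the largest posterior exceeds \code{p_thr} the vector is replaced by
#' a one-hot vector at its argmax (ties broken toward the lowest stimulus
#' index); otherwise it is returned unchanged.
#'
#' @param p Posterior vector or matrix (rows = trials).
#' @param p_thr Threshold in \code{[0, 1]}.
#' @return Thresholded posteriors, same shape as \code{p}.
#' @export
apply_wta <- function(p, p_thr) {
  if (p_thr < 0 || p_thr > 1) stop("'p_thr' must lie in [0, 1]")
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, nrow = 1L)
  mx <- apply(p, 1L, max)
  hit <- mx > p_thr
  if (any(hit)) {
    arg <- max.col(p, ties.method = "first")
    p[hit, ] <- 0
    p[cbind(which(hit), arg[hit])] <- 1
  }
  if (vec) p[1L, ] else p
}

#' Decoded force vector from thresholded posteriors
#'
#' The force applied to the point mass is the posterior-weighted sum of the
#' four region forces, so it always lies in their convex hull.
#'
#' @param p_tilde Length-4 (thresholded) posterior vector.
#' @param forces \code{4 x 2} matrix of region force vectors (rows =
#'   regions).
#' @return Length-2 force vector.
#' @export
decode_force <- function(p_tilde, forces) {
  forces <- as.matrix(forces)
  if (length(p_tilde) != nrow(forces))
    stop("posterior length must match the number of forces")
  as.numeric(crossprod(forces, p_tilde))
}

#' Leave-one-out decoding of a session
#'
#' For every trial \code{m}, the PCA and the LDA are refit on the other
#' \code{M - 1} trials (no leakage) and trial \code{m} is decoded; the
#' resulting posteriors are winner-take-all thresholded. Folds whose
#' training set lost a class entirely fall back to the empirical priors
#' with a warning. If \code{k} exceeds a fold's rank it is capped at that
#' rank.
#'
#' @param dataset A \code{"state_activity"} dataset (or plain matrix with
#'   \code{labels}).
#' @param k Retained principal components per fold.
#' @param p_thr Winner-take-all threshold.
#' @param labels Labels when \code{dataset} is a plain matrix.
#' @return List with \code{p_tilde} (\code{M x 4} thresholded posteriors),
#'   \code{p_raw}, \code{predicted} labels, and \code{classes}.
#' @export
loo_decode <- function(dataset, k, p_thr = 1, labels = NULL) {
  if (inherits(dataset, "state_activity")) {
    labels <- dataset$labels
    a <- dataset$A
  } else a <- as.matrix(dataset)
  if (is.null(labels)) stop("labels required")
  scores <- loo_scores(a, k)
  loo_lda_pass(scores, labels, p_thr)
}

# Per-fold PCA scores for all leave-one-out folds. Label-independent, so
# shuffle-based bias estimation can reuse this across permutations. Uses
# the cheaper of feature-space (F x F scatter) or Gram-space
# ((M-1) x (M-1)) eigendecomposition; both are exact and, because LDA
# posteriors are invariant to orthonormal rotations of score space and the
# shrinkage target is isotropic, the two routes give identical posteriors.
loo_scores <- function(a, k) {
  m <- nrow(a); f <- ncol(a)
  if (m < 3L) stop("leave-one-out needs at least 3 trials")
  folds <- vector("list", m)
  if (f <= m - 1L) {
    cs <- colSums(a)
    cp <- crossprod(a)                       # F x F
    for (i in seq_len(m)) {
      ai <- a[i, ]
      mu <- (cs - ai) / (m - 1)
      s <- cp - tcrossprod(ai) - (m - 1) * tcrossprod(mu)
      e <- eigen((s + t(s)) / 2, symmetric = TRUE)
      tol <- max(e$values[1], 0) * 1e-9
      rank <- sum(e$values > tol)
      kk <- max(1L, min(k, rank))
      v <- e$vectors[, seq_len(kk), drop = FALSE]
      xc <- sweep(a[-i, , drop = FALSE], 2L, mu)
      folds[[i]] <- list(h = xc %*% v,
                         h_test = as.numeric((ai - mu) %*% v))
    }
  } else {
    g <- tcrossprod(a)                       # M x M
    rs_all <- rowSums(g)
    s_all <- sum(rs_all)
    for (i in seq_len(m)) {
      idx <- seq_len(m)[-i]
      rs <- rs_all - g[, i]                  # over j != i, all rows
      tm <- s_all - 2 * rs_all[i] + g[i, i]  # sum over idx x idx
      gc <- g[idx, idx] -
        outer(rs[idx], rep(1, m - 1L)) / (m - 1) -
        outer(rep(1, m - 1L), rs[idx]) / (m - 1) + tm / (m - 1)^2
      e <- eigen((gc + t(gc)) / 2, symmetric = TRUE)
      tol <- max(e$values[1], 0) * 1e-9
      rank <- sum(e$values > tol)
      kk <- max(1L, min(k, rank))
      lam <- e$values[seq_len(kk)]
      u <- e$vectors[, seq_len(kk), drop = FALSE]
      gt <- g[idx, i] - rs[idx] / (m - 1) - rs[i] / (m - 1) + tm / (m - 1)^2
      folds[[i]] <- list(h = u %*% diag(sqrt(lam), kk),
                         h_test = as.numeric(crossprod(u, gt) / sqrt(lam)))
    }
  }
  folds
}

# LDA + WTA pass over precomputed fold scores for a given labeling.
loo_lda_pass <- function(folds, labels, p_thr, classes = sort(unique(labels))) {
  m <- length(folds)
  d <- length(classes)
  p_raw <- matrix(NA_real_, m, d)
  warned <- FALSE
  for (i in seq_len(m)) {
    lab_tr <- labels[-i]
    cnt <- tabulate(match(lab_tr, classes), d)
    if (any(cnt == 0L)) {
      pri <- cnt / sum(cnt)
      p_raw[i, ] <- pri
      warned <- TRUE
      next
    }
    lda <- lda_fit(folds[[i]]$h, lab_tr, classes)
    p_raw[i, ] <- lda_posterior(lda, folds[[i]]$h_test)
  }
  if (warned)
    warning("fold(s) with an empty training class fell back to priors")
  p_tilde <- apply_wta(p_raw, p_thr)
  colnames(p_raw) <- colnames(p_tilde) <- classes
  list(p_tilde = p_tilde, p_raw = p_raw,
       predicted = classes[max.col(p_tilde, ties.method = "first")],
       classes = classes)
}
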