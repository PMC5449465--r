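# Decoding-performance evaluation: soft confusion matrices, mutual
# information in bits with shuffle-based bias correction, nested
# leave-one-out hyperparameter optimization, the state-only-information
# control, and the angular-error metric of the decoded force.

#' Soft confusion matrix of decoded posteriors
#'
#' Entry \code{Q[d, i]} is the mean (thresholded) posterior assigned to
#' decoded stimulus \code{d} over the trials on which stimulus \code{i} was
#' presented, so each column is a probability distribution over decoded
#' stimuli.
#'
#' @param p_tilde \code{M x D} matrix of (thresholded) posteriors.
#' @param labels Presented-stimulus labels, all classes present.
#' @param classes Class set (default the sorted unique labels).
#' @return An object of class \code{"confusion_matrix"}: list with
#'   \code{Q} (\code{D x D}, decoded in rows, presented in columns),
#'   \code{priors} \code{P(s_i)}, and the decoded \code{marginal}
#'   \code{Q(s_d)}.
#' @export
confusion_matrix <- function(p_tilde, labels, classes = sort(unique(labels))) {
  p_tilde <- as.matrix(p_tilde)
  d <- length(classes)
  if (ncol(p_tilde) != d) stop("posterior width must match the class set")
  cnt <- tabulate(match(labels, classes), d)
  if (any(cnt == 0L)) stop("every stimulus class must appear at least once")
  q <- matrix(0, d, d, dimnames = list(decoded = classes, presented = classes))
  for (j in seq_len(d))
    q[, j] <- colMeans(p_tilde[labels == classes[j], , drop = FALSE])
  priors <- cnt / sum(cnt)
  structure(list(Q = q, priors = priors,
                 marginal = as.numeric(q %*% priors), classes = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix Q(decoded | presented):\n")
  print(round(x$Q, 3))
  cat(sprintf("mutual information: %.4f bits\n", mutual_information(x)))
  invisible(x)
}

#' Mutual information of a confusion matrix
#'
#' \code{I(S; D) = sum_{d,i} P(s_i) Q(s_d | s_i) log2[ Q(s_d | s_i) /
#' Q(s_d) ]} with the convention \code{0 * log 0 = 0}. For four
#' equiprobable stimuli the result lies in \code{[0, 2]} bits.
#'
#' @param q A \code{"confusion_matrix"}, or a plain column-stochastic
#'   matrix (uniform priors assumed).
#' @return Information in bits.
#' @export
mutual_information <- function(q) {
  if (inherits(q, "confusion_matrix")) {
    priors <- q$priors; qm <- q$Q
  } else {
    qm <- as.matrix(q); priors <- rep(1 / ncol(qm), ncol(qm))
  }
  marg <- as.numeric(qm %*% priors)
  bits <- 0
  for (i in seq_along(priors)) for (d in seq_along(marg)) {
    if (qm[d, i] > 0 && marg[d] > 0)
      bits <- bits + priors[i] * qm[d, i] * log2(qm[d, i] / marg[d])
  }
  bits
}

#' Shuffle-corrected decoding information of a session dataset
#'
#' Runs the full leave-one-out pipeline (PCA + LDA + WTA, confusion matrix,
#' mutual information) on the dataset, then estimates the finite-sampling
#' bias as the mean information obtained after permuting the stimulus
#' labels across trials (class counts preserved) and rerunning the decode.
#' The corrected value \code{raw - bias} may be negative and is reported
#' as-is.
#'
#' Because the per-fold PCA does not depend on the labels, fold scores are
#' computed once and only the discriminant stage is refit per permutation;
#' this is exactly equivalent to rerunning the whole pipeline per shuffle.
#'
#' @param dataset A \code{"state_activity"} dataset.
#' @param k Retained principal components.
#' @param p_thr Winner-take-all threshold.
#' @param n_shuffles Number of label permutations (default 100).
#' @param seed Seed for the permutations.
#' @return An object of class \code{"info_result"}: list with
#'   \code{raw_bits}, \code{bias_bits}, \code{corrected_bits},
#'   \code{shuffle_sem}, \code{n_shuffles}, \code{k}, \code{p_thr},
#'   \code{variant}, \code{signal}.
#' @export
shuffle_bias_correct <- function(dataset, k, p_thr = 1, n_shuffles = 100L,
                                 seed = 1L) {
  stopifnot(inherits(dataset, "state_activity"))
  if (n_shuffles < 1L) stop("'n_shuffles' must be >= 1")
  labels <- dataset$labels
  classes <- sort(unique(labels))
  scores <- loo_scores(dataset$A, k)
  raw <- mutual_information(
    confusion_matrix(loo_lda_pass(scores, labels, p_thr, classes)$p_tilde,
                     labels, classes))
  sh <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      perm <- sample(labels)
      mutual_information(
        confusion_matrix(loo_lda_pass(scores, perm, p_thr, classes)$p_tilde,
                         perm, classes))
    }, numeric(1))
  })
  structure(list(raw_bits = raw, bias_bits = mean(sh),
                 corrected_bits = raw - mean(sh),
                 shuffle_sem = stats::sd(sh) / sqrt(length(sh)),
                 n_shuffles = as.integer(n_shuffles),
                 k = k, p_thr = p_thr,
                 variant = dataset$variant, signal = dataset$signal),
            class = "info_result")
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("Decoding information (%s, %s): %.4f bits (raw %.4f - bias %.4f, %d shuffles, sem %.4f)\n",
              x$variant %||% "?", x$signal %||% "?", x$corrected_bits,
              x$raw_bits, x$bias_bits, x$n_shuffles, x$shuffle_sem))
  invisible(x)
}

#' Default hyperparameter grid
#'
#' Candidate values for the winner-take-all threshold, the number of
#' principal components (\code{NA} = full rank), the feature variant, the
#' signal type, and the numbers of pre- and post-stimulus bins.
#'
#' @return A data frame of grid points.
#' @export
default_param_grid <- function() {
  g <- expand.grid(p_thr = c(0.5, 0.7, 0.8, 0.9, 1.0),
                   k = c(2, 4, 8, 16, 32, NA),
                   variant = c("SD-TD", "SD-TA", "SI"),
                   signal = c("SUA", "MUA"),
                   t_theta = c(0L, 13L, 26L, 39L),
                   t_r = c(5L, 10L, 20L),
                   stringsAsFactors = FALSE)
  # SI ignores pre bins; state-dependent variants need at least one
  g <- g[!(g$variant == "SI" & g$t_theta > 0L), ]
  g <- g[!(g$variant != "SI" & g$t_theta == 0L), ]
  rownames(g) <- NULL
  g
}

#' Nested leave-one-out hyperparameter optimization
#'
#' For a held-out test trial \code{m}, evaluates every grid point by inner
#' leave-one-out decoding over the remaining \code{M - 1} trials and
#' returns the point maximizing the confusion-matrix information. The test
#' trial is never touched. Ties are broken deterministically: smallest
#' \code{k}, then smallest \code{p_thr}, then variant preference SD-TD over
#' SD-TA over SI, then smallest \code{t_theta}, smallest \code{t_r}, SUA
#' over MUA.
#'
#' @param session A \code{"spike_session"}.
#' @param grid Data frame of candidate hyperparameters (see
#'   \code{\link{default_param_grid}}); \code{t_theta}/\code{t_r} are capped
#'   at what \code{schedule} provides.
#' @param test_trial Index of the held-out trial.
#' @param schedule Binning schedule at full resolution (default the 39-bin
#'   schedule over the session's windows).
#' @return A one-row data frame: the chosen grid point with its inner-loop
#'   information \code{inner_bits}.
#' @export
optimize_parameters <- function(session, grid = default_param_grid(),
                                test_trial = 1L, schedule = NULL) {
  stopifnot(inherits(session, "spike_session"))
  if (!nrow(grid)) stop("empty hyperparameter grid")
  meta <- session$meta
  schedule <- schedule %||% make_default_schedule(meta$pre_span, meta$post_span,
                                                  meta$artifact_blank)
  keep <- setdiff(seq_along(session$trials), test_trial)
  counts <- lapply(session$trials[keep], bin_spikes, schedule = schedule)
  labels <- session$labels[keep]
  grid$t_theta <- pmin(grid$t_theta, schedule$t_theta)
  grid$t_r <- pmin(grid$t_r, schedule$t_r)
  grid <- unique(grid)
  inner <- numeric(nrow(grid))
  # group rows sharing a dataset so fold scores are reused across p_thr
  key <- with(grid, paste(variant, signal, t_theta, t_r, k))
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(grid))) {
    gp <- grid[r, ]
    ck <- key[r]
    if (is.null(cache[[ck]])) {
      ds <- assemble_from_counts(counts, labels, schedule, gp$variant,
                                 gp$signal, t_theta = gp$t_theta,
                                 t_r = gp$t_r)
      kk <- if (is.na(gp$k)) qr(sweep(ds$A, 2, colMeans(ds$A)))$rank else gp$k
      kk <- max(1L, min(kk, ncol(ds$A), nrow(ds$A) - 2L))
      cache[[ck]] <- list(scores = loo_scores(ds$A, kk), labels = labels)
    }
    sc <- cache[[ck]]
    res <- loo_lda_pass(sc$scores, sc$labels, gp$p_thr)
    inner[r] <- mutual_information(
      confusion_matrix(res$p_tilde, sc$labels))
  }
  vr <- match(grid$variant, c("SD-TD", "SD-TA", "SI"))
  sr <- match(grid$signal, c("SUA", "MUA"))
  kord <- ifelse(is.na(grid$k), Inf, grid$k)
  ord <- order(-inner, kord, grid$p_thr, vr, grid$t_theta, grid$t_r, sr)
  best <- grid[ord[1L], , drop = FALSE]
  best$inner_bits <- inner[ord[1L]]
  rownames(best) <- NULL
  best
}

#' Information carried by the state variables alone
#'
#' Control analysis: runs the identical decoding pipeline but feeds the
#' decoder only the pre-stimulus state features (no post-stimulus
#' response), quantifying how much stimulus information leaks into the
#' state variables themselves.
#'
#' @param session A \code{"spike_session"}.
#' @param schedule Binning schedule (default the 39-bin schedule).
#' @param variant \code{"SD-TD"} (full pre-stimulus time course) or
#'   \code{"SD-TA"} (time-averaged).
#' @param k,p_thr,n_shuffles,seed Passed to the pipeline.
#' @param signal \code{"SUA"} or \code{"MUA"}.
#' @return An \code{"info_result"}.
#' @export
state_only_information <- function(session, schedule = NULL,
                                   variant = c("SD-TD", "SD-TA"),
                                   k = 8L, p_thr = 1, n_shuffles = 100L,
                                   seed = 1L, signal = "SUA") {
  variant <- match.arg(variant)
  meta <- session$meta
  schedule <- schedule %||% make_default_schedule(meta$pre_span, meta$post_span,
                                                  meta$artifact_blank)
  counts <- lapply(session$trials, bin_spikes, schedule = schedule)
  ds <- assemble_from_counts(counts, session$labels, schedule, variant,
                             signal, t_r = 0L)
  k <- max(1L, min(k, ncol(ds$A)))
  shuffle_bias_correct(ds, k = k, p_thr = p_thr, n_shuffles = n_shuffles,
                       seed = seed)
}

#' Angular error of a decoded force
#'
#' Unsigned angle (degrees, in \code{[0, 180]}) between the decoded force
#' and the force vector of the sensory region containing the point mass.
#' Perfect decoding gives 0; a zero decoded force has no direction and is
#' returned as \code{NA}.
#'
#' @param f_decoded Length-2 decoded force.
#' @param region Index of the region containing the point mass.
#' @param forces \code{4 x 2} matrix of region forces.
#' @return Angle in degrees, or \code{NA} for a zero decoded force.
#' @export
angular_error <- function(f_decoded, region, forces) {
  forces <- as.matrix(forces)
  f_ref <- forces[region, ]
  n1 <- sqrt(sum(f_decoded^2)); n2 <- sqrt(sum(f_ref^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  cosang <- sum(f_decoded * f_ref) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * 180 / pi
}
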