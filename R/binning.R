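# Discretization of spike trains into the count matrices and
# state-activity feature vectors the decoder consumes.
#
# Pre-stimulus bins are adaptive: fine (5 ms) immediately before onset,
# where the ongoing-activity time course matters most for estimating the
# instantaneous network state, and progressively coarser further back.
# Post-stimulus bins are uniform 5 ms starting at the end of the
# stimulation-artifact blank.

#' Construct a binning schedule
#'
#' @param pre_edges Strictly increasing pre-stimulus bin edges (s), all
#'   \code{<= 0}, ending exactly at 0; widths must be non-increasing toward
#'   onset (coarse-to-fine).
#' @param post_edges Strictly increasing post-stimulus bin edges (s), first
#'   edge at the end of the artifact blank; widths must all equal 5 ms.
#' @return An object of class \code{"binning_schedule"} with elements
#'   \code{pre_edges}, \code{post_edges}, \code{t_theta}, \code{t_r}.
#' @export
binning_schedule <- function(pre_edges, post_edges) {
  pre_edges <- as.numeric(pre_edges); post_edges <- as.numeric(post_edges)
  if (length(pre_edges) >= 2L) {
    if (any(diff(pre_edges) <= 0)) stop("pre edges must be strictly increasing")
    if (abs(pre_edges[length(pre_edges)]) > 1e-12)
      stop("pre edges must end at stimulus onset (0)")
    w <- diff(pre_edges)
    if (any(diff(w) > 1e-12))
      stop("pre bin widths must be non-increasing toward onset")
  } else if (length(pre_edges) == 1L && abs(pre_edges) > 1e-12) {
    stop("a single pre edge must sit at 0")
  }
  if (length(post_edges) >= 2L) {
    if (any(diff(post_edges) <= 0)) stop("post edges must be strictly increasing")
    if (any(abs(diff(post_edges) - 0.005) > 1e-9))
      stop("post bin width is fixed at 5 ms")
    if (post_edges[1] < 0) stop("post edges must start at or after onset")
  }
  structure(list(pre_edges = pre_edges, post_edges = post_edges,
                 t_theta = max(length(pre_edges) - 1L, 0L),
                 t_r = max(length(post_edges) - 1L, 0L)),
            class = "binning_schedule")
}

#' @export
print.binning_schedule <- function(x, ...) {
  cat(sprintf("Binning schedule: %d pre bins over %.3f s, %d post bins of 5 ms",
              x$t_theta,
              if (x$t_theta) diff(range(x$pre_edges)) else 0, x$t_r), "\n")
  invisible(x)
}

#' Default adaptive binning schedule
#'
#' Pre-stimulus window of 0.75 s discretized coarse-to-fine into 39 bins:
#' 9 bins of 50 ms, then 10 bins of 20 ms, then 20 bins of 5 ms ending at
#' onset. Post-stimulus window discretized into uniform 5 ms bins starting
#' at the end of the artifact blank.
#'
#' @param pre_span Pre-stimulus span (s); must be at least 0.75 (the
#'   schedule covers the most recent 0.75 s).
#' @param post_span Post-stimulus span (s) after the blank; must be a
#'   positive multiple of 5 ms.
#' @param artifact_blank Start of the first post bin (s, default 0.030).
#' @return A \code{\link{binning_schedule}}.
#' @export
make_default_schedule <- function(pre_span = 0.75, post_span = 0.05,
                                  artifact_blank = 0.030) {
  if (pre_span < 0.75 - 1e-12)
    stop("default 39-bin schedule needs pre_span >= 0.75 s")
  n_post <- post_span / 0.005
  if (post_span <= 0 || abs(n_post - round(n_post)) > 1e-9)
    stop("post_span must be a positive multiple of 5 ms")
  widths <- c(rep(0.050, 9L), rep(0.020, 10L), rep(0.005, 20L))
  pre_edges <- -rev(c(0, cumsum(rev(widths))))
  post_edges <- artifact_blank + 0.005 * (0:round(n_post))
  binning_schedule(pre_edges, post_edges)
}

#' Bin one trial's spikes into count matrices
#'
#' Counts spikes per (unit, bin) with half-open bins \code{[lo, hi)}.
#' Spikes outside the schedule span (including the artifact blank gap) are
#' ignored with a warning.
#'
#' @param trial A trial record (see \code{\link{generate_trial}}).
#' @param schedule A \code{\link{binning_schedule}}.
#' @return An object of class \code{"trial_counts"}: list with \code{theta}
#'   (\code{N x t_theta} pre-stimulus counts) and \code{r} (\code{N x t_r}
#'   post-stimulus counts).
#' @export
bin_spikes <- function(trial, schedule) {
  stopifnot(inherits(schedule, "binning_schedule"))
  n_units <- length(trial$spikes)
  theta <- matrix(0L, n_units, schedule$t_theta)
  r <- matrix(0L, n_units, schedule$t_r)
  dropped <- 0L
  for (n in seq_len(n_units)) {
    s <- trial$spikes[[n]]
    if (!length(s)) next
    binned <- logical(length(s))
    if (schedule$t_theta) {
      idx <- findInterval(s, schedule$pre_edges, rightmost.closed = FALSE)
      ok <- idx >= 1L & idx <= schedule$t_theta & s < 0
      if (any(ok)) theta[n, ] <- theta[n, ] + tabulate(idx[ok], schedule$t_theta)
      binned <- binned | ok
    }
    if (schedule$t_r) {
      idx <- findInterval(s, schedule$post_edges, rightmost.closed = FALSE)
      ok <- idx >= 1L & idx <= schedule$t_r
      if (any(ok)) r[n, ] <- r[n, ] + tabulate(idx[ok], schedule$t_r)
      binned <- binned | ok
    }
    dropped <- dropped + sum(!binned)
  }
  if (dropped > 0L)
    warning(sprintf("%d spike(s) outside the schedule span were ignored", dropped))
  structure(list(theta = theta, r = r), class = "trial_counts")
}

#' Pool single-unit counts into one multi-unit channel
#'
#' Sums counts across units per time bin, turning \code{N x T} matrices into
#' \code{1 x T}. Idempotent for a single unit.
#'
#' @param counts A \code{"trial_counts"} object.
#' @return A \code{"trial_counts"} with one row per matrix.
#' @export
pool_mua <- function(counts) {
  stopifnot(inherits(counts, "trial_counts"))
  structure(list(theta = matrix(colSums(counts$theta), 1L),
                 r = matrix(colSums(counts$r), 1L)),
            class = "trial_counts")
}

#' Build the state-activity feature vector of one trial
#'
#' Flattens the count matrices unit-by-unit (unit-major, pre-stimulus bins
#' oldest-first before post-stimulus bins) into the decoder's feature
#' vector:
#' \itemize{
#'   \item \code{"SI"}: post-stimulus counts only (length \code{N * t_r});
#'   \item \code{"SD-TD"}: full pre-stimulus time course followed by the
#'     response, per unit (length \code{N * (t_theta + t_r)});
#'   \item \code{"SD-TA"}: one time-averaged pre-stimulus value per unit
#'     followed by the response (length \code{N * (1 + t_r)}). The average
#'     is duration-weighted (total counts over total pre duration, scaled by
#'     the mean bin width) so unequal bin widths do not bias it.
#' }
#'
#' @param counts A \code{"trial_counts"} object.
#' @param variant One of \code{"SI"}, \code{"SD-TA"}, \code{"SD-TD"}.
#' @param pre_widths Pre-bin widths (needed for \code{"SD-TA"}; defaults to
#'   equal widths).
#' @return Numeric feature vector.
#' @export
build_activity_vector <- function(counts, variant, pre_widths = NULL) {
  stopifnot(inherits(counts, "trial_counts"))
  variant <- match.arg(variant, c("SI", "SD-TA", "SD-TD"))
  switch(variant,
    "SI" = as.numeric(t(counts$r)),
    "SD-TD" = as.numeric(t(cbind(counts$theta, counts$r))),
    "SD-TA" = {
      t_theta <- ncol(counts$theta)
      if (t_theta == 0L) stop("SD-TA needs at least one pre-stimulus bin")
      # time-averaged pre-stimulus activity as the total count over the
      # window (duration-weighted mean rate times window length): invariant
      # to the bin partition, and on the same count scale as the response
      # features so the PCA step weights it comparably
      ta <- rowSums(counts$theta)
      as.numeric(t(cbind(ta, counts$r)))
    })
}

#' Assemble the trial-by-feature state-activity matrix of a session
#'
#' Bins every trial, optionally pools units into a single multi-unit
#' channel, builds the per-trial feature vector for the requested decoder
#' variant, and stacks them in trial order.
#'
#' @param session A \code{"spike_session"}.
#' @param schedule A \code{\link{binning_schedule}}.
#' @param variant \code{"SI"}, \code{"SD-TA"} or \code{"SD-TD"}.
#' @param signal \code{"SUA"} (per-unit) or \code{"MUA"} (pooled).
#' @return An object of class \code{"state_activity"}: list with the
#'   \code{M x F} matrix \code{A}, \code{labels}, \code{variant},
#'   \code{signal}, \code{n_units} (after pooling), \code{t_theta},
#'   \code{t_r}, and the \code{schedule}.
#' @export
assemble_dataset <- function(session, schedule, variant = "SI",
                             signal = c("SUA", "MUA")) {
  stopifnot(inherits(session, "spike_session"),
            inherits(schedule, "binning_schedule"))
  signal <- match.arg(signal)
  variant <- match.arg(variant, c("SI", "SD-TA", "SD-TD"))
  n_units <- unique(vapply(session$trials, function(tr) length(tr$spikes), 1L))
  if (length(n_units) != 1L)
    stop("inconsistent unit counts across trials")
  counts <- lapply(session$trials, bin_spikes, schedule = schedule)
  assemble_from_counts(counts, session$labels, schedule, variant, signal)
}

# Shared core: build the M x F matrix from pre-binned counts, optionally
# truncating to the most recent t_theta pre bins / first t_r post bins
# (used by the hyperparameter search, which bins once at full resolution).
assemble_from_counts <- function(counts, labels, schedule, variant, signal,
                                 t_theta = NULL, t_r = NULL) {
  full_theta <- schedule$t_theta
  t_theta <- t_theta %||% full_theta
  t_r <- t_r %||% schedule$t_r
  if (t_theta > full_theta || t_r > schedule$t_r)
    stop("requested more bins than the schedule provides")
  pre_keep <- if (t_theta > 0L) (full_theta - t_theta + 1L):full_theta else integer(0)
  pre_widths <- diff(schedule$pre_edges)[pre_keep]
  rows <- lapply(counts, function(cm) {
    cm <- structure(list(theta = cm$theta[, pre_keep, drop = FALSE],
                         r = cm$r[, seq_len(t_r), drop = FALSE]),
                    class = "trial_counts")
    if (signal == "MUA") cm <- pool_mua(cm)
    build_activity_vector(cm, variant, pre_widths = pre_widths)
  })
  f_len <- unique(lengths(rows))
  if (length(f_len) != 1L) stop("inconsistent feature lengths across trials")
  a <- matrix(unlist(rows, use.names = FALSE), nrow = length(rows),
              ncol = f_len, byrow = TRUE)
  structure(list(A = a, labels = as.integer(labels), variant = variant,
                 signal = signal,
                 n_units = if (signal == "MUA") 1L else nrow(counts[[1]]$r),
                 t_theta = t_theta, t_r = t_r, schedule = schedule),
            class = "state_activity")
}

#' @export
print.state_activity <- function(x, ...) {
  cat(sprintf("State-activity dataset: %d trials x %d features (%s, %s; T_theta = %d, T_r = %d)\n",
              nrow(x$A), ncol(x$A), x$variant, x$signal, x$t_theta, x$t_r))
  invisible(x)
}
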