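# Synthetic spike sessions with a latent cortical state.
#
# The generator emulates the statistical structure that state-dependent
# decoding assumes: a slow, stimulus-independent excitability process x(t)
# adds to every unit's firing rate (with a per-unit coupling scale), so that
# pre-stimulus ongoing activity is informative about the state of the
# network at response time, while carrying no stimulus information itself.

#' Parameters for the synthetic spike-session generator
#'
#' Bundles every knob of the generator. Defaults describe an anesthetized
#' cortical recording of the kind the decoder targets: 10 single units, four
#' microstimulation patterns each delivered \code{n_trials_per_stimulus}
#' times, a 30 ms stimulation-artifact blank after onset, ongoing activity
#' whose excitability fluctuates on a ~1 s timescale with a 1-4 Hz
#' oscillatory component, and a slow linear drift of evoked rates of +20.5\%
#' over the session. The four patterns differ both in which units they
#' recruit (mild tuning) and in overall stimulation efficacy (distinct
#' total drives), and the latent excitability additively gates each unit's
#' overall evoked drive, so knowing the pre-stimulus state genuinely helps
#' interpret the response.
#'
#' @param n_units Number of single units (default 10).
#' @param n_trials_per_stimulus Trials per stimulus pattern (default 100).
#' @param baseline_rate Ongoing firing rate, spikes/s (default 25).
#' @param state_coupling Dimensionless gain \code{g} of the latent state;
#'   scales both the additive ongoing-rate coupling and the evoked-gain
#'   coupling, so 0 disables state dependence entirely (default 1).
#' @param evoked_coupling Relative weight of the state's additive modulation
#'   of the evoked response (the excitability gate on each unit's overall
#'   evoked drive, sharing the response time course); the effective gate is
#'   \code{state_coupling * evoked_coupling} (default 0.45).
#' @param state_timescale Decorrelation time of the latent state, s (default 0.85).
#' @param state_oscillation_band Frequency band (Hz) of the oscillatory state
#'   component; one frequency is drawn uniformly per trace (default c(1, 4)).
#' @param drift_fraction Fractional linear change of evoked rate from the
#'   first to the last trial of the session (default 0.205).
#' @param artifact_blank Duration of the stimulation-artifact blanking window
#'   after stimulus onset, s (default 0.030).
#' @param pre_span Pre-stimulus window length, s (default 0.75).
#' @param post_span Analysed post-stimulus window length, s, counted from the
#'   end of the artifact blank (default 0.1).
#' @param evoked_templates \code{n_units x 4} matrix of peak evoked-rate
#'   amplitudes (spikes/s); entry \code{[n, s]} scales unit \code{n}'s
#'   response to stimulus \code{s}. \code{NULL} builds the default tuned set.
#' @param template_decay Time constant of the evoked-rate decay after the
#'   blank, s (default 0.04).
#' @param scale_sdlog Log-sd of the per-unit state-coupling scales, drawn
#'   once per session from a log-normal with median \code{baseline_rate}.
#' @param sim_dt Simulation grid step for rates and the latent state, s.
#' @param seed Master seed; fully determines the session.
#'
#' @return An object of class \code{"sim_params"}.
#' @export
sim_params <- function(n_units = 10L,
                       n_trials_per_stimulus = 100L,
                       baseline_rate = 25,
                       state_coupling = 1,
                       evoked_coupling = 0.45,
                       state_timescale = 0.85,
                       state_oscillation_band = c(1, 4),
                       drift_fraction = 0.205,
                       artifact_blank = 0.030,
                       pre_span = 0.75,
                       post_span = 0.1,
                       evoked_templates = NULL,
                       template_decay = 0.04,
                       scale_sdlog = 0.5,
                       sim_dt = 0.001,
                       seed = 1L) {
  stop_if_not_scalar(n_units, "n_units", positive = TRUE)
  stop_if_not_scalar(n_trials_per_stimulus, "n_trials_per_stimulus", positive = TRUE)
  stop_if_not_scalar(baseline_rate, "baseline_rate")
  if (baseline_rate < 0) stop("'baseline_rate' must be >= 0")
  stop_if_not_scalar(state_coupling, "state_coupling")
  stop_if_not_scalar(state_timescale, "state_timescale", positive = TRUE)
  stop_if_not_scalar(drift_fraction, "drift_fraction")
  if (drift_fraction < 0) stop("'drift_fraction' must be >= 0")
  stop_if_not_scalar(artifact_blank, "artifact_blank")
  stop_if_not_scalar(pre_span, "pre_span", positive = TRUE)
  stop_if_not_scalar(post_span, "post_span", positive = TRUE)
  stop_if_not_scalar(sim_dt, "sim_dt", positive = TRUE)
  if (length(state_oscillation_band) != 2L || diff(state_oscillation_band) < 0)
    stop("'state_oscillation_band' must be c(lo, hi) with lo <= hi")
  if (!is.null(evoked_templates)) {
    evoked_templates <- as.matrix(evoked_templates)
    if (nrow(evoked_templates) != n_units || ncol(evoked_templates) != 4L)
      stop("'evoked_templates' must be an n_units x 4 amplitude matrix")
    if (any(evoked_templates < 0)) stop("template amplitudes must be >= 0")
  }
  structure(list(
    n_units = as.integer(n_units),
    n_trials_per_stimulus = as.integer(n_trials_per_stimulus),
    stimulus_count = 4L,
    baseline_rate = baseline_rate,
    state_coupling = state_coupling,
    evoked_coupling = evoked_coupling,
    state_timescale = state_timescale,
    state_oscillation_band = as.numeric(state_oscillation_band),
    drift_fraction = drift_fraction,
    artifact_blank = artifact_blank,
    pre_span = pre_span,
    post_span = post_span,
    evoked_templates = evoked_templates,
    template_decay = template_decay,
    scale_sdlog = scale_sdlog,
    sim_dt = sim_dt,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic session parameters\n")
  cat(sprintf("  units: %d, trials/stimulus: %d (M = %d)\n",
              x$n_units, x$n_trials_per_stimulus, 4L * x$n_trials_per_stimulus))
  cat(sprintf("  baseline %.1f sp/s, state coupling g = %.2f, timescale %.2f s\n",
              x$baseline_rate, x$state_coupling, x$state_timescale))
  cat(sprintf("  windows: pre %.2f s, blank %.0f ms, post %.2f s; drift +%.1f%%\n",
              x$pre_span, 1000 * x$artifact_blank, x$post_span,
              100 * x$drift_fraction))
  invisible(x)
}

# Default evoked-amplitude matrix: units cycle through preferred stimuli,
# non-preferred amplitudes fall off with circular stimulus distance. Peak
# and fall-off were calibrated once so that state-independent decoding of a
# default session lands mid-range (~1 bit), then frozen.
default_templates <- function(n_units, peak = 1100, falloff = 0.85,
                              drive = c(0.4, 0.75, 1.2, 1.8)) {
  pref <- ((seq_len(n_units) - 1L) %% 4L) + 1L
  amp <- matrix(0, n_units, 4L)
  for (n in seq_len(n_units)) {
    d <- pmin(abs(pref[n] - 1:4), 4L - abs(pref[n] - 1:4))  # circular distance
    amp[n, ] <- peak * falloff^d
  }
  sweep(amp, 2L, drive, `*`)
}

#' Sample one latent excitability trace
#'
#' The latent cortical state is an Ornstein-Uhlenbeck process (decorrelation
#' time \code{state_timescale}) mixed with a random-phase sinusoid whose
#' frequency is drawn uniformly in \code{state_oscillation_band}; the two
#' components carry half the variance each, so the trace has zero mean and
#' unit variance in expectation before coupling.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param seed Seed for this trace.
#' @return A list with the time grid \code{t} (s, stimulus onset at 0,
#'   spanning \code{[-pre_span, artifact_blank + post_span]}), the trace
#'   \code{x}, and the grid step \code{dt}.
#' @export
sample_latent_state <- function(params, seed = params$seed) {
  if (params$state_timescale <= 0) stop("state_timescale must be > 0")
  dt <- params$sim_dt
  t <- seq(-params$pre_span, params$artifact_blank + params$post_span - dt, by = dt)
  with_seed(seed, {
    x0 <- stats::rnorm(1)
    ou <- ou_path(x0, length(t), dt, params$state_timescale)
    f <- stats::runif(1, params$state_oscillation_band[1], params$state_oscillation_band[2])
    phi <- stats::runif(1, 0, 2 * pi)
    # variance split: 85% slow mean-reverting excitability, 15% oscillation
    x <- sqrt(0.85) * ou + sqrt(2 * 0.15) * sin(2 * pi * f * t + phi)
    list(t = t, x = x, dt = dt, freq = f, phase = phi, ou_end = ou[length(ou)])
  })
}

# Exact OU update with unit stationary variance.
ou_path <- function(x0, n, dt, tau) {
  a <- exp(-dt / tau)
  s <- sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- x0
  eps <- stats::rnorm(n - 1)
  for (i in seq_len(n - 1L)) x[i + 1L] <- a * x[i] + s * eps[i]
  x
}

# Rate time courses (N x length(t)) for a trial: rectified sum of baseline,
# drifted evoked template, and the additive latent-state term.
trial_rates <- function(params, stimulus, drift_factor, state, scales) {
  t <- state$t
  amp <- params$evoked_templates %||% default_templates(params$n_units)
  post <- t >= params$artifact_blank
  shape <- numeric(length(t))
  shape[post] <- exp(-(t[post] - params$artifact_blank) / params$template_decay)
  evoked <- outer(amp[, stimulus] * drift_factor, shape)
  ge <- params$state_coupling * (params$evoked_coupling %||% 0)
  if (ge != 0) {
    # state-modulated evoked component: network excitability additively
    # gates each unit's overall evoked drive (its mean template across
    # patterns), with the same post-stimulus time course as the response
    u <- rowMeans(amp)
    evoked <- evoked + ge * outer(u, shape * state$x)
  }
  rate <- params$baseline_rate + evoked +
    params$state_coupling * outer(scales, state$x)
  rate[rate < 0] <- 0
  rate
}

#' Generate one trial of spiking activity
#'
#' Spikes are drawn as an inhomogeneous Poisson process on the simulation
#' grid: unit \code{n}'s instantaneous rate is
#' \code{max(0, baseline + template[n, s](t) * drift + g * x(t) * scale[n])},
#' where the evoked template is non-zero only after the artifact blank and
#' the drift factor grows linearly from 1 to \code{1 + drift_fraction}
#' across the session. Spikes falling inside \code{[0, artifact_blank)} are
#' deleted (stimulation artifact).
#'
#' @param params A \code{\link{sim_params}} object.
#' @param stimulus Stimulus label in 1..4.
#' @param trial_index 1-based trial position in the session (drives drift).
#' @param seed Seed for this trial.
#' @param scales Per-unit state-coupling scales; defaults to the log-normal
#'   draw a session would use (median \code{baseline_rate}).
#' @param state Optional pre-sampled latent trace (for the closed-loop
#'   oracle); sampled fresh when \code{NULL}.
#' @param drift_factor Optional explicit drift multiplier overriding the
#'   within-session schedule.
#' @return A trial record: list with \code{stimulus}, \code{trial}, and
#'   \code{spikes} (a list of per-unit spike-time vectors, s, onset = 0).
#' @export
generate_trial <- function(params, stimulus, trial_index = 1L,
                           seed = params$seed, scales = NULL, state = NULL,
                           drift_factor = NULL) {
  if (!stimulus %in% 1:4) stop("unknown stimulus label: ", stimulus)
  m_total <- 4L * params$n_trials_per_stimulus
  if (is.null(drift_factor)) {
    drift_factor <- if (m_total > 1L)
      1 + params$drift_fraction * (trial_index - 1L) / (m_total - 1L) else 1
  }
  if (is.null(scales))
    scales <- with_seed(derive_seed(seed, "scales"),
                        stats::rlnorm(params$n_units,
                                      meanlog = log(max(params$baseline_rate, .Machine$double.eps)),
                                      sdlog = params$scale_sdlog))
  if (is.null(state))
    state <- sample_latent_state(params, seed = derive_seed(seed, "state"))
  rate <- trial_rates(params, stimulus, drift_factor, state, scales)
  spikes <- with_seed(derive_seed(seed, "spikes"),
                      draw_poisson_spikes(rate, state$t, state$dt))
  # artifact blanking: remove spikes in [0, artifact_blank)
  spikes <- lapply(spikes, function(s) s[s < 0 | s >= params$artifact_blank])
  list(stimulus = as.integer(stimulus), trial = as.integer(trial_index),
       spikes = spikes)
}

draw_poisson_spikes <- function(rate, t, dt) {
  n_units <- nrow(rate)
  counts <- matrix(stats::rpois(length(rate), rate * dt), n_units)
  lapply(seq_len(n_units), function(n) {
    k <- counts[n, ]
    idx <- rep.int(seq_along(k), k)
    if (!length(idx)) return(numeric(0))
    sort(t[idx] + stats::runif(length(idx), 0, dt))
  })
}

#' Generate a full synthetic spike session
#'
#' Produces \code{M = 4 * n_trials_per_stimulus} trials in a seeded random
#' stimulus order, with per-trial seed substreams derived from the master
#' seed (so any single trial can be regenerated independently) and one
#' session-wide draw of per-unit state-coupling scales.
#'
#' @param params A \code{\link{sim_params}} object.
#' @return An object of class \code{"spike_session"}: list with
#'   \code{trials} (trial records, see \code{\link{generate_trial}}),
#'   \code{labels} (integer vector), and \code{meta}.
#' @export
generate_session <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  m_total <- 4L * params$n_trials_per_stimulus
  order_seed <- derive_seed(params$seed, "stimulus-order")
  labels <- with_seed(order_seed,
                      sample(rep.int(1:4, params$n_trials_per_stimulus)))
  scales <- with_seed(derive_seed(params$seed, "scales"),
                      stats::rlnorm(params$n_units,
                                    meanlog = log(max(params$baseline_rate, .Machine$double.eps)),
                                    sdlog = params$scale_sdlog))
  trial_seeds <- with_seed(derive_seed(params$seed, "trial-seeds"),
                           sample.int(2147483646L, m_total))
  trials <- vector("list", m_total)
  for (m in seq_len(m_total)) {
    trials[[m]] <- generate_trial(params, labels[m], trial_index = m,
                                  seed = trial_seeds[m], scales = scales)
  }
  structure(list(
    trials = trials,
    labels = labels,
    meta = list(n_units = params$n_units, pre_span = params$pre_span,
                post_span = params$post_span,
                artifact_blank = params$artifact_blank,
                seed = params$seed, scales = scales, params = params)
  ), class = "spike_session")
}

#' @export
print.spike_session <- function(x, ...) {
  cat(sprintf("Spike session: %d trials, %d units, labels %s\n",
              length(x$trials), x$meta$n_units,
              paste(tabulate(x$labels, 4L), collapse = "/")))
  cat(sprintf("  windows: [-%.2f, %.2f] s, artifact blank %.0f ms\n",
              x$meta$pre_span, x$meta$artifact_blank + x$meta$post_span,
              1000 * x$meta$artifact_blank))
  invisible(x)
}

#' Write a spike session to disk
#'
#' Serializes to the documented plain-text schema: \code{session.json}
#' (metadata and generator parameters), \code{spikes.csv} with columns
#' \code{trial, unit, time_s} (onset = 0, pre-stimulus negative), and
#' \code{labels.csv} with columns \code{trial, stimulus}.
#'
#' @param session A \code{"spike_session"}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "spike_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- session$meta
  meta$params <- unclass(meta$params)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  rows <- do.call(rbind, lapply(session$trials, function(tr) {
    n_sp <- lengths(tr$spikes)
    if (sum(n_sp) == 0L) return(NULL)
    data.frame(trial = tr$trial,
               unit = rep.int(seq_along(tr$spikes), n_sp),
               time_s = unlist(tr$spikes, use.names = FALSE))
  }))
  utils::write.csv(rows, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(trial = seq_along(session$labels),
                              stimulus = session$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a spike session written by \code{\link{write_session}}
#'
#' @param dir Directory containing \code{session.json}, \code{spikes.csv},
#'   \code{labels.csv}.
#' @return A \code{"spike_session"}.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"), simplifyVector = TRUE)
  labs <- utils::read.csv(file.path(dir, "labels.csv"))
  spk <- utils::read.csv(file.path(dir, "spikes.csv"))
  n_units <- meta$n_units
  trials <- lapply(seq_len(nrow(labs)), function(m) {
    sub <- spk[spk$trial == m, , drop = FALSE]
    spikes <- lapply(seq_len(n_units), function(n)
      sort(sub$time_s[sub$unit == n]))
    list(stimulus = labs$stimulus[m], trial = m, spikes = spikes)
  })
  if (!is.null(meta$params)) {
    p <- meta$params
    meta$params <- sim_params(
      n_units = p$n_units, n_trials_per_stimulus = p$n_trials_per_stimulus,
      baseline_rate = p$baseline_rate, state_coupling = p$state_coupling,
      state_timescale = p$state_timescale,
      state_oscillation_band = p$state_oscillation_band,
      drift_fraction = p$drift_fraction, artifact_blank = p$artifact_blank,
      pre_span = p$pre_span, post_span = p$post_span,
      evoked_templates = p$evoked_templates,
      template_decay = p$template_decay, scale_sdlog = p$scale_sdlog,
      sim_dt = p$sim_dt, seed = p$seed)
  }
  structure(list(trials = trials, labels = as.integer(labs$stimulus),
                 meta = meta), class = "spike_session")
}

#' Stateful neural oracle for the closed loop
#'
#' Returns a generator whose latent excitability evolves continuously across
#' successive queries (no state reset between steps), so state-dependent
#' decoders can exploit pre-stimulus activity inside the loop. Each call to
#' \code{$emit(stimulus)} advances the latent state over one trial window
#' and returns a trial record.
#'
#' Closed-loop emissions use a fixed drift factor (default 1, i.e. the
#' nominal template amplitude): the within-session drift is a property of
#' the recorded training session, not of the evaluation block.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param seed Seed for the oracle's stream.
#' @param scales Per-unit coupling scales; defaults to the session draw the
#'   same seed would produce.
#' @param drift_factor Fixed evoked-rate multiplier for emitted trials.
#' @return A list with function \code{emit(stimulus)} and environment
#'   \code{env} (exposed for inspection in tests).
#' @export
neural_oracle <- function(params, seed = params$seed, scales = NULL,
                          drift_factor = 1) {
  if (is.null(scales))
    scales <- with_seed(derive_seed(seed, "scales"),
                        stats::rlnorm(params$n_units,
                                      meanlog = log(max(params$baseline_rate, .Machine$double.eps)),
                                      sdlog = params$scale_sdlog))
  env <- new.env(parent = emptyenv())
  env$params <- params
  env$scales <- scales
  env$t_abs <- 0            # absolute time of the next window start
  env$counter <- 0L
  with_seed(derive_seed(seed, "oracle-init"), {
    env$ou <- stats::rnorm(1)
    env$freq <- stats::runif(1, params$state_oscillation_band[1],
                             params$state_oscillation_band[2])
    env$phase <- stats::runif(1, 0, 2 * pi)
  })
  env$seed <- seed
  emit <- function(stimulus) {
    p <- env$params
    dt <- p$sim_dt
    t_rel <- seq(-p$pre_span, p$artifact_blank + p$post_span - dt, by = dt)
    env$counter <- env$counter + 1L
    step_seed <- derive_seed(env$seed, paste0("step-", env$counter))
    ou <- with_seed(derive_seed(step_seed, "ou"),
                    ou_path(env$ou, length(t_rel), dt, p$state_timescale))
    env$ou <- ou[length(ou)]
    t_abs <- env$t_abs + (t_rel - t_rel[1])
    x <- sqrt(0.5) * ou + sin(2 * pi * env$freq * t_abs + env$phase)
    env$t_abs <- t_abs[length(t_abs)] + dt
    state <- list(t = t_rel, x = x, dt = dt)
    rate <- trial_rates(p, stimulus, drift_factor, state, env$scales)
    spikes <- with_seed(derive_seed(step_seed, "spikes"),
                        draw_poisson_spikes(rate, t_rel, dt))
    spikes <- lapply(spikes, function(s) s[s < 0 | s >= p$artifact_blank])
    list(stimulus = as.integer(stimulus), trial = env$counter, spikes = spikes)
  }
  list(emit = emit, env = env)
}
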