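# Closed-loop bidirectional BMI around a simulated point mass in a viscous
# medium: a square workspace split into four sensory regions with force
# vectors at their centroids pointing at a central target, a position
# encoder choosing the microstimulation pattern, exact exponential
# integration of the overdamped dynamics, and the trajectory-metric suite.

#' Construct the BMI workspace
#'
#' A square plane centered on the origin, divided into four quadrant
#' sensory regions (1 = upper-right, 2 = upper-left, 3 = lower-left,
#' 4 = lower-right). Each region's force vector sits at its centroid and
#' points toward the target disc at the origin.
#'
#' @param side Side of the square workspace, cm (default 36).
#' @param f_mag Magnitude of each region force, N (default 0.008).
#' @param r_target Target-disc radius, cm; 0 is allowed for the
#'   closest-point analysis (default 1).
#' @param start_positions \code{8 x 2} matrix of start positions, cm.
#' @return An object of class \code{"bmi_workspace"}.
#' @export
bmi_workspace <- function(side = 36, f_mag = 0.008, r_target = 1,
                          start_positions = NULL) {
  stop_if_not_scalar(side, "side", positive = TRUE)
  stop_if_not_scalar(f_mag, "f_mag", positive = TRUE)
  stop_if_not_scalar(r_target, "r_target")
  if (r_target < 0) stop("'r_target' must be >= 0")
  q <- side / 4
  centroids <- rbind(c(q, q), c(-q, q), c(-q, -q), c(q, -q))
  forces <- -f_mag * centroids / sqrt(rowSums(centroids^2))
  if (is.null(start_positions)) {
    s <- side * 14 / 36; d <- side * 10 / 36
    start_positions <- rbind(c(s, 0), c(0, s), c(-s, 0), c(0, -s),
                             c(d, d), c(-d, d), c(-d, -d), c(d, -d))
  }
  start_positions <- as.matrix(start_positions)
  structure(list(side = side, f_mag = f_mag, r_target = r_target,
                 centroids = centroids, forces = forces,
                 start_positions = start_positions),
            class = "bmi_workspace")
}

#' @export
print.bmi_workspace <- function(x, ...) {
  cat(sprintf("BMI workspace: %.0f x %.0f cm, 4 quadrant regions, |F| = %g N, target radius %.2f cm\n",
              x$side, x$side, x$f_mag, x$r_target))
  invisible(x)
}

#' Encode a position as a stimulus label
#'
#' Returns the index of the sensory region containing the position.
#' Axis boundaries follow a half-open convention: \code{x >= 0} is the
#' right half, \code{y >= 0} the top half; the origin maps to region 1.
#'
#' @param position Length-2 position, cm.
#' @param workspace A \code{\link{bmi_workspace}}.
#' @return Stimulus label in 1..4.
#' @export
encode_position <- function(position, workspace) {
  h <- workspace$side / 2
  if (any(abs(position) > h + 1e-9))
    stop("position outside the workspace")
  x <- position[1]; y <- position[2]
  if (y >= 0) { if (x >= 0) 1L else 2L } else { if (x < 0) 3L else 4L }
}

#' One step of the point-mass dynamics
#'
#' Integrates \code{m dv/dt = F - b v} exactly over a step of duration
#' \code{dt} (exponential update, not Euler), with position integrated
#' consistently. Positions and velocities are in cm and cm/s; force in N,
#' mass in kg, viscosity in N s/m.
#'
#' @param state List with \code{position} (cm) and \code{velocity} (cm/s).
#' @param force Length-2 force, N.
#' @param dt Step duration, s.
#' @param mass Mass, kg.
#' @param viscosity Viscous drag coefficient \code{b}, N s/m.
#' @return Updated state list.
#' @export
step_dynamics <- function(state, force, dt, mass = 0.02, viscosity = 0.4) {
  if (any(!is.finite(force))) stop("non-finite force")
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  stop_if_not_scalar(mass, "mass", positive = TRUE)
  stop_if_not_scalar(viscosity, "viscosity", positive = TRUE)
  v_term <- 100 * force / viscosity            # terminal velocity, cm/s
  decay <- exp(-viscosity * dt / mass)
  dv <- state$velocity - v_term
  velocity <- v_term + dv * decay
  position <- state$position + v_term * dt +
    dv * (mass / viscosity) * (1 - decay)
  list(position = position, velocity = velocity)
}

clamp_to_workspace <- function(state, workspace) {
  h <- workspace$side / 2
  p <- state$position; v <- state$velocity
  for (ax in 1:2) {
    if (p[ax] > h) { p[ax] <- h; if (v[ax] > 0) v[ax] <- 0 }
    if (p[ax] < -h) { p[ax] <- -h; if (v[ax] < 0) v[ax] <- 0 }
  }
  list(position = p, velocity = v)
}

#' Run one closed-loop trajectory
#'
#' Per step: the encoder converts the point-mass position into a stimulus
#' pattern; the neural oracle emits a synthetic trial (its latent state
#' evolving continuously across steps); the trial is binned and decoded;
#' the winner-take-all posteriors weight the region forces into the decoded
#' force; the dynamics advance one step. The loop stops when the mass
#' enters the target disc or after \code{max_steps} steps.
#'
#' @param start Length-2 start position, cm.
#' @param workspace A \code{\link{bmi_workspace}}.
#' @param decoder A fitted \code{\link{sd_decoder}} (or any function
#'   \code{f(trial) -> length-4 thresholded posterior}, useful for decoder
#'   stubs in tests).
#' @param schedule Binning schedule matching the decoder's features
#'   (ignored when \code{decoder} is a function).
#' @param oracle A \code{\link{neural_oracle}}.
#' @param max_steps Step cap (default 100).
#' @param dt,mass,viscosity Dynamics constants.
#' @return An object of class \code{"bmi_trajectory"}: list with
#'   \code{positions} ((steps+1) x 2), \code{velocities}, \code{forces}
#'   (steps x 2), \code{p_tilde} (steps x 4), \code{stimuli},
#'   \code{converged}, \code{n_steps}, \code{start}.
#' @export
run_trajectory <- function(start, workspace, decoder, schedule = NULL,
                           oracle = NULL, max_steps = 100L,
                           dt = 0.5, mass = 0.02, viscosity = 0.4) {
  decode_fun <- if (is.function(decoder)) {
    decoder
  } else {
    stopifnot(inherits(decoder, "sd_decoder"), !is.null(schedule),
              !is.null(oracle))
    pre_widths <- diff(schedule$pre_edges)
    function(trial) {
      cm <- bin_spikes(trial, schedule)
      if (identical(decoder$signal, "MUA")) cm <- pool_mua(cm)
      a <- build_activity_vector(cm, decoder$variant %||% "SI",
                                 pre_widths = pre_widths)
      as.numeric(predict(decoder, a, type = "wta"))
    }
  }
  state <- list(position = as.numeric(start), velocity = c(0, 0))
  positions <- matrix(NA_real_, max_steps + 1L, 2L)
  velocities <- matrix(NA_real_, max_steps + 1L, 2L)
  forces <- matrix(NA_real_, max_steps, 2L)
  p_tilde <- matrix(NA_real_, max_steps, 4L)
  stimuli <- integer(max_steps)
  positions[1L, ] <- state$position
  velocities[1L, ] <- state$velocity
  converged <- sqrt(sum(state$position^2)) <= workspace$r_target &&
    workspace$r_target > 0
  n <- 0L
  while (!converged && n < max_steps) {
    n <- n + 1L
    stim <- encode_position(state$position, workspace)
    stimuli[n] <- stim
    trial <- if (is.null(oracle)) list(stimulus = stim) else oracle$emit(stim)
    pt <- decode_fun(trial)
    p_tilde[n, ] <- pt
    f <- decode_force(pt, workspace$forces)
    forces[n, ] <- f
    state <- step_dynamics(state, f, dt, mass, viscosity)
    state <- clamp_to_workspace(state, workspace)
    positions[n + 1L, ] <- state$position
    velocities[n + 1L, ] <- state$velocity
    if (workspace$r_target > 0 &&
        sqrt(sum(state$position^2)) <= workspace$r_target)
      converged <- TRUE
  }
  keep <- seq_len(n)
  structure(list(positions = positions[c(1L, keep + 1L), , drop = FALSE],
                 velocities = velocities[c(1L, keep + 1L), , drop = FALSE],
                 forces = forces[keep, , drop = FALSE],
                 p_tilde = p_tilde[keep, , drop = FALSE],
                 stimuli = stimuli[keep],
                 converged = converged, n_steps = n,
                 start = as.numeric(start)),
            class = "bmi_trajectory")
}

#' @export
print.bmi_trajectory <- function(x, ...) {
  cat(sprintf("BMI trajectory from (%.1f, %.1f): %d steps, %s\n",
              x$start[1], x$start[2], x$n_steps,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Run the full session protocol
#'
#' Repeats \code{run_trajectory} \code{reps_per_start} times from each of
#' the workspace's eight start positions (a fresh seeded oracle per
#' trajectory) and aggregates the trajectory metrics.
#'
#' @param workspace A \code{\link{bmi_workspace}}.
#' @param decoder Fitted \code{\link{sd_decoder}} or decode function.
#' @param schedule Binning schedule for the decoder.
#' @param oracle_params \code{\link{sim_params}} used to spawn per-trajectory
#'   oracles (\code{NULL} when \code{decoder} is a self-contained function).
#' @param reps_per_start Trajectories per start position (default 100).
#' @param seed Master seed for the oracles.
#' @param scales Per-unit coupling scales shared by all oracles (defaults
#'   to the training session's draw when supplied).
#' @param oracle_drift Evoked-rate multiplier for emitted trials; defaults
#'   to the session-average drift factor \code{1 + drift_fraction / 2}, so
#'   the loop is evaluated at the amplitude the decoder saw on average.
#' @param max_steps,dt,mass,viscosity Loop and dynamics constants.
#' @return List with \code{trajectories} and \code{metrics}
#'   (a \code{"trajectory_metrics"} object).
#' @export
run_session_protocol <- function(workspace, decoder, schedule = NULL,
                                 oracle_params = NULL, reps_per_start = 100L,
                                 seed = 1L, scales = NULL,
                                 oracle_drift = NULL, max_steps = 100L,
                                 dt = 0.5, mass = 0.02, viscosity = 0.4) {
  if (is.null(oracle_drift))
    oracle_drift <- if (is.null(oracle_params)) 1 else
      1 + oracle_params$drift_fraction / 2
  starts <- workspace$start_positions
  trajs <- vector("list", nrow(starts) * reps_per_start)
  idx <- 0L
  for (s in seq_len(nrow(starts))) {
    for (r in seq_len(reps_per_start)) {
      idx <- idx + 1L
      oracle <- if (is.null(oracle_params)) NULL else
        neural_oracle(oracle_params,
                      seed = derive_seed(seed, sprintf("traj-%d-%d", s, r)),
                      scales = scales, drift_factor = oracle_drift)
      tr <- run_trajectory(starts[s, ], workspace, decoder, schedule,
                           oracle, max_steps, dt, mass, viscosity)
      tr$start_index <- s
      trajs[[idx]] <- tr
    }
  }
  list(trajectories = trajs,
       metrics = trajectory_metrics(trajs, workspace))
}

#' Closest approach of a trajectory to the target
#'
#' @param trajectory A \code{"bmi_trajectory"}.
#' @param center Target center (default the origin).
#' @return Minimum Euclidean distance over all visited positions, in mm.
#' @export
closest_point_distance <- function(trajectory, center = c(0, 0)) {
  p <- sweep(trajectory$positions, 2L, center)
  10 * sqrt(min(rowSums(p^2)))
}

#' Directive force: decoded-force component toward the target
#'
#' Scalar projection of the decoded force onto the unit vector from the
#' current position toward the target center; positive values point at the
#' target.
#'
#' @param f_decoded Length-2 decoded force.
#' @param position Current position (must differ from \code{center}).
#' @param center Target center (default the origin).
#' @return Signed magnitude, or \code{NA} when the position sits at the
#'   center.
#' @export
directed_force <- function(f_decoded, position, center = c(0, 0)) {
  u <- center - position
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(NA_real_)
  sum(f_decoded * u) / nu
}

#' Within-trajectory variance of a start-position group
#'
#' Pools the per-step displacement vectors of all trajectories sharing one
#' start position; with \code{C_x} and \code{C_y} the variances of the
#' displacement components, returns \code{sqrt(C_x^2 + C_y^2)}. Lower
#' values mean more reproducible trajectories.
#'
#' @param trajectories List of \code{"bmi_trajectory"} from one start.
#' @return The wtv statistic.
#' @export
within_trajectory_variance <- function(trajectories) {
  if (length(trajectories) < 2L)
    stop("wtv needs at least 2 trajectories")
  disp <- do.call(rbind, lapply(trajectories, function(tr) {
    if (nrow(tr$positions) < 2L) return(NULL)
    diff(tr$positions)
  }))
  if (is.null(disp) || nrow(disp) < 2L)
    stop("wtv needs at least 2 displacement steps")
  cx <- stats::var(disp[, 1]); cy <- stats::var(disp[, 2])
  sqrt(cx^2 + cy^2)
}

#' Aggregate trajectory metrics
#'
#' Computes the full closed-loop metric suite over a list of trajectories:
#' convergence rate (\%), mean steps of converging trajectories, mean and
#' per-trajectory closest-point distance to the target (mm), mean directive
#' force, mean within-trajectory variance across start-position groups, and
#' per-start mean trajectories with per-step displacement covariance.
#'
#' @param trajectories List of \code{"bmi_trajectory"} (with
#'   \code{start_index} set, as from \code{\link{run_session_protocol}}).
#' @param workspace The \code{\link{bmi_workspace}} used.
#' @return An object of class \code{"trajectory_metrics"}.
#' @export
trajectory_metrics <- function(trajectories, workspace) {
  n <- length(trajectories)
  conv <- vapply(trajectories, function(tr) tr$converged, logical(1))
  steps <- vapply(trajectories, function(tr) tr$n_steps, numeric(1))
  closest <- vapply(trajectories, closest_point_distance, numeric(1))
  fdir <- unlist(lapply(trajectories, function(tr) {
    if (!nrow(tr$forces)) return(numeric(0))
    vapply(seq_len(nrow(tr$forces)), function(i)
      directed_force(tr$forces[i, ], tr$positions[i, ]), numeric(1))
  }))
  groups <- vapply(trajectories, function(tr) tr$start_index %||% 1L, 1L)
  wtv_by_start <- vapply(split(trajectories, groups), function(g) {
    if (length(g) < 2L) return(NA_real_)
    tryCatch(within_trajectory_variance(g), error = function(e) NA_real_)
  }, numeric(1))
  mean_traj <- lapply(split(trajectories, groups), function(g) {
    len <- max(vapply(g, function(tr) nrow(tr$positions), 1L))
    xs <- sapply(g, function(tr) c(tr$positions[, 1],
                                   rep(NA, len - nrow(tr$positions))))
    ys <- sapply(g, function(tr) c(tr$positions[, 2],
                                   rep(NA, len - nrow(tr$positions))))
    xs <- matrix(xs, nrow = len); ys <- matrix(ys, nrow = len)
    cbind(x = rowMeans(xs, na.rm = TRUE), y = rowMeans(ys, na.rm = TRUE))
  })
  disp_cov <- lapply(split(trajectories, groups), function(g) {
    d <- do.call(rbind, lapply(g, function(tr)
      if (nrow(tr$positions) >= 2L) diff(tr$positions) else NULL))
    if (is.null(d) || nrow(d) < 2L) matrix(NA_real_, 2L, 2L) else stats::cov(d)
  })
  structure(list(
    n_trajectories = n,
    convergence_rate = 100 * mean(conv),
    mean_steps = if (any(conv)) mean(steps[conv]) else NA_real_,
    closest_distance_mm = closest,
    mean_closest_distance_mm = mean(closest),
    mean_directed_force = mean(fdir, na.rm = TRUE),
    wtv_by_start = wtv_by_start,
    mean_wtv = mean(wtv_by_start, na.rm = TRUE),
    mean_trajectories = mean_traj,
    displacement_cov = disp_cov,
    r_target = workspace$r_target
  ), class = "trajectory_metrics")
}

#' @export
print.trajectory_metrics <- function(x, ...) {
  cat(sprintf("Trajectory metrics over %d runs (target radius %.2f cm):\n",
              x$n_trajectories, x$r_target))
  cat(sprintf("  convergence rate: %.1f%%, mean steps (converging): %.1f\n",
              x$convergence_rate, x$mean_steps))
  cat(sprintf("  mean closest distance: %.1f mm, mean F_dir: %.5f N, mean wtv: %.3f\n",
              x$mean_closest_distance_mm, x$mean_directed_force, x$mean_wtv))
  invisible(x)
}

#' Write trajectories to CSV
#'
#' One row per step with columns \code{trajectory_id, step, x_cm, y_cm,
#' vx, vy, Fx, Fy, stimulus, converged}.
#'
#' @param trajectories List of \code{"bmi_trajectory"}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    ns <- tr$n_steps
    if (ns == 0L) return(NULL)
    data.frame(trajectory_id = i, step = seq_len(ns),
               x_cm = tr$positions[-1L, 1], y_cm = tr$positions[-1L, 2],
               vx = tr$velocities[-1L, 1], vy = tr$velocities[-1L, 2],
               Fx = tr$forces[, 1], Fy = tr$forces[, 2],
               stimulus = tr$stimuli, converged = tr$converged)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
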