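# JSON-config pipelines wiring the generator, the decoder and the closed
# loop into reproducible end-to-end runs; backs the command-line interface.

config_schema <- function() {
  list(
    seed = "integer", out_dir = "character", verbose = "logical",
    n_units = "integer", n_trials_per_stimulus = "integer",
    baseline_rate = "numeric", state_coupling = "numeric",
    evoked_coupling = "numeric",
    state_timescale = "numeric", drift_fraction = "numeric",
    artifact_blank = "numeric", pre_span = "numeric", post_span = "numeric",
    variant = "character", signal = "character",
    k = "integer", p_thr = "numeric", n_shuffles = "integer",
    target_radius = "numeric", reps_per_start = "integer",
    max_steps = "integer", mass = "numeric", viscosity = "numeric",
    dt = "numeric", f_mag = "numeric", side = "numeric",
    session_dir = "character"
  )
}

#' Default pipeline configuration
#'
#' Every tunable constant of the generator, decoder, evaluation and closed
#' loop, with the package defaults.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(seed = 1L, out_dir = "sdbmi-out", verbose = TRUE,
       n_units = 10L, n_trials_per_stimulus = 100L,
       baseline_rate = 25, state_coupling = 1,
       evoked_coupling = 0.45,
       state_timescale = 0.85, drift_fraction = 0.205,
       artifact_blank = 0.030, pre_span = 0.75, post_span = 0.1,
       variant = "SD-TD", signal = "SUA",
       k = 48L, p_thr = 1, n_shuffles = 100L,
       target_radius = 1, reps_per_start = 100L,
       max_steps = 100L, mass = 0.02, viscosity = 0.4,
       dt = 0.5, f_mag = 0.008, side = 36,
       session_dir = "")
}

#' Validate a pipeline configuration
#'
#' Fills unset keys from \code{\link{default_config}}, rejects unknown
#' keys, checks types and physical constraints (positive mass, viscosity,
#' time steps; threshold in \code{[0, 1]}; known variant and signal).
#'
#' @param config Named list (e.g. parsed from JSON).
#' @return The completed, validated config.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  full <- utils::modifyList(default_config(), config)
  for (key in names(schema)) {
    val <- full[[key]]
    ok <- switch(schema[[key]],
                 integer = is.numeric(val) && length(val) == 1L &&
                   is.finite(val) && abs(val - round(val)) < 1e-9,
                 numeric = is.numeric(val) && length(val) == 1L && is.finite(val),
                 character = is.character(val) && length(val) == 1L,
                 logical = is.logical(val) && length(val) == 1L)
    if (!ok) stop(sprintf("config key '%s' must be %s", key, schema[[key]]))
    if (schema[[key]] == "integer") full[[key]] <- as.integer(round(val))
  }
  for (key in c("mass", "viscosity", "dt", "f_mag", "side", "state_timescale",
                "pre_span", "post_span"))
    if (full[[key]] <= 0) stop(sprintf("config key '%s' must be > 0", key))
  if (full$p_thr < 0 || full$p_thr > 1) stop("'p_thr' must lie in [0, 1]")
  if (full$target_radius < 0) stop("'target_radius' must be >= 0")
  if (!full$variant %in% c("SI", "SD-TA", "SD-TD"))
    stop("'variant' must be SI, SD-TA or SD-TD")
  if (!full$signal %in% c("SUA", "MUA")) stop("'signal' must be SUA or MUA")
  full
}

config_params <- function(cfg) {
  sim_params(n_units = cfg$n_units,
             n_trials_per_stimulus = cfg$n_trials_per_stimulus,
             baseline_rate = cfg$baseline_rate,
             state_coupling = cfg$state_coupling,
             evoked_coupling = cfg$evoked_coupling,
             state_timescale = cfg$state_timescale,
             drift_fraction = cfg$drift_fraction,
             artifact_blank = cfg$artifact_blank,
             pre_span = cfg$pre_span, post_span = cfg$post_span,
             seed = cfg$seed)
}

pipeline_log <- function(cfg, dir, ...) {
  msg <- sprintf(...)
  if (isTRUE(cfg$verbose)) message(msg)
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
      file = file.path(dir, "run.log"), append = TRUE, sep = "")
}

#' Run an end-to-end pipeline command
#'
#' Commands: \code{"simulate-session"} (generate and serialize a synthetic
#' session), \code{"fit-decode"} (assemble features, run the leave-one-out
#' decoder, write shuffle-corrected information for the configured
#' variant), \code{"run-bmi"} (fit the decoder on a session and run the
#' closed-loop protocol, writing trajectories and metrics), and
#' \code{"report"} (summary tables and figures from previous outputs).
#' Every output directory receives the resolved config and a log. Outputs
#' are deterministic for a fixed config.
#'
#' @param config Named list or path to a JSON config file.
#' @param command One of the commands above.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config,
                         command = c("simulate-session", "fit-decode",
                                     "run-bmi", "report")) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- validate_config(as.list(config))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "config.resolved.json"),
                       auto_unbox = TRUE, digits = NA)
  params <- config_params(cfg)
  get_session <- function() {
    if (nzchar(cfg$session_dir)) {
      pipeline_log(cfg, cfg$out_dir, "reading session from %s", cfg$session_dir)
      read_session(cfg$session_dir)
    } else {
      pipeline_log(cfg, cfg$out_dir, "generating session (seed %d)", cfg$seed)
      generate_session(params)
    }
  }
  if (command == "simulate-session") {
    session <- generate_session(params)
    write_session(session, cfg$out_dir)
    pipeline_log(cfg, cfg$out_dir, "wrote %d trials to %s",
                 length(session$trials), cfg$out_dir)
  } else if (command == "fit-decode") {
    session <- get_session()
    schedule <- make_default_schedule(cfg$pre_span, cfg$post_span,
                                      cfg$artifact_blank)
    ds <- assemble_dataset(session, schedule, cfg$variant, cfg$signal)
    k <- min(cfg$k, nrow(ds$A) - 2L, ncol(ds$A))
    info <- shuffle_bias_correct(ds, k = k, p_thr = cfg$p_thr,
                                 n_shuffles = cfg$n_shuffles,
                                 seed = derive_seed(cfg$seed, "shuffles"))
    res <- list(variant = cfg$variant, signal = cfg$signal, k = k,
                p_thr = cfg$p_thr, raw_bits = info$raw_bits,
                bias_bits = info$bias_bits,
                corrected_bits = info$corrected_bits,
                shuffle_sem = info$shuffle_sem, n_shuffles = info$n_shuffles)
    jsonlite::write_json(res, file.path(cfg$out_dir, "decode_info.json"),
                         auto_unbox = TRUE, digits = NA)
    pipeline_log(cfg, cfg$out_dir, "%s: %.4f corrected bits", cfg$variant,
                 info$corrected_bits)
  } else if (command == "run-bmi") {
    session <- get_session()
    schedule <- make_default_schedule(cfg$pre_span, cfg$post_span,
                                      cfg$artifact_blank)
    ds <- assemble_dataset(session, schedule, cfg$variant, cfg$signal)
    k <- min(cfg$k, nrow(ds$A) - 2L, ncol(ds$A))
    dec <- sd_decoder(ds, k = k, p_thr = cfg$p_thr)
    ws <- bmi_workspace(side = cfg$side, f_mag = cfg$f_mag,
                        r_target = cfg$target_radius)
    prot <- run_session_protocol(ws, dec, schedule, params,
                                 reps_per_start = cfg$reps_per_start,
                                 seed = derive_seed(cfg$seed, "bmi"),
                                 scales = session$meta$scales,
                                 max_steps = cfg$max_steps, dt = cfg$dt,
                                 mass = cfg$mass, viscosity = cfg$viscosity)
    write_trajectories(prot$trajectories,
                       file.path(cfg$out_dir, "trajectories.csv"))
    met <- prot$metrics
    jsonlite::write_json(
      list(variant = cfg$variant, convergence_rate = met$convergence_rate,
           mean_steps = met$mean_steps,
           mean_closest_distance_mm = met$mean_closest_distance_mm,
           mean_directed_force = met$mean_directed_force,
           mean_wtv = met$mean_wtv, r_target = met$r_target,
           n_trajectories = met$n_trajectories),
      file.path(cfg$out_dir, "bmi_metrics.json"), auto_unbox = TRUE,
      digits = NA)
    pipeline_log(cfg, cfg$out_dir, "%s closed loop: %.1f%% convergence",
                 cfg$variant, met$convergence_rate)
  } else if (command == "report") {
    report_pipeline(cfg)
  }
  invisible(cfg$out_dir)
}

# Summary tables + figures from fit-decode / run-bmi outputs found in
# subdirectories (or the directory itself) of out_dir.
report_pipeline <- function(cfg) {
  root <- cfg$out_dir
  dirs <- unique(dirname(c(
    Sys.glob(file.path(root, "*", "decode_info.json")),
    Sys.glob(file.path(root, "*", "bmi_metrics.json")),
    Sys.glob(file.path(root, "decode_info.json")),
    Sys.glob(file.path(root, "bmi_metrics.json")))))
  info <- do.call(rbind, lapply(Sys.glob(file.path(dirs, "decode_info.json")),
    function(f) as.data.frame(jsonlite::read_json(f, simplifyVector = TRUE))))
  bmi <- do.call(rbind, lapply(Sys.glob(file.path(dirs, "bmi_metrics.json")),
    function(f) as.data.frame(jsonlite::read_json(f, simplifyVector = TRUE))))
  if (!is.null(info))
    utils::write.csv(info, file.path(root, "report_information.csv"),
                     row.names = FALSE)
  if (!is.null(bmi))
    utils::write.csv(bmi, file.path(root, "report_bmi.csv"), row.names = FALSE)
  grDevices::pdf(file.path(root, "report_figures.pdf"), width = 7, height = 5)
  on.exit(grDevices::dev.off())
  if (!is.null(info)) {
    graphics::barplot(info$corrected_bits, names.arg = info$variant,
                      ylab = "corrected information (bits)",
                      main = "Decoding information by variant")
  }
  if (!is.null(bmi)) {
    graphics::barplot(bmi$convergence_rate, names.arg = bmi$variant,
                      ylab = "convergence rate (%)",
                      main = "Closed-loop convergence by variant")
    graphics::barplot(bmi$mean_closest_distance_mm, names.arg = bmi$variant,
                      ylab = "mean closest distance (mm)",
                      main = "Closest approach to target")
  }
  pipeline_log(cfg, root, "report written to %s", root)
  invisible(root)
}
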