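#' Run configuration
#'
#' Detector, artifact and simulation parameters for a pipeline run,
#' read/written as YAML. Unknown keys are rejected rather than ignored, and
#' every parameter is range-checked, so a typo in a config file fails loudly
#' instead of silently running with defaults.
#'
#' @param epoch_length Epoch duration (s), default 30.
#' @param k Threshold multiplier, default 2.
#' @param min_run Minimum episode length in epochs, default 15 (7.5 min).
#' @param accel_floor Acceleration floor (g) before inversion, default 0.005.
#' @param error_quantity `"sem"`, `"sd"` or `"residual_se"`, default `"sem"`.
#' @param max_gap Bridged-gap allowance in epochs, default 0.
#' @param hour_attribution `"overlap"` (default) or `"completion"`.
#' @param artifact Named list overriding [artifact_policy()] fields.
#' @param sim Named list overriding [sim_config()] fields.
#' @param seed Integer seed, default 1.
#' @param log_level `"info"` (default) or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(epoch_length = 30, k = 2, min_run = 15,
                       accel_floor = 0.005,
                       error_quantity = c("sem", "sd", "residual_se"),
                       max_gap = 0,
                       hour_attribution = c("overlap", "completion"),
                       artifact = list(), sim = list(), seed = 1,
                       log_level = c("info", "quiet")) {
  error_quantity <- match.arg(error_quantity)
  hour_attribution <- match.arg(hour_attribution)
  log_level <- match.arg(log_level)
  stopifnot(epoch_length > 0, k >= 0, min_run >= 1, accel_floor > 0,
            max_gap >= 0)
  policy <- do.call(artifact_policy, artifact)
  simc <- do.call(sim_config, utils::modifyList(
    list(epoch_length = epoch_length, accel_floor = accel_floor,
         error_quantity = error_quantity, k = k, min_run = min_run), sim))
  structure(list(epoch_length = epoch_length, k = k,
                 min_run = as.integer(min_run), accel_floor = accel_floor,
                 error_quantity = error_quantity, max_gap = max_gap,
                 hour_attribution = hour_attribution, artifact = policy,
                 sim = simc, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML config file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop(sprintf("%s: unknown config key(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (sub in c("artifact", "sim")) {
    if (!is.null(raw[[sub]])) {
      ok <- names(formals(if (sub == "artifact") artifact_policy
                          else sim_config))
      bad <- setdiff(names(raw[[sub]]), ok)
      if (length(bad)) {
        stop(sprintf("%s: unknown %s key(s): %s", path, sub,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      if (sub == "sim" && !is.null(raw$sim$calibration_plan)) {
        raw$sim$calibration_plan <-
          as.data.frame(lapply(raw$sim$calibration_plan, unlist))
      }
      if (sub == "sim" && !is.null(raw$sim$plant_plan)) {
        raw$sim$plant_plan <-
          as.data.frame(lapply(raw$sim$plant_plan, unlist))
      }
    }
  }
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config` to serialise.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(epoch_length = config$epoch_length, k = config$k,
              min_run = config$min_run, accel_floor = config$accel_floor,
              error_quantity = config$error_quantity,
              max_gap = config$max_gap,
              hour_attribution = config$hour_attribution,
              artifact = unclass(config$artifact),
              sim = unclass(config$sim),
              seed = config$seed, log_level = config$log_level)
  yaml::write_yaml(out, path)
  invisible(path)
}
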