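#' Expected RMSSD under the person's calibration model
#'
#' Evaluates `b0 + b1 / max(acceleration, accel_floor)` -- the RMSSD level
#' predicted from concurrent movement alone. Only models with `status "ok"`
#' may be used for detection.
#'
#' @param model A `person_model` with `status == "ok"`.
#' @param acceleration Numeric vector of accelerations (g), all >= 0.
#' @return Expected RMSSD (ms), vectorised over `acceleration`.
#' @export
expected_rmssd <- function(model, acceleration) {
  check_model_ok(model)
  if (any(acceleration < 0, na.rm = TRUE)) {
    stop("expected_rmssd: negative acceleration", call. = FALSE)
  }
  model$b0 + model$b1 / pmax(acceleration, model$accel_floor)
}

#' Detection threshold below the expected RMSSD
#'
#' `expected_rmssd(model, acceleration) - k * se`: actual RMSSD below this
#' line marks an epoch as an additional (non-metabolic) HRV decrease. Note
#' that some published descriptions print the formula with "actual" in place
#' of "expected"; the expected level is the quantity the threshold hangs
#' from, as the surrounding definition ("actual RMSSD two times the SE below
#' the *expected* level") makes clear.
#'
#' @inheritParams expected_rmssd
#' @param k Multiplier override; defaults to the model's stored `k` (2).
#' @return Threshold RMSSD (ms), vectorised.
#' @export
threshold <- function(model, acceleration, k = model$k) {
  expected_rmssd(model, acceleration) - k * model$se
}

#' Flag additional-HRV-decrease epochs
#'
#' An epoch is flagged when it is valid and its actual RMSSD lies strictly
#' below the person's threshold at the epoch's acceleration. Ties are not
#' flagged. Invalid epochs get a missing (`NA`) flag so that downstream
#' run detection can treat them as breaks.
#'
#' High movement does not exempt an epoch: the threshold tracks movement, so
#' a sufficiently suppressed RMSSD is flagged at any acceleration.
#'
#' @param model A `person_model` with `status == "ok"`.
#' @param day An [epoch_series()] of ambulatory epochs.
#' @param k Multiplier override (defaults to the model's `k`).
#' @return Logical vector, one flag per epoch (`NA` for invalid epochs).
#' @export
flag_epochs <- function(model, day, k = model$k) {
  check_model_ok(model)
  stopifnot(inherits(day, "epoch_series"))
  flags <- rep(NA, nrow(day))
  use <- day$valid
  flags[use] <- day$rmssd_ms[use] < threshold(model, day$accel_g[use], k = k)
  flags
}

#' Detect episodes as maximal runs of flagged epochs
#'
#' An episode is a maximal run of at least `min_run` consecutive flagged
#' epochs (default 15 epochs of 30 s, i.e. 7.5 min). Missing flags (invalid
#' epochs) break runs by default -- continuity may not be fabricated across
#' gaps -- though `max_gap` permits bridging up to that many consecutive
#' non-flagged epochs between flagged ones (the bridged epochs count toward
#' the episode span). Runs are maximal: a 40-epoch run is one episode, not a
#' set of overlapping windows.
#'
#' @param flags Logical vector from [flag_epochs()] (`NA` = invalid epoch).
#' @param min_run Minimum run length in epochs (default 15).
#' @param max_gap Maximum bridged gap in epochs (default 0).
#' @param epoch_length Epoch duration (s), used for episode start times.
#' @param start_s Start time of the first epoch (s).
#' @param person_id Person identifier.
#' @return An `episode_set`: list with `person_id`, `episodes` (data frame
#'   `start_index` (1-based), `start_s`, `length`), `flags`, `epoch_length`,
#'   `first_epoch_start_s`, `min_run`.
#' @export
detect_episodes <- function(flags, min_run = 15, max_gap = 0,
                            epoch_length = 30, start_s = 0,
                            person_id = "p1") {
  stopifnot(min_run >= 1, max_gap >= 0)
  f <- !is.na(flags) & flags
  runs <- flag_runs(f, max_gap)
  keep <- runs$length >= min_run
  episodes <- data.frame(start_index = as.integer(runs$start[keep]),
                         start_s = start_s +
                           (runs$start[keep] - 1) * epoch_length,
                         length = as.integer(runs$length[keep]))
  structure(list(person_id = person_id, episodes = episodes, flags = flags,
                 epoch_length = epoch_length, first_epoch_start_s = start_s,
                 min_run = as.integer(min_run)),
            class = "episode_set")
}

# Maximal runs of TRUE, optionally bridging gaps of <= max_gap FALSE/NA
# epochs between TRUE epochs. Returns start indices and span lengths.
flag_runs <- function(f, max_gap = 0) {
  r <- rle(f)
  len <- r$lengths
  val <- r$values
  ends <- cumsum(len)
  starts <- ends - len + 1
  if (max_gap > 0 && length(val) > 2) {
    # merge TRUE runs separated by a short gap, repeatedly
    i <- 1
    while (i + 2 <= length(val)) {
      if (val[i] && !val[i + 1] && val[i + 2] && len[i + 1] <= max_gap) {
        len[i] <- len[i] + len[i + 1] + len[i + 2]
        val <- val[-c(i + 1, i + 2)]
        len <- len[-c(i + 1, i + 2)]
      } else {
        i <- i + 1
      }
    }
    ends <- cumsum(len)
    starts <- ends - len + 1
  }
  list(start = starts[val], length = len[val])
}

#' @export
print.episode_set <- function(x, ...) {
  cat(sprintf("<episode_set> person %s: %d episode(s) (min_run=%d epochs)\n",
              x$person_id, nrow(x$episodes), x$min_run))
  invisible(x)
}

#' Hour grid helper
#'
#' Consecutive half-open hour windows `[end - 3600, end)` identified by their
#' end times, matching an hourly prompting scheme (e.g. prompts every hour
#' from 10:00 to 22:00 give 12 windows).
#'
#' @param first_hour_end_s End time of the first hour window (s).
#' @param n_hours Number of hourly windows.
#' @return Numeric vector of hour end times.
#' @export
hour_grid <- function(first_hour_end_s = 3600, n_hours = 12) {
  first_hour_end_s + 3600 * (seq_len(n_hours) - 1)
}

#' Code hours for the presence of AddHRVr episodes
#'
#' An hour is coded 1 when at least one detected episode has at least one
#' epoch whose window intersects the hour; hours without any episode are
#' coded 0. By default an episode flags *every* hour it intersects
#' (`attribution = "overlap"`); `attribution = "completion"` instead credits
#' only the hour containing the episode's `min_run`-th epoch, i.e. the hour
#' in which the episode criterion was first met. Per-hour means of RMSSD
#' and acceleration over valid epochs are returned alongside.
#'
#' @param episodes An `episode_set` from [detect_episodes()].
#' @param day The [epoch_series()] the episodes were detected on.
#' @param hour_ends Hour-window end times (s); see [hour_grid()]. Defaults
#'   to consecutive hours covering the day series.
#' @param attribution `"overlap"` (default) or `"completion"`.
#' @return An `hourly_coding` data frame: `hour_end_s`, `add_hrvr` (0/1),
#'   `n_episodes`, `mean_rmssd`, `mean_accel`, `n_valid_epochs`, with a
#'   `person_id` attribute.
#' @export
code_hours <- function(episodes, day, hour_ends = NULL,
                       attribution = c("overlap", "completion")) {
  stopifnot(inherits(episodes, "episode_set"), inherits(day, "epoch_series"))
  attribution <- match.arg(attribution)
  L <- attr(day, "epoch_length")
  if (is.null(hour_ends)) {
    day_start <- if (nrow(day)) day$start_s[1] else 0
    day_end <- if (nrow(day)) day$start_s[nrow(day)] + L else 3600
    hour_ends <- seq(day_start + 3600, by = 3600,
                     length.out = max(1, ceiling((day_end - day_start) / 3600)))
  }
  nh <- length(hour_ends)
  ep <- episodes$episodes
  n_epi <- integer(nh)
  for (h in seq_len(nh)) {
    lo <- hour_ends[h] - 3600; hi <- hour_ends[h]
    if (nrow(ep)) {
      if (attribution == "overlap") {
        ep_lo <- ep$start_s
        ep_hi <- ep$start_s + ep$length * L
        n_epi[h] <- sum(ep_lo < hi & ep_hi > lo)
      } else {
        done_t <- ep$start_s + (episodes$min_run - 1) * L  # min_run-th epoch
        n_epi[h] <- sum(done_t >= lo & done_t < hi)
      }
    }
  }
  mean_rmssd <- rep(NA_real_, nh)
  mean_accel <- rep(NA_real_, nh)
  n_valid <- integer(nh)
  for (h in seq_len(nh)) {
    in_h <- day$start_s >= hour_ends[h] - 3600 & day$start_s < hour_ends[h]
    use <- in_h & day$valid
    n_valid[h] <- sum(use)
    if (any(use)) {
      mean_rmssd[h] <- mean(day$rmssd_ms[use])
      mean_accel[h] <- mean(day$accel_g[use])
    }
  }
  out <- data.frame(hour_end_s = hour_ends,
                    add_hrvr = as.integer(n_epi >= 1),
                    n_episodes = n_epi, mean_rmssd = mean_rmssd,
                    mean_accel = mean_accel, n_valid_epochs = n_valid)
  attr(out, "person_id") <- episodes$person_id
  class(out) <- c("hourly_coding", "data.frame")
  out
}

check_model_ok <- function(model) {
  if (!inherits(model, "person_model")) {
    stop("expected a person_model", call. = FALSE)
  }
  if (!identical(model$status, "ok")) {
    stop(sprintf("model for person %s is excluded (status '%s') and cannot be used for detection",
                 model$person_id, model$status), call. = FALSE)
  }
  invisible(model)
}

#' Run detection for one person
#'
#' Convenience wrapper chaining [flag_epochs()], [detect_episodes()] and
#' [code_hours()] with the configuration stored in the model.
#'
#' @inheritParams flag_epochs
#' @inheritParams code_hours
#' @param max_gap Bridged-gap allowance passed to [detect_episodes()].
#' @return List with `flags`, `episodes` (an `episode_set`) and `hourly`
#'   (an `hourly_coding`).
#' @export
detect_person <- function(model, day, hour_ends = NULL, max_gap = 0,
                          attribution = c("overlap", "completion")) {
  flags <- flag_epochs(model, day)
  episodes <- detect_episodes(flags, min_run = model$min_run,
                              max_gap = max_gap,
                              epoch_length = attr(day, "epoch_length"),
                              start_s = if (nrow(day)) day$start_s[1] else 0,
                              person_id = model$person_id)
  hourly <- code_hours(episodes, day, hour_ends = hour_ends,
                       attribution = attribution)
  list(flags = flags, episodes = episodes, hourly = hourly)
}
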