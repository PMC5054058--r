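#' Artifact-cleaning policy for interbeat intervals
#'
#' Conventional range + relative-difference rule used in ambulatory HRV work:
#' an IBI is an artifact when it falls outside `[ibi_min, ibi_max]` ms or
#' when it differs from the previous retained IBI by more than `max_rel_diff`
#' (as a fraction of that previous value). `min_epoch_coverage` and
#' `min_beats_per_epoch` govern when an epoch built from cleaned IBIs is
#' considered valid (see [make_epochs()]).
#'
#' @param ibi_min,ibi_max Physiological IBI bounds in ms (defaults 300 and
#'   2000, i.e. 30--200 bpm).
#' @param max_rel_diff Maximum allowed relative jump between successive
#'   retained IBIs (default 0.30).
#' @param min_epoch_coverage Minimum fraction of an epoch's duration that
#'   must be covered by retained IBIs (default 0.8).
#' @param min_beats_per_epoch Minimum retained beats per epoch (default 10).
#' @return An object of class `artifact_policy`.
#' @export
artifact_policy <- function(ibi_min = 300, ibi_max = 2000,
                            max_rel_diff = 0.30, min_epoch_coverage = 0.8,
                            min_beats_per_epoch = 10) {
  stopifnot(ibi_min > 0, ibi_max > ibi_min,
            max_rel_diff > 0, max_rel_diff < 1,
            min_epoch_coverage > 0, min_epoch_coverage <= 1,
            min_beats_per_epoch >= 2)
  structure(list(ibi_min = ibi_min, ibi_max = ibi_max,
                 max_rel_diff = max_rel_diff,
                 min_epoch_coverage = min_epoch_coverage,
                 min_beats_per_epoch = min_beats_per_epoch),
            class = "artifact_policy")
}

#' Mark artifactual interbeat intervals
#'
#' Sequential single-pass rule: a sample is retained when it lies within the
#' policy's absolute bounds and differs from the *previous retained* sample
#' by at most `max_rel_diff` relative. The first in-bounds sample is exempt
#' from the relative rule. Rejected samples are marked `valid = FALSE`, never
#' deleted, so that epoch coverage remains computable. The operation is
#' idempotent: cleaning a cleaned stream changes nothing.
#'
#' @param stream An [ibi_stream()].
#' @param policy An [artifact_policy()].
#' @return The stream with updated `valid` marks.
#' @export
clean_ibis <- function(stream, policy = artifact_policy()) {
  stopifnot(inherits(stream, "ibi_stream"), inherits(policy, "artifact_policy"))
  n <- nrow(stream)
  valid <- stream$valid
  prev <- NA_real_
  for (i in seq_len(n)) {
    if (!valid[i]) next  # respect upstream marks
    x <- stream$ibi_ms[i]
    ok <- x >= policy$ibi_min && x <= policy$ibi_max
    if (ok && !is.na(prev)) {
      ok <- abs(x - prev) / prev <= policy$max_rel_diff
    }
    if (ok) prev <- x else valid[i] <- FALSE
  }
  stream$valid <- valid
  stream
}

#' Root mean square of successive differences
#'
#' The time-domain vagal HRV index used throughout the pipeline:
#' `sqrt(mean((ibi[i+1] - ibi[i])^2))` over a window of interbeat intervals.
#' Invariant under adding a constant to all IBIs and linear under positive
#' scaling.
#'
#' @param ibis Numeric vector of interbeat intervals (ms), length >= 2.
#' @return RMSSD in ms (non-negative scalar).
#' @examples
#' rmssd(c(800, 850, 800, 850))  # 50
#' @export
rmssd <- function(ibis) {
  ibis <- as.numeric(ibis)
  if (length(ibis) < 2 || anyNA(ibis)) {
    stop("rmssd: need >= 2 non-missing interbeat intervals", call. = FALSE)
  }
  sqrt(mean(diff(ibis)^2))
}

#' Acceleration magnitude from axis signals
#'
#' Per-sample Euclidean norm of tri-axial acceleration. A single-channel
#' input (already a magnitude or movement-component signal) is returned
#' unchanged. An optional constant offset (e.g. 1 g gravity on a dominant
#' axis) can be subtracted from the resulting magnitude; it is off by
#' default because ambulatory sensors typically export a movement-component
#' magnitude already.
#'
#' @param x,y,z Equal-length numeric vectors of per-sample acceleration (g).
#'   Omit `y` and `z` for single-channel input.
#' @param offset_g Constant subtracted from the magnitude (default 0); the
#'   result is floored at 0.
#' @return Numeric vector of magnitudes (g).
#' @examples
#' accel_magnitude(3, 4, 0)  # 5
#' @export
accel_magnitude <- function(x, y = NULL, z = NULL, offset_g = 0) {
  if (is.null(y) && is.null(z)) {
    m <- as.numeric(x)
  } else {
    if (is.null(y) || is.null(z) ||
        length(x) != length(y) || length(x) != length(z)) {
      stop("accel_magnitude: need three equal-length axes (or one channel)",
           call. = FALSE)
    }
    m <- sqrt(x^2 + y^2 + z^2)
  }
  pmax(m - offset_g, 0)
}

#' Aggregate cleaned IBIs and acceleration onto a common epoch grid
#'
#' Builds the detector's working representation: per half-open window
#' `[start, start + epoch_length)`, RMSSD over the retained IBIs whose
#' timestamps fall in the window, and the mean of the acceleration-magnitude
#' samples in the window. An epoch is valid when (a) retained IBIs cover at
#' least `min_epoch_coverage` of the window, (b) at least
#' `min_beats_per_epoch` retained beats fall in it, and (c) an acceleration
#' mean is available. Invalid epochs carry missing RMSSD rather than an
#' interpolated value.
#'
#' The grid is anchored at `origin_s` (default 0) and contains only windows
#' lying entirely within the span common to both streams; partial tail
#' windows form no epoch.
#'
#' @param ibis A cleaned [ibi_stream()] (see [clean_ibis()]).
#' @param accel Data frame with columns `time_s` and `accel_g`
#'   (magnitude samples), or an object coercible to one.
#' @param epoch_length Epoch duration in seconds (default 30).
#' @param policy The [artifact_policy()] supplying the validity thresholds.
#' @param origin_s Grid anchor time (default 0).
#' @return An [epoch_series()].
#' @export
make_epochs <- function(ibis, accel, epoch_length = 30,
                        policy = artifact_policy(), origin_s = 0) {
  stopifnot(inherits(ibis, "ibi_stream"))
  accel <- as.data.frame(accel)
  if (!all(c("time_s", "accel_g") %in% names(accel))) {
    stop("make_epochs: accel needs columns time_s, accel_g", call. = FALSE)
  }
  if (nrow(ibis) == 0 || nrow(accel) == 0) {
    stop("make_epochs: empty input stream", call. = FALSE)
  }
  span_lo <- max(min(ibis$time_s), min(accel$time_s))
  span_hi <- min(max(ibis$time_s), max(accel$time_s))
  if (span_lo >= span_hi) {
    stop("make_epochs: IBI and acceleration streams cover disjoint time spans",
         call. = FALSE)
  }
  first <- origin_s + floor((span_lo - origin_s) / epoch_length) *
    epoch_length
  # windows are complete when they end by the common span end; a leading
  # window that the data only partly covers is kept and left to the
  # coverage rule, but a partial tail forms no epoch
  starts <- seq(from = first, by = epoch_length,
                length.out = max(0, floor((span_hi - first + 1e-9) /
                                            epoch_length)))
  n <- length(starts)
  if (n == 0) {
    stop("make_epochs: streams too short for a single complete epoch",
         call. = FALSE)
  }
  rm_out <- rep(NA_real_, n)
  ac_out <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    lo <- starts[i]; hi <- starts[i] + epoch_length
    in_win <- ibis$time_s >= lo & ibis$time_s < hi
    kept <- in_win & ibis$valid
    coverage <- sum(ibis$ibi_ms[kept]) / 1000 / epoch_length
    a_in <- accel$time_s >= lo & accel$time_s < hi
    if (any(a_in)) ac_out[i] <- mean(accel$accel_g[a_in])
    nb <- sum(kept)
    if (nb >= policy$min_beats_per_epoch &&
        coverage >= policy$min_epoch_coverage && !is.na(ac_out[i])) {
      rm_out[i] <- rmssd(ibis$ibi_ms[kept])
      valid[i] <- TRUE
    }
  }
  epoch_series(starts, rm_out, ac_out, valid = valid,
               person_id = attr(ibis, "person_id"),
               epoch_length = epoch_length)
}
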