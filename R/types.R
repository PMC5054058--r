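#' Construct an interbeat-interval stream
#'
#' An `ibi_stream` is the package's representation of a timestamped sequence of
#' interbeat intervals (IBIs, also called RR intervals) for one person.
#' Timestamps are seconds since recording start and must be strictly
#' increasing; IBIs are milliseconds and must be positive. Each sample carries
#' a `valid` mark; artifact cleaning ([clean_ibis()]) flips marks rather than
#' deleting rows, so epoch coverage stays computable.
#'
#' @param time_s Numeric vector of sample timestamps (seconds), strictly
#'   increasing.
#' @param ibi_ms Numeric vector of interbeat intervals (milliseconds), all
#'   positive.
#' @param person_id Character scalar identifying the person.
#' @param valid Logical vector of validity marks (default all `TRUE`).
#' @return An object of class `ibi_stream`: a data frame with columns
#'   `time_s`, `ibi_ms`, `valid` and a `person_id` attribute.
#' @examples
#' ibi_stream(c(0, 0.8, 1.61), c(800, 810, 805))
#' @export
ibi_stream <- function(time_s, ibi_ms, person_id = "p1", valid = NULL) {
  time_s <- as.numeric(time_s)
  ibi_ms <- as.numeric(ibi_ms)
  if (length(time_s) != length(ibi_ms)) {
    stop("ibi_stream: time_s and ibi_ms must have equal length", call. = FALSE)
  }
  if (is.null(valid)) valid <- rep(TRUE, length(time_s))
  if (anyNA(time_s) || anyNA(ibi_ms)) {
    stop("ibi_stream: timestamps and IBIs must be non-missing", call. = FALSE)
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    bad <- which(diff(time_s) <= 0)[1] + 1
    stop(sprintf("ibi_stream: timestamps not strictly increasing at sample %d",
                 bad), call. = FALSE)
  }
  if (any(ibi_ms <= 0)) {
    stop(sprintf("ibi_stream: non-positive IBI at sample %d",
                 which(ibi_ms <= 0)[1]), call. = FALSE)
  }
  out <- data.frame(time_s = time_s, ibi_ms = ibi_ms,
                    valid = as.logical(valid))
  attr(out, "person_id") <- as.character(person_id)
  class(out) <- c("ibi_stream", "data.frame")
  out
}

#' Construct a 30-s epoch series
#'
#' An `epoch_series` holds aligned fixed-length epochs of RMSSD (ms) and mean
#' acceleration (g) for one person -- the detector's working representation.
#' Epoch windows are half-open `[start, start + epoch_length)`. Epochs with a
#' missing RMSSD or acceleration are always invalid; zero is a meaningful
#' physiological value and is never used to encode missingness.
#'
#' @param start_s Numeric vector of epoch start times (seconds); must form an
#'   arithmetic sequence with step `epoch_length`.
#' @param rmssd_ms Numeric vector of per-epoch RMSSD values (ms), `NA` where
#'   missing.
#' @param accel_g Numeric vector of per-epoch mean acceleration (g), `NA`
#'   where missing.
#' @param valid Logical validity flags; forced to `FALSE` wherever `rmssd_ms`
#'   or `accel_g` is missing. Defaults to "whatever is non-missing".
#' @param person_id Character scalar.
#' @param epoch_length Epoch duration in seconds (default 30).
#' @return An object of class `epoch_series`: a data frame with columns
#'   `start_s`, `rmssd_ms`, `accel_g`, `valid`, plus `person_id` and
#'   `epoch_length` attributes.
#' @examples
#' epoch_series(c(0, 30, 60), c(44, NA, 52), c(0.05, 0.06, 0.05))
#' @export
epoch_series <- function(start_s, rmssd_ms, accel_g, valid = NULL,
                         person_id = "p1", epoch_length = 30) {
  start_s <- as.numeric(start_s)
  rmssd_ms <- as.numeric(rmssd_ms)
  accel_g <- as.numeric(accel_g)
  n <- length(start_s)
  if (length(rmssd_ms) != n || length(accel_g) != n) {
    stop("epoch_series: column lengths differ", call. = FALSE)
  }
  if (n > 1) {
    steps <- diff(start_s)
    if (any(abs(steps - epoch_length) > 1e-9)) {
      bad <- which(abs(steps - epoch_length) > 1e-9)[1] + 1
      stop(sprintf(
        "epoch_series: start times must step by epoch_length (%g s); violated at epoch %d",
        epoch_length, bad), call. = FALSE)
    }
  }
  if (any(rmssd_ms < 0, na.rm = TRUE)) {
    stop("epoch_series: negative RMSSD", call. = FALSE)
  }
  if (any(accel_g < 0, na.rm = TRUE)) {
    stop("epoch_series: negative acceleration", call. = FALSE)
  }
  if (is.null(valid)) valid <- !is.na(rmssd_ms) & !is.na(accel_g)
  valid <- as.logical(valid) & !is.na(rmssd_ms) & !is.na(accel_g)
  out <- data.frame(start_s = start_s, rmssd_ms = rmssd_ms,
                    accel_g = accel_g, valid = valid)
  attr(out, "person_id") <- as.character(person_id)
  attr(out, "epoch_length") <- epoch_length
  class(out) <- c("epoch_series", "data.frame")
  out
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> person %s: %d epochs of %g s (%d valid)\n",
              attr(x, "person_id"), nrow(x), attr(x, "epoch_length"),
              sum(x$valid)))
  invisible(x)
}

#' Phase vocabulary of the scripted calibration protocol
#'
#' The calibration session consists of five scripted activity phases covering
#' a range of metabolic demand: sitting rest, standing, lying down, ergometer
#' cycling, and stair walking.
#' @export
CALIBRATION_PHASES <- c("rest", "standing", "lying", "cycling", "stairs")

#' Construct a calibration session
#'
#' Bundles phase-labelled epochs from the scripted calibration protocol
#' (rest, standing, lying, cycling, stairs). The rest phase is required
#' because resting RMSSD is defined as the mean RMSSD over its epochs.
#' Phases may not overlap and every phase must contain at least one valid
#' epoch. An epoch belongs to a phase when its start time falls inside the
#' half-open phase window `[start_s, end_s)`.
#'
#' @param epochs An [epoch_series()] restricted to the session.
#' @param phases Data frame with columns `label`, `start_s`, `end_s`; labels
#'   drawn from [CALIBRATION_PHASES].
#' @return An object of class `calibration_session`: a list with elements
#'   `person_id`, `phases`, `epochs`.
#' @export
calibration_session <- function(epochs, phases) {
  stopifnot(inherits(epochs, "epoch_series"))
  phases <- validate_phases(phases)
  if (!"rest" %in% phases$label) {
    stop("calibration_session: required 'rest' phase missing", call. = FALSE)
  }
  lab <- phase_of(epochs$start_s, phases)
  for (ph in phases$label) {
    if (!any(epochs$valid[!is.na(lab) & lab == ph])) {
      stop(sprintf("calibration_session: phase '%s' has no valid epoch", ph),
           call. = FALSE)
    }
  }
  structure(list(person_id = attr(epochs, "person_id"),
                 phases = phases, epochs = epochs),
            class = "calibration_session")
}

#' @export
print.calibration_session <- function(x, ...) {
  cat(sprintf("<calibration_session> person %s: %d phases, %d epochs\n",
              x$person_id, nrow(x$phases), nrow(x$epochs)))
  invisible(x)
}

# Validate a phase table: known labels, numeric half-open windows, no overlap.
validate_phases <- function(phases) {
  phases <- as.data.frame(phases)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(phases))) {
    stop("phases: need columns label, start_s, end_s", call. = FALSE)
  }
  phases$label <- as.character(phases$label)
  bad <- setdiff(phases$label, CALIBRATION_PHASES)
  if (length(bad)) {
    stop(sprintf("phases: unknown label '%s' (allowed: %s)", bad[1],
                 paste(CALIBRATION_PHASES, collapse = ", ")), call. = FALSE)
  }
  if (any(phases$end_s <= phases$start_s)) {
    stop("phases: end_s must exceed start_s", call. = FALSE)
  }
  ord <- order(phases$start_s)
  phases <- phases[ord, , drop = FALSE]
  if (nrow(phases) > 1 &&
      any(phases$start_s[-1] < phases$end_s[-nrow(phases)] - 1e-9)) {
    stop("phases: overlapping phase windows", call. = FALSE)
  }
  rownames(phases) <- NULL
  phases
}

# Map epoch start times to phase labels (NA outside every phase window).
phase_of <- function(start_s, phases) {
  lab <- rep(NA_character_, length(start_s))
  for (i in seq_len(nrow(phases))) {
    in_ph <- start_s >= phases$start_s[i] & start_s < phases$end_s[i]
    lab[in_ph] <- phases$label[i]
  }
  lab
}
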