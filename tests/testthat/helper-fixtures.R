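# Shared fixtures and independent oracles, built in code at test time.

# A calibration session with rmssd generated from an exact inverse law
# (optionally with i.i.d. Gaussian noise) on a supplied acceleration grid.
make_session <- function(accel, b0 = 21.56, b1 = 0.471, noise_sd = 0,
                         accel_floor = 0.005, rmssd = NULL,
                         person_id = "p1") {
  n <- length(accel)
  if (is.null(rmssd)) {
    rmssd <- b0 + b1 / pmax(accel, accel_floor)
    if (noise_sd > 0) rmssd <- rmssd + rnorm(n, 0, noise_sd)
    rmssd <- pmax(rmssd, 0)
  }
  ep <- epoch_series(30 * (seq_len(n) - 1), rmssd, accel,
                     person_id = person_id)
  # single covering phase table: first 6 epochs rest, remainder cycling
  n_rest <- min(6, n)
  phases <- data.frame(label = c("rest", if (n > n_rest) "cycling"),
                       start_s = c(0, if (n > n_rest) n_rest * 30),
                       end_s = c(n_rest * 30, if (n > n_rest) n * 30))
  calibration_session(ep, phases)
}

# An "ok" person model with chosen parameters, bypassing fitting, for
# detector unit tests.
make_model <- function(b0 = 30, b1 = 0.5, se = 2, k = 2, min_run = 15,
                       accel_floor = 0.005, status = "ok",
                       person_id = "p1") {
  structure(list(person_id = person_id, b0 = b0, b1 = b1, se = se,
                 r2 = 0.9, b1_pvalue = 1e-6, resting_rmssd = b0 + 10,
                 n_epochs = 30L, status = status, k = k,
                 min_run = as.integer(min_run), accel_floor = accel_floor,
                 error_quantity = "sem"),
            class = "person_model")
}

# A day epoch series with given rmssd/accel vectors (valid unless NA).
make_day <- function(rmssd, accel = rep(0.05, length(rmssd)), start_s = 0,
                     person_id = "p1") {
  epoch_series(start_s + 30 * (seq_along(rmssd) - 1), rmssd, accel,
               person_id = person_id)
}

# Independent run-length oracle: locate maximal runs of TRUE flags by
# grouping the indices of flagged epochs (different mechanism from the
# rle-based detector path).
oracle_runs <- function(flags, min_run) {
  idx <- which(!is.na(flags) & flags)
  if (!length(idx)) {
    return(data.frame(start_index = integer(0), length = integer(0)))
  }
  grp <- cumsum(c(1L, as.integer(diff(idx) != 1L)))
  starts <- tapply(idx, grp, min)
  lens <- tapply(idx, grp, length)
  keep <- lens >= min_run
  data.frame(start_index = as.integer(starts[keep]),
             length = as.integer(lens[keep]), row.names = NULL)
}

# Multi-person hourly table matching given per-person flagged-hour counts.
make_hourly_counts <- function(flagged_per_person, hours_per_person) {
  stopifnot(length(flagged_per_person) == length(hours_per_person),
            all(flagged_per_person <= hours_per_person))
  do.call(rbind, lapply(seq_along(hours_per_person), function(i) {
    nh <- hours_per_person[i]
    data.frame(person_id = sprintf("p%02d", i),
               hour_end_s = 3600 * seq_len(nh),
               add_hrvr = as.integer(seq_len(nh) <= flagged_per_person[i]))
  }))
}
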