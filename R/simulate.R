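#' Simulation configuration
#'
#' The stated world of the synthetic generator, anchored to the regime of
#' ambulatory calibration studies: an inverse movement-to-RMSSD law with
#' population coefficients `Expected RMSSD = 21.56 + 0.471 / acceleration`,
#' calibration RMSSD around 45 ms at sedentary movement near 0.05 g, worry
#' reports on roughly 16 % and stress reports on roughly 7 % of hours.
#' Movement over the day follows a two-state (quiet/bout) renewal process
#' with uniform bout intensities spanning the calibration acceleration
#' range. Suppression plants reduce RMSSD by `depth` multiples of the
#' person's calibration SE below the generating law, so a plant at depth
#' `k` sits exactly at the detection threshold.
#'
#' @param n_persons Number of simulated participants (default 32).
#' @param true_b0,true_b1 Generating inverse-law coefficients (ms; ms*g).
#' @param b0_sd,b1_sd Between-person SDs of the coefficients (default 3 ms
#'   and 0.1 ms*g).
#' @param epoch_noise_sd Gaussian epoch-to-epoch RMSSD noise SD in ms
#'   (default 5).
#' @param epoch_length Epoch duration in seconds (default 30).
#' @param accel_floor Acceleration floor (g) shared with the detector.
#' @param error_quantity Error quantity defining the SE unit for plants and
#'   the fitted detector (`"sem"`, `"sd"`, `"residual_se"`).
#' @param calibration_plan Data frame `label`, `duration_s`, `accel_lo`,
#'   `accel_hi`: per-phase durations and uniform acceleration ranges.
#' @param day_hours Length of the simulated ambulatory day in hours
#'   (default 12, matching an hourly prompting window such as 10:00-22:00).
#' @param quiet_accel_lo,quiet_accel_hi Uniform range of quiet-state
#'   acceleration (g).
#' @param bout_start_prob Per-epoch probability of starting a movement bout
#'   while quiet.
#' @param bout_mean_epochs Mean bout duration in epochs (geometric).
#' @param bout_accel_lo,bout_accel_hi Uniform range of bout intensity (g).
#' @param plant_plan Data frame `start_frac` (fraction of the day),
#'   `length_epochs`, `depth` (multiples of the person's SE). Default: two
#'   20-epoch plants at depth 4.
#' @param plant_prob Probability that each planned plant is instantiated
#'   for a given person (default 0.6). This produces between-person
#'   variation in episode exposure -- with the default two-plant plan about
#'   16 % of persons carry no plant at all and the mean number of
#'   plant-affected hours per person is near 2, the regime ambulatory
#'   studies report. Set to 1 to guarantee every planned plant.
#' @param invalid_prob Per-epoch probability of an invalid (missing) day
#'   epoch (default 0; missingness is normally produced upstream by
#'   artifact cleaning, not by this generator).
#' @param worry_prob_plant,worry_prob_base Probability of a worry report in
#'   hours overlapping vs not overlapping a plant (defaults 0.40 / 0.12,
#'   giving a marginal worry rate near 16 %).
#' @param stress_prob_plant,stress_prob_base Same for stress reports
#'   (defaults 0.15 / 0.055, marginal near 7 %).
#' @param k,min_run Detector parameters carried into fitted models.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_persons = 32,
                       true_b0 = 21.56, true_b1 = 0.471,
                       b0_sd = 3, b1_sd = 0.1,
                       epoch_noise_sd = 5,
                       epoch_length = 30,
                       accel_floor = 0.005,
                       error_quantity = "sem",
                       calibration_plan = default_calibration_plan(),
                       day_hours = 12,
                       quiet_accel_lo = 0.01, quiet_accel_hi = 0.04,
                       bout_start_prob = 0.02, bout_mean_epochs = 6,
                       bout_accel_lo = 0.10, bout_accel_hi = 0.40,
                       plant_plan = data.frame(start_frac = c(0.25, 0.60),
                                               length_epochs = c(20, 20),
                                               depth = c(4, 4)),
                       plant_prob = 0.6,
                       invalid_prob = 0,
                       worry_prob_plant = 0.40, worry_prob_base = 0.12,
                       stress_prob_plant = 0.15, stress_prob_base = 0.055,
                       k = 2, min_run = 15) {
  stopifnot(n_persons >= 1, epoch_noise_sd >= 0, epoch_length > 0,
            day_hours > 0, all(calibration_plan$duration_s > 0),
            invalid_prob >= 0, invalid_prob < 1)
  cfg <- as.list(environment())
  stopifnot(all(c(worry_prob_plant, worry_prob_base, stress_prob_plant,
                  stress_prob_base, plant_prob) >= 0),
            all(c(worry_prob_plant, worry_prob_base, stress_prob_plant,
                  stress_prob_base, plant_prob) <= 1))
  if (nrow(plant_plan)) {
    stopifnot(all(plant_plan$length_epochs > 0), all(plant_plan$depth > 0),
              all(plant_plan$start_frac >= 0 & plant_plan$start_frac < 1))
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_calibration_plan <- function() {
  data.frame(label = c("rest", "standing", "lying", "cycling", "stairs"),
             duration_s = c(180, 180, 180, 180, 180),
             accel_lo = c(0.010, 0.020, 0.008, 0.100, 0.200),
             accel_hi = c(0.030, 0.060, 0.020, 0.250, 0.400))
}

# The generating law shared by calibration and day simulation.
inverse_law <- function(accel, b0, b1, floor_g) {
  b0 + b1 / pmax(accel, floor_g)
}

#' Simulate a scripted calibration session
#'
#' Walks the configured phase plan: per 30-s epoch, acceleration is drawn
#' uniformly from the phase's range and RMSSD from the inverse law plus
#' Gaussian epoch noise. Fully reproducible from `person_seed`.
#'
#' @param cfg A [sim_config()].
#' @param person_seed Integer seed for this person's calibration.
#' @param person_id Person identifier.
#' @param b0,b1 Person-level generating coefficients; default to the
#'   population values in `cfg`.
#' @return A [calibration_session()].
#' @export
simulate_calibration <- function(cfg, person_seed = 1, person_id = "p1",
                                 b0 = cfg$true_b0, b1 = cfg$true_b1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(person_seed)
  plan <- cfg$calibration_plan
  L <- cfg$epoch_length
  starts <- numeric(0); accel <- numeric(0); lab_n <- integer(0)
  t0 <- 0
  phases <- data.frame(label = plan$label, start_s = NA_real_,
                       end_s = NA_real_)
  for (i in seq_len(nrow(plan))) {
    n_ep <- floor(plan$duration_s[i] / L)
    phases$start_s[i] <- t0
    phases$end_s[i] <- t0 + n_ep * L
    starts <- c(starts, t0 + L * (seq_len(n_ep) - 1))
    accel <- c(accel, stats::runif(n_ep, plan$accel_lo[i], plan$accel_hi[i]))
    t0 <- t0 + n_ep * L
  }
  law <- inverse_law(accel, b0, b1, cfg$accel_floor)
  rm_ms <- pmax(law + stats::rnorm(length(law), 0, cfg$epoch_noise_sd), 0)
  ep <- epoch_series(starts, rm_ms, accel, person_id = person_id,
                     epoch_length = L)
  calibration_session(ep, phases)
}

#' Simulate an ambulatory day with planted suppression episodes
#'
#' Generates a day-long epoch grid. Movement follows a two-state renewal
#' process: quiet epochs draw acceleration from the quiet range; bouts start
#' with probability `bout_start_prob` per quiet epoch, last a geometric
#' number of epochs (mean `bout_mean_epochs`) and draw acceleration around a
#' per-bout uniform intensity. Baseline RMSSD follows the person's inverse
#' law plus Gaussian epoch noise; within each planted window RMSSD is
#' pinned at `depth` multiples of the person's SE below the law (epoch
#' noise suppressed), so the plant depth is exact in the units of the
#' detection threshold: a depth-`k` plant sits exactly at the threshold
#' and ties are, by convention, not flagged.
#'
#' @param cfg A [sim_config()].
#' @param person_truth List with elements `b0`, `b1`, `se` (the person's
#'   generating coefficients and SE unit); see [simulate_person()].
#' @param person_seed Integer seed.
#' @param person_id Person identifier.
#' @param day_start_s Start time of the day grid (default 0).
#' @return List with `day` (an [epoch_series()]) and `truth` (a
#'   `synthetic_truth`: generating parameters, planted windows, hour-level
#'   truth flags).
#' @export
simulate_day <- function(cfg, person_truth, person_seed = 1,
                         person_id = "p1", day_start_s = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(person_seed)
  L <- cfg$epoch_length
  n <- as.integer(round(cfg$day_hours * 3600 / L))
  starts <- day_start_s + L * (seq_len(n) - 1)

  plants <- plant_windows(cfg$plant_plan, n)
  if (nrow(plants) && cfg$plant_prob < 1) {
    plants <- plants[stats::runif(nrow(plants)) < cfg$plant_prob, ,
                     drop = FALSE]
  }

  # two-state movement process
  accel <- numeric(n)
  in_bout <- FALSE; bout_left <- 0L; bout_mid <- NA_real_
  for (i in seq_len(n)) {
    if (!in_bout && stats::runif(1) < cfg$bout_start_prob) {
      in_bout <- TRUE
      bout_left <- 1L + stats::rgeom(1, 1 / cfg$bout_mean_epochs)
      bout_mid <- stats::runif(1, cfg$bout_accel_lo, cfg$bout_accel_hi)
    }
    if (in_bout) {
      jit <- 0.1 * (cfg$bout_accel_hi - cfg$bout_accel_lo)
      accel[i] <- max(stats::runif(1, bout_mid - jit, bout_mid + jit),
                      cfg$quiet_accel_lo)
      bout_left <- bout_left - 1L
      if (bout_left <= 0L) in_bout <- FALSE
    } else {
      accel[i] <- stats::runif(1, cfg$quiet_accel_lo, cfg$quiet_accel_hi)
    }
  }

  law <- inverse_law(accel, person_truth$b0, person_truth$b1,
                     cfg$accel_floor)
  rm_ms <- law + stats::rnorm(n, 0, cfg$epoch_noise_sd)

  for (j in seq_len(nrow(plants))) {
    idx <- seq(plants$start_index[j],
               plants$start_index[j] + plants$length[j] - 1)
    # plants pin RMSSD at the stated suppression level (epoch noise
    # suppressed inside the window) so that depth is exact in threshold
    # units: depth k sits exactly at the detection threshold and, by the
    # strict-inequality tie rule, is not flagged
    rm_ms[idx] <- law[idx] - plants$depth[j] * person_truth$se
  }
  rm_ms <- pmax(rm_ms, 0)

  valid <- rep(TRUE, n)
  if (cfg$invalid_prob > 0) {
    valid <- stats::runif(n) >= cfg$invalid_prob
  }
  rm_out <- ifelse(valid, rm_ms, NA_real_)

  day <- epoch_series(starts, rm_out, accel, valid = valid,
                      person_id = person_id, epoch_length = L)
  plants$start_s <- starts[plants$start_index]
  hour_ends <- hour_grid(day_start_s + 3600, cfg$day_hours)
  hour_truth <- vapply(hour_ends, function(he) {
    any(plants$start_s < he &
          plants$start_s + plants$length * L > he - 3600)
  }, logical(1))
  truth <- structure(list(person_id = person_id, b0 = person_truth$b0,
                          b1 = person_truth$b1, se_true = person_truth$se,
                          plants = plants, hour_ends = hour_ends,
                          hour_truth = as.integer(hour_truth)),
                     class = "synthetic_truth")
  list(day = day, truth = truth)
}

# Resolve the plant plan to epoch indices on an n-epoch grid and check
# windows fit the day and do not overlap.
plant_windows <- function(plan, n) {
  if (is.null(plan) || nrow(plan) == 0) {
    return(data.frame(start_index = integer(0), length = integer(0),
                      depth = numeric(0)))
  }
  out <- data.frame(start_index = pmax(1L, 1L + as.integer(floor(plan$start_frac * n))),
                    length = as.integer(plan$length_epochs),
                    depth = plan$depth)
  out <- out[order(out$start_index), , drop = FALSE]
  if (any(out$start_index + out$length - 1 > n)) {
    stop("plant plan: window extends past the simulated day", call. = FALSE)
  }
  if (nrow(out) > 1 &&
      any(out$start_index[-1] <= out$start_index[-nrow(out)] +
            out$length[-nrow(out)] - 1)) {
    stop("plant plan: overlapping plant windows", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Simulate hourly self-reports coupled to planted episodes
#'
#' Per hour of the simulated day, worry and stress indicators are Bernoulli
#' draws whose probability depends on whether the hour overlaps a planted
#' suppression window; positive hours get a count of `1 + Poisson(0.3)`
#' episodes. Affect ratings are Gaussian around anchored means with a
#' plant-dependent shift (explicit positive affect lowered, negative affect
#' raised in plant hours), truncated to their rating scales.
#'
#' @param truth A `synthetic_truth` from [simulate_day()].
#' @param cfg A [sim_config()].
#' @param person_seed Integer seed.
#' @return An hourly report data frame (see [read_hourly_reports()]).
#' @export
simulate_reports <- function(truth, cfg, person_seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(cfg, "sim_config"))
  set.seed(person_seed)
  on_plant <- truth$hour_truth == 1
  nh <- length(truth$hour_ends)
  draw_count <- function(p_plant, p_base) {
    p <- ifelse(on_plant, p_plant, p_base)
    hit <- stats::runif(nh) < p
    ifelse(hit, 1L + stats::rpois(nh, 0.3), 0L)
  }
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  out <- data.frame(
    hour_end_s = truth$hour_ends,
    worry_count = draw_count(cfg$worry_prob_plant, cfg$worry_prob_base),
    stress_count = draw_count(cfg$stress_prob_plant, cfg$stress_prob_base),
    explicit_pa = clip(stats::rnorm(nh, 4.0 - 0.5 * on_plant, 1.2), 1, 6),
    explicit_na = clip(stats::rnorm(nh, 1.88 + 0.3 * on_plant, 0.78), 1, 6),
    implicit_pa = clip(stats::rnorm(nh, 3.34 - 0.2 * on_plant, 1.25), 1, 6),
    implicit_na = clip(stats::rnorm(nh, 2.85 + 0.2 * on_plant, 1.13), 1, 6))
  attr(out, "person_id") <- truth$person_id
  out
}

#' Score detected episodes against planted truth
#'
#' Episode-level sensitivity is the fraction of planted windows overlapped
#' (in epoch indices) by at least one detected episode; precision is the
#' fraction of detected episodes overlapping at least one plant (missing
#' when nothing was detected). Hour-level confusion counts compare the
#' planted hour flags with the coded hours.
#'
#' @param truth A `synthetic_truth`.
#' @param detected An `episode_set` from [detect_episodes()].
#' @param hourly Optional `hourly_coding` for the same day; enables the
#'   hour-level confusion counts.
#' @return List with `sensitivity`, `precision`, `n_plants`, `n_detected`,
#'   and (given `hourly`) `hour_confusion` (`tp`, `fp`, `fn`, `tn`).
#' @export
evaluate_recovery <- function(truth, detected, hourly = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(detected, "episode_set"))
  pl <- truth$plants
  ep <- detected$episodes
  overlaps <- function(s1, l1, s2, l2) {
    s1 <= s2 + l2 - 1 & s2 <= s1 + l1 - 1
  }
  plant_hit <- vapply(seq_len(nrow(pl)), function(i) {
    nrow(ep) > 0 && any(overlaps(pl$start_index[i], pl$length[i],
                                 ep$start_index, ep$length))
  }, logical(1))
  epi_hit <- vapply(seq_len(nrow(ep)), function(j) {
    nrow(pl) > 0 && any(overlaps(ep$start_index[j], ep$length[j],
                                 pl$start_index, pl$length))
  }, logical(1))
  out <- list(
    sensitivity = if (nrow(pl)) mean(plant_hit) else NA_real_,
    precision = if (nrow(ep)) mean(epi_hit) else NA_real_,
    n_plants = nrow(pl), n_detected = nrow(ep))
  if (!is.null(hourly)) {
    stopifnot(nrow(hourly) == length(truth$hour_truth))
    if (any(abs(hourly$hour_end_s - truth$hour_ends) > 1e-6)) {
      stop("evaluate_recovery: hour grids differ between truth and coding",
           call. = FALSE)
    }
    t1 <- truth$hour_truth == 1
    d1 <- hourly$add_hrvr == 1
    out$hour_confusion <- c(tp = sum(t1 & d1), fp = sum(!t1 & d1),
                            fn = sum(t1 & !d1), tn = sum(!t1 & !d1))
  }
  out
}

#' Simulate one person end to end
#'
#' Calibration session, fitted person model, ambulatory day with plants, and
#' hourly reports, all derived deterministically from one seed. Person-level
#' coefficients are drawn around the population values (`b0_sd`, `b1_sd`,
#' truncated so `b1` stays positive). The SE unit used for plant depths is
#' the same error quantity the fitted detector uses, computed from the
#' simulated calibration epochs, so plant depth `k` sits exactly at the
#' threshold when the fit is exact.
#'
#' @param cfg A [sim_config()].
#' @param person_id Person identifier.
#' @param person_seed Integer seed.
#' @return List: `calibration`, `model` (fitted `person_model`), `day`,
#'   `truth`, `reports`.
#' @export
simulate_person <- function(cfg, person_id = "p1", person_seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(person_seed)
  b0 <- stats::rnorm(1, cfg$true_b0, cfg$b0_sd)
  b1 <- max(stats::rnorm(1, cfg$true_b1, cfg$b1_sd), 0.05)
  calib <- simulate_calibration(cfg, person_seed = person_seed + 1L,
                                person_id = person_id, b0 = b0, b1 = b1)
  model <- fit_inverse_model(calib, accel_floor = cfg$accel_floor,
                             error_quantity = cfg$error_quantity,
                             k = cfg$k, min_run = cfg$min_run)
  ep <- calib$epochs
  y <- ep$rmssd_ms[ep$valid]
  se_true <- switch(cfg$error_quantity,
                    sem = stats::sd(y) / sqrt(length(y)),
                    sd = stats::sd(y),
                    residual_se = {
                      x <- 1 / pmax(ep$accel_g[ep$valid], cfg$accel_floor)
                      summary(stats::lm(y ~ x))$sigma
                    })
  sim <- simulate_day(cfg, list(b0 = b0, b1 = b1, se = se_true),
                      person_seed = person_seed + 2L, person_id = person_id)
  reports <- simulate_reports(sim$truth, cfg, person_seed = person_seed + 3L)
  list(calibration = calib, model = model, day = sim$day,
       truth = sim$truth, reports = reports)
}

#' Simulate a complete multi-person study
#'
#' Runs [simulate_person()] for `cfg$n_persons` participants with seeds
#' derived from one master seed, applies detection with each fitted model
#' (persons whose calibration is excluded by the quality gate contribute no
#' detection rows, mirroring participant exclusion), and stacks the results.
#'
#' @param cfg A [sim_config()].
#' @param seed Master seed (integer).
#' @return List: `persons` (per-person results incl. `detection`), `hourly`
#'   (stacked detection/report table across included persons), `models`,
#'   `summary` (per-person aggregates from [aggregate_persons()]).
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1) {
  persons <- vector("list", cfg$n_persons)
  hourly_all <- list()
  reports_all <- list()
  for (i in seq_len(cfg$n_persons)) {
    pid <- sprintf("p%02d", i)
    pseed <- (as.integer(seed) %% 100000L) * 10000L + i * 10L
    res <- simulate_person(cfg, person_id = pid, person_seed = pseed)
    if (identical(res$model$status, "ok")) {
      det <- detect_person(res$model, res$day,
                           hour_ends = res$truth$hour_ends)
      res$detection <- det
      h <- as.data.frame(det$hourly)
      h <- cbind(person_id = pid, h)
      hourly_all[[length(hourly_all) + 1]] <- h
      r <- cbind(person_id = pid, as.data.frame(res$reports))
      reports_all[[length(reports_all) + 1]] <- r
    }
    persons[[i]] <- res
  }
  hourly <- if (length(hourly_all)) do.call(rbind, hourly_all) else NULL
  reports <- if (length(reports_all)) do.call(rbind, reports_all) else NULL
  joined <- if (!is.null(hourly)) join_hourly(hourly, reports) else NULL
  list(persons = persons,
       models = lapply(persons, `[[`, "model"),
       hourly = joined,
       summary = if (!is.null(joined))
         aggregate_persons(hourly, reports) else NULL)
}
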