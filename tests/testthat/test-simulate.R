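cfg_small <- function(...) {
  sim_config(n_persons = 2, day_hours = 4, plant_prob = 1,
             plant_plan = data.frame(start_frac = 0.3, length_epochs = 20,
                                     depth = 4), ...)
}

test_that("simulation is fully deterministic given (cfg, seed)", {
  cfg <- cfg_small()
  a <- simulate_person(cfg, "p1", 42)
  b <- simulate_person(cfg, "p1", 42)
  expect_identical(a$calibration$epochs$rmssd_ms,
                   b$calibration$epochs$rmssd_ms)
  expect_identical(a$day$rmssd_ms, b$day$rmssd_ms)
  expect_identical(a$day$accel_g, b$day$accel_g)
  expect_identical(a$reports, b$reports)
  c <- simulate_person(cfg, "p1", 43)
  expect_false(identical(a$day$rmssd_ms, c$day$rmssd_ms))
})

test_that("noiseless sessions are exactly identifiable", {
  cfg <- sim_config(epoch_noise_sd = 0, b0_sd = 0, b1_sd = 0)
  sess <- simulate_calibration(cfg, person_seed = 5)
  m <- fit_inverse_model(sess, accel_floor = cfg$accel_floor)
  expect_equal(m$b0, cfg$true_b0, tolerance = 1e-8)
  expect_equal(m$b1, cfg$true_b1, tolerance = 1e-8)
})

test_that("simulated calibration sits in a plausible physiological band", {
  cfg <- sim_config()
  rmssd_means <- vapply(1:20, function(r) {
    mean(simulate_calibration(cfg, person_seed = r)$epochs$rmssd_ms)
  }, numeric(1))
  expect_true(all(rmssd_means > 30 & rmssd_means < 60))
  accel_means <- vapply(1:20, function(r) {
    mean(simulate_calibration(cfg, person_seed = r)$epochs$accel_g)
  }, numeric(1))
  expect_true(all(accel_means > 0.02 & accel_means < 0.25))
})

test_that("plant bookkeeping validates windows and records truth", {
  cfg <- cfg_small()
  res <- simulate_person(cfg, "p1", 7)
  pl <- res$truth$plants
  expect_equal(nrow(pl), 1)
  expect_equal(pl$length, 20)
  n_epochs <- nrow(res$day)
  expect_lte(pl$start_index + pl$length - 1, n_epochs)
  # hour truth flags exactly the hours the plant window intersects
  L <- 30
  hit <- vapply(res$truth$hour_ends, function(he) {
    pl$start_s < he && pl$start_s + pl$length * L > he - 3600
  }, logical(1))
  expect_equal(res$truth$hour_truth, as.integer(hit))

  over <- sim_config(day_hours = 4, plant_prob = 1,
                     plant_plan = data.frame(start_frac = c(0.3, 0.31),
                                             length_epochs = c(20, 20),
                                             depth = c(4, 4)))
  expect_error(simulate_person(over, "p1", 7), "overlap")
  past <- sim_config(day_hours = 4, plant_prob = 1,
                     plant_plan = data.frame(start_frac = 0.99,
                                             length_epochs = 20, depth = 4))
  expect_error(simulate_person(past, "p1", 7), "past")
})

test_that("planted suppressions are detected; ties and short plants are not", {
  cfg <- cfg_small()
  hits <- 0; n_ok <- 0
  for (r in 1:25) {
    res <- simulate_person(cfg, "p1", 100 + r)
    if (res$model$status != "ok") next
    n_ok <- n_ok + 1
    det <- detect_person(res$model, res$day, hour_ends = res$truth$hour_ends)
    ev <- evaluate_recovery(res$truth, det$episodes, det$hourly)
    if (!is.na(ev$sensitivity) && ev$sensitivity == 1) hits <- hits + 1
  }
  expect_gte(n_ok, 20)
  expect_gte(hits / n_ok, 0.9)  # scaled-down power regression

  # a depth-k plant sits exactly at the detection threshold
  tie <- sim_config(day_hours = 4, plant_prob = 1, epoch_noise_sd = 0,
                    b0_sd = 0, b1_sd = 0,
                    plant_plan = data.frame(start_frac = 0.3,
                                            length_epochs = 20, depth = 2))
  res <- simulate_person(tie, "p1", 11)
  pl <- res$truth$plants
  idx <- pl$start_index:(pl$start_index + pl$length - 1)
  thr <- threshold(res$model, res$day$accel_g[idx])
  expect_equal(res$day$rmssd_ms[idx], thr, tolerance = 1e-8)

  # plants shorter than min_run yield no episode at that plant (noiseless)
  short <- sim_config(day_hours = 4, plant_prob = 1, epoch_noise_sd = 0,
                      b0_sd = 0,
                      b1_sd = 0,
                      plant_plan = data.frame(start_frac = 0.3,
                                              length_epochs = 10,
                                              depth = 6))
  res2 <- simulate_person(short, "p1", 11)
  det2 <- detect_person(res2$model, res2$day,
                        hour_ends = res2$truth$hour_ends)
  expect_equal(nrow(det2$episodes$episodes), 0)
})

test_that("without plants the detector stays quiet at default noise", {
  cfg <- sim_config(day_hours = 4,
                    plant_plan = data.frame(start_frac = numeric(0),
                                            length_epochs = integer(0),
                                            depth = numeric(0)))
  fp_hours <- 0; total <- 0
  for (r in 1:15) {
    res <- simulate_person(cfg, "p1", 300 + r)
    if (res$model$status != "ok") next
    det <- detect_person(res$model, res$day, hour_ends = res$truth$hour_ends)
    fp_hours <- fp_hours + sum(det$hourly$add_hrvr)
    total <- total + nrow(det$hourly)
  }
  expect_equal(fp_hours / total, 0)  # frozen regression value
})

test_that("report base rates and coupling behave as configured", {
  # zero plants: marginal rates match configured base rates within
  # binomial error
  cfg <- sim_config(day_hours = 12,
                    plant_plan = data.frame(start_frac = numeric(0),
                                            length_epochs = integer(0),
                                            depth = numeric(0)))
  worry <- 0; stress <- 0; n <- 0
  for (r in 1:60) {
    res <- simulate_person(cfg, sprintf("p%d", r), 500 + r)
    worry <- worry + sum(res$reports$worry_count > 0)
    stress <- stress + sum(res$reports$stress_count > 0)
    n <- n + nrow(res$reports)
  }
  expect_equal(worry / n, 0.12, tolerance = 0.25)
  expect_equal(stress / n, 0.055, tolerance = 0.35)
  # affect ratings stay on their scales
  res <- simulate_person(cfg, "p1", 501)
  expect_true(all(res$reports$explicit_pa >= 1 &
                    res$reports$explicit_pa <= 6))
})

test_that("strong worry coupling yields a positive person-level correlation", {
  cfg <- sim_config(n_persons = 40, day_hours = 6,
                    worry_prob_plant = 0.8, worry_prob_base = 0.1,
                    plant_plan = data.frame(start_frac = c(0.2, 0.6),
                                            length_epochs = c(20, 20),
                                            depth = c(4, 4)))
  st <- simulate_study(cfg, seed = 17)
  s <- st$summary
  ok <- !is.na(s$total_worry_episodes)
  r <- pearson_cor(s$total_addhrvr_hours[ok], s$total_worry_episodes[ok])
  expect_gt(r$r, 0)
  expect_lt(r$p, 0.05)
})

test_that("evaluate_recovery scores hand-constructed configurations", {
  truth <- structure(list(person_id = "p1", b0 = 21, b1 = 0.5, se_true = 2,
                          plants = data.frame(start_index = c(10, 100),
                                              length = c(20, 20),
                                              depth = c(4, 4),
                                              start_s = c(270, 2970)),
                          hour_ends = hour_grid(3600, 2),
                          hour_truth = c(1L, 1L)),
                     class = "synthetic_truth")
  mk_eps <- function(starts, lengths) {
    structure(list(person_id = "p1",
                   episodes = data.frame(start_index = starts,
                                         start_s = (starts - 1) * 30,
                                         length = lengths),
                   flags = logical(0), epoch_length = 30,
                   first_epoch_start_s = 0, min_run = 15L),
              class = "episode_set")
  }
  # exact recovery
  ev <- evaluate_recovery(truth, mk_eps(c(10, 100), c(20, 20)))
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$precision, 1)
  # nothing detected: sensitivity 0, precision missing
  ev0 <- evaluate_recovery(truth, mk_eps(integer(0), integer(0)))
  expect_equal(ev0$sensitivity, 0)
  expect_true(is.na(ev0$precision))
  # one of two plants found, no false alarm
  ev1 <- evaluate_recovery(truth, mk_eps(12, 18))
  expect_equal(ev1$sensitivity, 0.5)
  expect_equal(ev1$precision, 1)
  # false alarm only
  ev2 <- evaluate_recovery(truth, mk_eps(200, 20))
  expect_equal(ev2$sensitivity, 0)
  expect_equal(ev2$precision, 0)
})

test_that("the simulated study pipeline closes end to end", {
  st <- simulate_study(sim_config(n_persons = 3, day_hours = 4), seed = 9)
  expect_length(st$persons, 3)
  expect_true(!is.null(st$hourly))
  expect_true(all(c("add_hrvr", "worry_count") %in% names(st$hourly)))
  d <- decompose_within_between(st$hourly)
  expect_equal(d$add_hrvr_between + d$add_hrvr_within, d$add_hrvr)
  expect_equal(nrow(st$summary), sum(vapply(st$models, function(m)
    identical(m$status, "ok"), logical(1))))
})
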