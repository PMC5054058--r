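test_that("expected_rmssd and threshold follow the model arithmetic", {
  m <- make_model(b0 = 21.56, b1 = 0.471)
  expect_equal(expected_rmssd(m, 0.471), 22.56)
  # flat model: any acceleration returns b0
  flat <- make_model(b0 = 30, b1 = 0)
  expect_equal(expected_rmssd(flat, c(0.01, 0.1, 1)), rep(30, 3))
  # acceleration below the floor behaves as the floor
  expect_equal(expected_rmssd(m, 0.001), expected_rmssd(m, m$accel_floor))
  expect_equal(expected_rmssd(m, 0), 21.56 + 0.471 / 0.005)

  m2 <- make_model(b0 = 30, b1 = 0, se = 2, k = 2)
  expect_equal(threshold(m2, 0.05), 26)
  expect_equal(threshold(m2, 0.05, k = 0), 30)
  m3 <- make_model(b0 = 30, b1 = 0, se = 0)
  expect_equal(threshold(m3, 0.05), expected_rmssd(m3, 0.05))

  # expected rmssd non-increasing in acceleration when b1 > 0
  a <- sort(runif(50, 0, 0.5))
  expect_true(all(diff(expected_rmssd(m, a)) <= 1e-12))
})

test_that("excluded models cannot be used for detection", {
  bad <- make_model(status = "excluded_low_r2")
  expect_error(expected_rmssd(bad, 0.05), "excluded")
  expect_error(flag_epochs(bad, make_day(c(40, 40))), "excluded")
})

test_that("flag_epochs uses strict inequality and propagates invalidity", {
  m <- make_model(b0 = 30, b1 = 0, se = 2, k = 2)  # threshold 26 everywhere
  day <- make_day(c(25.9, 26, 26.1, NA, 10), accel = rep(0.05, 5))
  fl <- flag_epochs(m, day)
  expect_identical(fl, c(TRUE, FALSE, FALSE, NA, TRUE))
  # high movement does not exempt a suppressed epoch
  deep <- make_day(5, accel = 0.4)
  expect_true(flag_epochs(make_model(b0 = 30, b1 = 0.5, se = 2), deep))
})

test_that("detect_episodes keeps maximal runs of at least min_run", {
  f <- function(x) detect_episodes(x, min_run = 15)$episodes
  expect_equal(nrow(f(rep(TRUE, 15))), 1)
  expect_equal(f(rep(TRUE, 15))$length, 15)
  expect_equal(nrow(f(c(rep(TRUE, 14), FALSE))), 0)
  e <- f(rep(TRUE, 40))
  expect_equal(nrow(e), 1)
  expect_equal(e$length, 40)
  # missing flags break runs
  broken <- c(rep(TRUE, 10), NA, rep(TRUE, 10))
  expect_equal(nrow(f(broken)), 0)
  # start time bookkeeping
  e2 <- detect_episodes(c(FALSE, rep(TRUE, 16)), min_run = 15,
                        epoch_length = 30, start_s = 600)
  expect_equal(e2$episodes$start_index, 2)
  expect_equal(e2$episodes$start_s, 630)
})

test_that("max_gap bridges short gaps without fabricating starts or ends", {
  flags <- c(rep(TRUE, 8), FALSE, rep(TRUE, 8))
  expect_equal(nrow(detect_episodes(flags, min_run = 15)$episodes), 0)
  e <- detect_episodes(flags, min_run = 15, max_gap = 1)$episodes
  expect_equal(nrow(e), 1)
  expect_equal(e$start_index, 1)
  expect_equal(e$length, 17)
  # a gap wider than max_gap still breaks
  flags2 <- c(rep(TRUE, 8), FALSE, FALSE, rep(TRUE, 8))
  expect_equal(nrow(detect_episodes(flags2, min_run = 15,
                                    max_gap = 1)$episodes), 0)
  # leading/trailing non-flags are never absorbed
  flags3 <- c(FALSE, rep(TRUE, 15), FALSE)
  e3 <- detect_episodes(flags3, min_run = 15, max_gap = 2)$episodes
  expect_equal(e3$start_index, 2)
  expect_equal(e3$length, 15)
})

test_that("detect_episodes matches the independent run oracle on random sequences", {
  set.seed(2024)
  for (case in 1:300) {
    n <- sample(1:400, 1)
    flags <- sample(c(TRUE, FALSE, NA), n, replace = TRUE,
                    prob = c(0.55, 0.3, 0.15))
    min_run <- sample(1:20, 1)
    got <- detect_episodes(flags, min_run = min_run)$episodes
    want <- oracle_runs(flags, min_run)
    expect_equal(got$start_index, want$start_index)
    expect_equal(got$length, want$length)
  }
})

test_that("flag/episode monotonicity properties hold", {
  set.seed(77)
  m <- make_model(b0 = 40, b1 = 0.4, se = 3)
  rm_vals <- runif(200, 20, 60)
  accel <- runif(200, 0.01, 0.4)
  day <- make_day(rm_vals, accel)
  fl <- flag_epochs(m, day)
  # decreasing an epoch's rmssd never unsets its flag
  day2 <- make_day(rm_vals - 5, accel)
  fl2 <- flag_epochs(m, day2)
  expect_true(all(fl2[fl]))
  # increasing k never increases the number of flagged epochs
  expect_lte(sum(flag_epochs(m, day, k = 3), na.rm = TRUE),
             sum(fl, na.rm = TRUE))
  # increasing min_run never increases the episode count
  flags <- sample(c(TRUE, FALSE), 500, replace = TRUE, prob = c(0.8, 0.2))
  counts <- vapply(1:25, function(mr)
    nrow(detect_episodes(flags, min_run = mr)$episodes), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("code_hours marks every hour an episode intersects", {
  # 12-hour day, one episode wholly inside hour 3
  rm_vals <- rep(50, 12 * 120)
  day <- make_day(rm_vals)
  ep <- detect_episodes(c(rep(FALSE, 260), rep(TRUE, 20),
                          rep(FALSE, 12 * 120 - 280)), min_run = 15)
  hours <- hour_grid(3600, 12)
  hc <- code_hours(ep, day, hours)
  expect_equal(hc$add_hrvr, as.integer(seq_len(12) == 3))
  expect_equal(hc$n_episodes[3], 1)
  expect_equal(hc$n_valid_epochs, rep(120L, 12))
  expect_equal(hc$mean_rmssd, rep(50, 12))

  # episode straddling hours 3-4 codes both
  ep2 <- detect_episodes(c(rep(FALSE, 350), rep(TRUE, 20),
                           rep(FALSE, 12 * 120 - 370)), min_run = 15)
  expect_equal(code_hours(ep2, day, hours)$add_hrvr,
               as.integer(seq_len(12) %in% c(3, 4)))

  # no episodes: all hours 0
  ep0 <- detect_episodes(rep(FALSE, 12 * 120), min_run = 15)
  expect_true(all(code_hours(ep0, day, hours)$add_hrvr == 0))

  # completion attribution credits only the hour of the 15th epoch
  hc3 <- code_hours(ep2, day, hours, attribution = "completion")
  expect_equal(hc3$add_hrvr, as.integer(seq_len(12) == 4))
})

test_that("every episode contributes to at least one hour", {
  set.seed(31)
  for (i in 1:20) {
    flags <- sample(c(TRUE, FALSE), 480, replace = TRUE, prob = c(0.7, 0.3))
    day <- make_day(rep(50, 480))
    ep <- detect_episodes(flags, min_run = 10)
    hc <- code_hours(ep, day, hour_grid(3600, 4))
    expect_gte(sum(hc$n_episodes), nrow(ep$episodes))
    expect_lte(sum(hc$add_hrvr), nrow(hc))
    if (nrow(ep$episodes) == 0) expect_true(all(hc$add_hrvr == 0))
  }
})
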