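test_that("all generators are deterministic under a fixed seed", {
  w1 <- simulate_walk(seed = 42, duration_s = 10)
  w2 <- simulate_walk(seed = 42, duration_s = 10)
  expect_identical(w1$recording$z, w2$recording$z)
  expect_false(identical(simulate_walk(seed = 43, duration_s = 10)$recording$z,
                         w1$recording$z))
  n1 <- simulate_nonwalk(7, seed = 5, duration_s = 20)
  n2 <- simulate_nonwalk(7, seed = 5, duration_s = 20)
  expect_identical(n1$recording$x, n2$recording$x)
  s1 <- simulate_treadmill_session(seed = 3, duration_each = 15)
  s2 <- simulate_treadmill_session(seed = 3, duration_each = 15)
  expect_identical(s1$recording$z, s2$recording$z)
  c1 <- simulate_cohort(cohort_spec(n_subjects = 5, seed = 4))
  c2 <- simulate_cohort(cohort_spec(n_subjects = 5, seed = 4))
  expect_identical(c1$subjects, c2$subjects)
})

test_that("noise-free single-harmonic walking matches the count oracle", {
  p <- gait_params(harmonics = c(0, 0), cycle_asymmetry = 0,
                   noise_sd = 0, amplitude = 0.3)
  w <- simulate_walk(p, duration_s = 20, seed = 1)
  ct <- walkcounts:::epoch_counts_all(w$recording)
  # rectified sinusoid integral (2/pi) A T on each axis, horizontal axes
  # attenuated by 0.5 and 0.3
  expected <- (2 / pi) * 0.3 * 5 * (1 + 0.5 + 0.3)
  expect_equal(mean(ct$counts), expected, tolerance = 0.01)
})

test_that("walking vector magnitude is periodic at the step frequency", {
  w <- simulate_walk(duration_s = 60, seed = 7)
  vm <- vector_magnitude(w$recording)
  ac <- as.numeric(acf(vm, lag.max = 120, plot = FALSE)$acf)[-1]
  step_lag <- 60 / 1.8
  # a local autocorrelation maximum within one sample of fs/step_freq
  win <- round(step_lag) + (-1:1)
  expect_true(any(diff(sign(diff(ac[(min(win) - 1):(max(win) + 1)]))) == -2))
  expect_gt(max(ac[win]), 0.3)
})

test_that("nonwalk intensity targeting is accurate and aperiodic", {
  nw <- simulate_nonwalk(7, duration_s = 600, seed = 4)
  ct <- walkcounts:::epoch_counts_all(nw$recording)
  cpm <- mean(ct$rate) * 60
  expect_gt(cpm, 6.3); expect_lt(cpm, 7.7)
  expect_true(all(nw$truth$truth == "nonwalk"))
  # no dominant periodicity: autocorrelation sidelobes stay low
  vm <- vector_magnitude(nw$recording)
  ac <- as.numeric(acf(vm, lag.max = 240, plot = FALSE)$acf)[-(1:5)]
  expect_lt(max(abs(ac)), 0.5)
  # zero target: motionless, all epochs inactive
  n0 <- simulate_nonwalk(0, duration_s = 60, seed = 4)
  ct0 <- walkcounts:::epoch_counts_all(n0$recording)
  expect_true(all(ct0$inactive))
  expect_true(all(n0$truth$truth == "inactive"))
})

test_that("treadmill sessions expose monotone speed-intensity structure", {
  sess <- simulate_treadmill_session(seed = 11)
  expect_identical(nrow(sess$truth), 144L)   # 4 x 180 s / 5 s
  cal <- get_calibration()
  ft <- epoch_feature_table(sess$recording, cal$template)
  mean_sds <- tapply(ft$sd_s, sess$truth$speed, mean)
  expect_true(all(diff(mean_sds) > 0))
})

test_that("simulated days carry consistent ground truth", {
  d <- simulate_day(day_schedule(c("nonwalk", "walk", "nonwalk"),
                                 c(300, 55, 300)), seed = 2)
  b <- find_bouts(d$truth$truth)
  expect_identical(nrow(b), 1L)
  expect_identical(b$category, "short")
  expect_equal(d$truth_summary$short_walk_min, 55 / 60)
  expect_equal(d$truth_summary$long_walk_min, 0)

  # 9 h of wear is an invalid day; scheduled wear excludes device-off time
  d9 <- simulate_day(day_schedule(c("inactive", "nonwear"),
                                  c(9 * 3600, 3600)), seed = 2)
  expect_equal(d9$truth_summary$wear_time_h, 9)
  expect_false(d9$truth_summary$valid)

  # empty schedule: empty recording, zero summary
  d0 <- simulate_day(day_schedule(character(0), numeric(0)), seed = 1)
  expect_identical(length(d0$recording$x), 0L)
  expect_equal(d0$truth_summary$activity_min, 0)

  # additive identities hold on the truth summary
  ts <- d$truth_summary
  expect_identical(ts$activity_counts,
                   ts$walking_counts + ts$nonwalking_counts)
  expect_identical(ts$walking_min, ts$short_walk_min + ts$long_walk_min)
})

test_that("epoch time is conserved through the pipeline", {
  sch <- default_day_schedule(seed = 33)
  d <- simulate_day(sch, seed = 33)
  cfg <- pipeline_config()
  ct <- walkcounts:::epoch_counts_all(d$recording)
  classified_s <- sum(!ct$inactive) * cfg$epoch_s
  inactive_s <- sum(ct$inactive) * cfg$epoch_s
  discarded_s <- (length(d$recording$x) -
                    nrow(ct) * cfg$fs * cfg$epoch_s) / cfg$fs
  expect_equal(classified_s + inactive_s + discarded_s,
               length(d$recording$x) / cfg$fs)
})

test_that("cohort generator reproduces its specification", {
  # zero SDs: identical subjects
  spec0 <- cohort_spec(n_subjects = 4, n_days = 3,
                       time_sd = c(nonwalking = 0, short_walk = 0,
                                   long_walk = 0),
                       intensity_sd = c(nonwalking = 0, short_walk = 0,
                                        long_walk = 0),
                       day_cv = 1e-12, pal_noise_sd = 0, seed = 2)
  co0 <- simulate_cohort(spec0)
  expect_lt(sd(co0$subjects$activity_counts), 1e-6)
  expect_lt(sd(co0$subjects$pal), 1e-9)
  # default spec sits near the published cohort structure
  co <- simulate_cohort(cohort_spec(n_subjects = 60, seed = 10))
  expect_equal(mean(co$subjects$nonwalking_min), 500, tolerance = 0.1)
  expect_equal(mean(co$subjects$nonwalking_cpm), 7.0, tolerance = 0.1)
  # additive identities
  expect_equal(co$subjects$activity_counts,
               co$subjects$nonwalking_counts + co$subjects$walking_counts)
})

test_that("refitting the cohort recovers the generating slope", {
  slopes <- vapply(1:25, function(r) {
    co <- simulate_cohort(cohort_spec(seed = 3000 + r))
    fit_pal_model(co$subjects$pal,
                  co$subjects["activity_counts"])$coefficients[[1]]
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 9.7e-5), 3 * se + 1e-6)
})
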