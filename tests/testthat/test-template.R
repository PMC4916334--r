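test_that("gait cycles are cut at the stride for asymmetric gait", {
  w <- simulate_walk(gait_params(), duration_s = 60, fs = 60, seed = 3)
  cyc <- extract_gait_cycles(w$recording)
  # 60 s at 0.9 strides/s -> ~54 stride cycles of ~67 samples
  expect_gt(length(cyc), 48)
  expect_lt(length(cyc), 58)
  expect_true(abs(median(lengths(cyc)) - 60 / 0.9) <= 2)
  expect_true(all(abs(vapply(cyc, mean, numeric(1))) < 1e-9))
})

test_that("a pure sinusoid yields one-period cycles", {
  t <- (0:3599) / 60
  rec <- triax_recording(rep(0, 3600), rep(0, 3600),
                         1 + 0.3 * sin(2 * pi * 0.9 * t), fs = 60)
  cyc <- extract_gait_cycles(rec)
  expect_true(all(lengths(cyc) %in% 65:68))
})

test_that("non-periodic calibration input is rejected", {
  const <- triax_recording(rep(0, 1200), rep(0, 1200), rep(1, 1200), fs = 60)
  expect_error(extract_gait_cycles(const), "periodicity")
  set.seed(2)
  noise <- triax_recording(rnorm(1200), rnorm(1200), rnorm(1200), fs = 60)
  expect_error(extract_gait_cycles(noise), "periodicity|cycles")
})

# independent linear-interpolation resampler used only to build inputs
resample_waveform_oracle <- function(v, n)
  approx(seq(0, 1, length.out = length(v)), v,
         xout = seq(0, 1, length.out = n))$y

test_that("template averaging recovers the clean cycle", {
  # an asymmetric cycle (fundamental + phase-shifted harmonic) has a
  # sharp, unambiguous alignment optimum
  ph <- 2 * pi * (0:66) / 67
  cyc <- sin(ph) + 0.5 * sin(2 * ph + 0.7)
  cyc <- cyc - mean(cyc)
  # identical cycles reproduce the cycle
  tm <- build_template(list(cyc, cyc, cyc))
  expect_equal(tm$waveform, cyc, tolerance = 1e-12)
  expect_identical(tm$n_cycles_used, 3L)
  # symmetric noise cancels in the mean
  set.seed(4)
  noise <- rnorm(67, 0, 0.02)
  tm2 <- build_template(list(cyc + noise, cyc - noise))
  expect_equal(tm2$waveform, cyc, tolerance = 1e-12)
  # median-length resampling: lengths 66 and 68 -> 67
  tm3 <- build_template(list(cyc[1:66], resample_waveform_oracle(cyc, 68)))
  expect_identical(tm3$cycle_len, 67L)
  expect_error(build_template(list()), "at least one")
  expect_lt(abs(mean(tm$waveform)), 1e-9 * diff(range(tm$waveform)))
})

test_that("template is invariant to cycle order up to circular shift", {
  w <- simulate_walk(duration_s = 30, seed = 8)
  cyc <- extract_gait_cycles(w$recording)
  tm1 <- build_template(cyc)
  set.seed(1)
  tm2 <- build_template(sample(cyc))
  expect_identical(length(tm1$waveform), length(tm2$waveform))
  n <- length(tm1$waveform)
  best <- max(vapply(0:(n - 1), function(s) {
    v <- tm2$waveform[((seq_len(n) - 1 + s) %% n) + 1]
    cor(tm1$waveform, v)
  }, numeric(1)))
  expect_gt(best, 0.99)
})

test_that("epoch features behave as SDs and a matched filter", {
  cal <- get_calibration()
  tmpl <- cal$template
  const <- segment_epochs(triax_recording(rep(0, 300), rep(0, 300),
                                          rep(1, 300), fs = 60))[[1]]
  f0 <- epoch_features(const, tmpl)
  expect_equal(f0$sd_s, 0)
  expect_equal(f0$sd_cc, 0)

  # epoch = template tiled: sd_cc beats any scrambled version of the
  # same samples (matched-filter property)
  tile <- rep_len(tmpl$waveform, 300)
  ep <- segment_epochs(triax_recording(rep(0, 300), rep(0, 300), 1 + tile,
                                       fs = 60))[[1]]
  f1 <- epoch_features(ep, tmpl)
  set.seed(5)
  scrambled <- replicate(25, {
    eps <- segment_epochs(triax_recording(rep(0, 300), rep(0, 300),
                                          1 + sample(tile), fs = 60))[[1]]
    epoch_features(eps, tmpl)$sd_cc
  })
  expect_true(all(f1$sd_cc > scrambled))

  # linearity in epoch amplitude (amplitudes kept small enough that the
  # vertical axis stays positive and the vector magnitude scales linearly)
  eph <- segment_epochs(triax_recording(rep(0, 300), rep(0, 300),
                                        1 + 0.5 * tile, fs = 60))[[1]]
  fh <- epoch_features(eph, tmpl)
  expect_equal(f1$sd_s, 2 * fh$sd_s)
  expect_equal(f1$sd_cc, 2 * fh$sd_cc)

  # determinism
  expect_identical(epoch_features(ep, tmpl), epoch_features(ep, tmpl))
})

test_that("vectorized feature table agrees with per-epoch features", {
  cal <- get_calibration()
  w <- simulate_walk(duration_s = 30, seed = 21)
  ft <- epoch_feature_table(w$recording, cal$template)
  eps <- segment_epochs(w$recording)
  for (i in c(1, 3, 6)) {
    f <- epoch_features(eps[[i]], cal$template)
    expect_equal(ft$sd_s[i], f$sd_s)
    expect_equal(ft$sd_cc[i], f$sd_cc)
    expect_equal(ft$counts[i], f$counts)
  }
})

test_that("sd_cc discriminates gait from matched-power noise", {
  cal <- get_calibration()
  w <- simulate_walk(duration_s = 200, seed = 31)
  ft_w <- epoch_feature_table(w$recording, cal$template)
  nw <- simulate_nonwalk(7, duration_s = 200, seed = 32)
  ft_n <- epoch_feature_table(nw$recording, cal$template)
  # both features scale linearly with amplitude, so compare the
  # scale-free shape score sd_cc / sd_s
  r_w <- ft_w$sd_cc / ft_w$sd_s
  r_n <- ft_n$sd_cc / ft_n$sd_s
  wins <- outer(r_w, r_n, ">")
  expect_gt(mean(wins), 0.95)
})

test_that("templates round-trip through JSON exactly", {
  cal <- get_calibration()
  path <- withr::local_tempfile(fileext = ".json")
  write_template(cal$template, path)
  back <- read_template(path)
  expect_identical(back$waveform, cal$template$waveform)
  expect_identical(back$cycle_len, cal$template$cycle_len)
  expect_identical(back$subject_id, cal$template$subject_id)
})
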