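#' Gait signal parameters
#'
#' Parameters of the synthetic gait generator.  Walking acceleration is
#' modeled as a harmonic series at the step frequency on top of 1 g
#' gravity: a fundamental plus two harmonics, amplitude-modulated at the
#' stride frequency (half the step frequency) to mimic left/right step
#' asymmetry, with white Gaussian sensor noise.  The horizontal axes carry
#' attenuated, phase-shifted copies of the vertical waveform.  A harmonic
#' model (rather than recorded waveforms) keeps closed-form count oracles
#' available and the detection difficulty controllable.
#'
#' @param step_freq Step frequency in Hz (healthy adult walking is roughly
#'   1.5–2.1 Hz; default 1.8).
#' @param amplitude Peak acceleration of the fundamental in g (default
#'   0.3, typical of lower-back accelerometry at comfortable speed).
#' @param harmonics Relative amplitudes of the 2nd and 3rd harmonics.
#' @param cycle_asymmetry Fractional amplitude difference between
#'   alternating steps (default 0.2); this is what makes the stride, not
#'   the step, the fundamental period of the signal.
#' @param noise_sd Gaussian sensor noise SD in g (default 0.03).
#' @param attenuation Relative amplitude of the two horizontal axes.
#' @return A `gait_params` list.
#' @export
gait_params <- function(step_freq = 1.8, amplitude = 0.3,
                        harmonics = c(0.5, 0.25), cycle_asymmetry = 0.2,
                        noise_sd = 0.03, attenuation = c(0.5, 0.3)) {
  stopifnot(step_freq > 0.5, step_freq < 3.5, amplitude > 0,
            noise_sd >= 0, cycle_asymmetry >= 0, cycle_asymmetry < 1)
  structure(list(step_freq = step_freq, amplitude = amplitude,
                 harmonics = harmonics, cycle_asymmetry = cycle_asymmetry,
                 noise_sd = noise_sd, attenuation = attenuation),
            class = "gait_params")
}

## Deterministic harmonic gait waveform (no noise), unit fundamental.
gait_waveform <- function(t, params) {
  f <- params$step_freq
  base <- sin(2 * pi * f * t)
  for (i in seq_along(params$harmonics))
    base <- base + params$harmonics[i] * sin(2 * pi * (i + 1) * f * t + 0.5 * i)
  mod <- 1 + params$cycle_asymmetry * sin(pi * f * t)
  base * mod
}

#' Simulate steady walking
#'
#' Generates a triaxial recording of continuous walking with ground-truth
#' epoch labels.  The vertical axis is 1 g plus the gait waveform scaled
#' by `amplitude`; the horizontal axes carry the same waveform attenuated
#' and phase-shifted by a quarter and a sixth of a step, plus independent
#' sensor noise.  Output is deterministic for a fixed seed.
#'
#' @param params A [gait_params()].
#' @param duration_s Duration in seconds (>= 5).
#' @param fs Sampling rate in Hz.
#' @param seed Integer RNG seed.
#' @param subject_id Subject identifier.
#' @return A list: `recording` (a [triax_recording()]) and `truth`, a
#'   data.frame with one `"walk"` label per complete epoch.
#' @export
simulate_walk <- function(params = gait_params(), duration_s = 60,
                          fs = 60, seed = 1, subject_id = "S01") {
  stopifnot(duration_s >= 5)
  set.seed(seed)
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  A <- params$amplitude
  shift1 <- 0.25 / params$step_freq
  shift2 <- 1 / 6 / params$step_freq
  z <- 1 + A * gait_waveform(t, params)
  x <- params$attenuation[1] * A * gait_waveform(t - shift1, params)
  y <- params$attenuation[2] * A * gait_waveform(t - shift2, params)
  if (params$noise_sd > 0) {
    z <- z + stats::rnorm(n, 0, params$noise_sd)
    x <- x + stats::rnorm(n, 0, params$noise_sd)
    y <- y + stats::rnorm(n, 0, params$noise_sd)
  }
  rec <- triax_recording(x, y, z, fs = fs, subject_id = subject_id)
  n_epochs <- n %/% as.integer(round(fs * 5))
  list(recording = rec,
       truth = data.frame(epoch = seq_len(n_epochs),
                          truth = rep("walk", n_epochs)))
}

## Band-limited (lo-hi Hz) unit-variance Gaussian noise via FFT masking.
bandlimited_noise <- function(n, fs, lo = 0.3, hi = 8) {
  v <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  fmir <- pmin(f, fs - f)
  mask <- fmir >= lo & fmir <= hi
  if (!any(mask)) return(rep(0, n))
  out <- Re(stats::fft(stats::fft(v) * mask, inverse = TRUE) / n)
  s <- stats::sd(out)
  if (s > 0) out / s else out
}

#' Simulate non-walking movement
#'
#' Aperiodic band-limited (0.3–8 Hz) acceleration noise on all three axes,
#' scaled so that the mean realized epoch count rate matches the requested
#' intensity exactly (counts are linear in amplitude, so a single
#' rescaling hits the target mean).  With `intensity_target = 0` the
#' recording is motionless and every epoch is inactive.
#'
#' @param intensity_target Target mean intensity in counts/minute (the
#'   published non-walking mean is 7.0 counts/min).
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer RNG seed.
#' @param subject_id Subject identifier.
#' @param config A [pipeline_config()] (for the epoch length and the
#'   inactivity threshold used in the truth labels).
#' @return A list: `recording` and `truth` (labels `"nonwalk"` or
#'   `"inactive"` depending on whether the target rate clears the
#'   inactivity threshold).
#' @export
simulate_nonwalk <- function(intensity_target = 7, duration_s = 60,
                             fs = 60, seed = 1, subject_id = "S01",
                             config = pipeline_config()) {
  stopifnot(intensity_target >= 0, duration_s >= 5)
  set.seed(seed)
  n <- as.integer(round(duration_s * fs))
  x <- bandlimited_noise(n, fs)
  y <- bandlimited_noise(n, fs)
  z <- bandlimited_noise(n, fs)
  rec0 <- triax_recording(0.02 * x, 0.02 * y, 1 + 0.02 * z, fs = fs,
                          subject_id = subject_id)
  ct0 <- epoch_counts_all(rec0, config)
  target_per_epoch <- intensity_target * config$epoch_s / 60
  scale <- if (nrow(ct0) > 0 && mean(ct0$counts) > 0)
    target_per_epoch / mean(ct0$counts) else 0
  rec <- triax_recording(0.02 * scale * x, 0.02 * scale * y,
                         1 + 0.02 * scale * z, fs = fs,
                         subject_id = subject_id)
  n_epochs <- n %/% as.integer(round(fs * config$epoch_s))
  lab <- if (intensity_target / 60 < config$inactivity_rate)
    "inactive" else "nonwalk"
  list(recording = rec,
       truth = data.frame(epoch = seq_len(n_epochs),
                          truth = rep(lab, n_epochs)))
}

#' Map treadmill speed to gait parameters
#'
#' Affine mapping from treadmill speed (km/h) to step frequency and
#' vertical amplitude; only monotonicity matters for calibration, and the
#' defaults place 3–6 km/h at 1.65–2.1 Hz and 0.23–0.41 g, typical of
#' adult treadmill walking.
#'
#' @param speed Treadmill speed in km/h.
#' @param base A [gait_params()] supplying the non-speed-dependent fields.
#' @return A `gait_params` for that speed.
#' @export
speed_to_gait_params <- function(speed, base = gait_params()) {
  gait_params(step_freq = 1.2 + 0.15 * speed,
              amplitude = 0.05 + 0.06 * speed,
              harmonics = base$harmonics,
              cycle_asymmetry = base$cycle_asymmetry,
              noise_sd = base$noise_sd,
              attenuation = base$attenuation)
}

#' Simulate a 4-speed treadmill calibration session
#'
#' Concatenates constant-speed walking blocks (default 4 speeds of 3 min
#' each), mirroring the laboratory calibration protocol from which the
#' personalized template and the walking likelihoods are derived.
#'
#' @param params Base [gait_params()] (speed-independent fields).
#' @param speeds Treadmill speeds in km/h (4 values by default).
#' @param duration_each Seconds per speed block.
#' @param fs Sampling rate in Hz.
#' @param seed Integer RNG seed.
#' @param subject_id Subject identifier.
#' @return A list: `recording`, `truth` (all `"walk"`, with a `speed`
#'   column per epoch), and `speeds`.
#' @export
simulate_treadmill_session <- function(params = gait_params(),
                                       speeds = c(3, 4, 5, 6),
                                       duration_each = 180, fs = 60,
                                       seed = 1, subject_id = "S01") {
  stopifnot(length(speeds) >= 1)
  blocks <- lapply(seq_along(speeds), function(i) {
    p <- speed_to_gait_params(speeds[i], base = params)
    simulate_walk(p, duration_s = duration_each, fs = fs,
                  seed = seed + 101L * i, subject_id = subject_id)
  })
  rec <- triax_recording(
    unlist(lapply(blocks, function(b) b$recording$x)),
    unlist(lapply(blocks, function(b) b$recording$y)),
    unlist(lapply(blocks, function(b) b$recording$z)),
    fs = fs, subject_id = subject_id)
  ep_per_block <- vapply(blocks, function(b) nrow(b$truth), integer(1))
  truth <- data.frame(epoch = seq_len(sum(ep_per_block)),
                      truth = "walk",
                      speed = rep(speeds, ep_per_block))
  list(recording = rec, truth = truth, speeds = speeds)
}

#' Day schedule for the simulator
#'
#' An ordered list of activity segments.  Durations must be positive
#' multiples of the epoch length so that ground-truth labels align with
#' epoch boundaries, and must total at most 24 h.  Activities: `walk`,
#' `nonwalk`, `inactive` (worn but motionless apart from a noise floor)
#' and `nonwear` (device off: exact zeros).
#'
#' @param activity Character vector of segment activities.
#' @param duration_s Segment durations in seconds.
#' @param epoch_s Epoch length the durations must align to.
#' @return A `day_schedule` data.frame.
#' @export
day_schedule <- function(activity, duration_s, epoch_s = 5) {
  stopifnot(length(activity) == length(duration_s))
  ok <- c("walk", "nonwalk", "inactive", "nonwear")
  if (!all(activity %in% ok))
    stop("unknown activity; use ", paste(ok, collapse = "/"), call. = FALSE)
  if (length(duration_s) &&
      (any(duration_s <= 0) ||
       any(abs(duration_s / epoch_s - round(duration_s / epoch_s)) > 1e-9)))
    stop("durations must be positive multiples of ", epoch_s, " s",
         call. = FALSE)
  if (sum(duration_s) > 24 * 3600)
    stop("schedule exceeds 24 h", call. = FALSE)
  structure(data.frame(activity = activity, duration_s = duration_s),
            class = c("day_schedule", "data.frame"))
}

#' Random day schedule with realistic activity mix
#'
#' Draws a sequence of segments whose composition mirrors a free-living
#' day in an older-adult cohort — about one fifth of active time walking,
#' with roughly 80% of walking bouts shorter than one minute — compressed
#' to a configurable total so that many days remain cheap to simulate.
#'
#' @param seed Integer RNG seed.
#' @param total_active_s Approximate total of non-nonwear segments, in
#'   seconds (default 2400 s).
#' @return A `day_schedule`.
#' @export
default_day_schedule <- function(seed = 1, total_active_s = 2400) {
  set.seed(seed)
  act <- character(0); dur <- numeric(0)
  tot <- 0
  while (tot < total_active_s) {
    type <- sample(c("walk", "nonwalk", "inactive"), 1,
                   prob = c(0.30, 0.45, 0.25))
    d <- switch(type,
                walk = if (stats::runif(1) < 0.8)
                  sample(seq(20, 55, by = 5), 1) else
                    sample(seq(60, 180, by = 5), 1),
                nonwalk = sample(seq(60, 480, by = 5), 1),
                inactive = sample(seq(60, 300, by = 5), 1))
    act <- c(act, type); dur <- c(dur, d)
    tot <- tot + d
  }
  day_schedule(act, dur)
}

#' Simulate one day of free-living accelerometry
#'
#' Concatenates the schedule's segment generators into one recording and
#' derives the ground-truth epoch labels and the ground-truth daily
#' summary (computed from the true labels and the realized counts — the
#' oracle against which classification and aggregation are checked).
#' Ground-truth wear time is the scheduled worn (non-`nonwear`) duration.
#'
#' @param schedule A [day_schedule()].
#' @param fs Sampling rate in Hz.
#' @param seed Integer RNG seed.
#' @param params [gait_params()] used for walk segments.
#' @param nonwalk_intensity Target intensity of nonwalk segments
#'   (counts/min).
#' @param inactive_intensity Residual noise-floor intensity of worn-idle
#'   segments (counts/min); must sit below the inactivity threshold.
#' @param subject_id Subject identifier.
#' @param date Calendar date for the summary.
#' @param config A [pipeline_config()].
#' @return A list: `recording`, `truth` (per-epoch labels), and
#'   `truth_summary` (a [summarize_day()] row computed from the truth).
#' @export
simulate_day <- function(schedule, fs = 60, seed = 1,
                         params = gait_params(), nonwalk_intensity = 7,
                         inactive_intensity = 0.01, subject_id = "S01",
                         date = as.Date("1970-01-01"),
                         config = pipeline_config()) {
  stopifnot(inherits(schedule, "day_schedule"))
  if (nrow(schedule) == 0L) {
    rec <- triax_recording(numeric(0), numeric(0), numeric(0), fs = fs,
                           subject_id = subject_id)
    empty <- data.frame(epoch = integer(), counts = numeric(),
                        label = character())
    ts <- summarize_day(empty, date = date, wear_time_h = 0,
                        config = config)
    return(list(recording = rec,
                truth = data.frame(epoch = integer(), truth = character()),
                truth_summary = ts))
  }
  xs <- ys <- zs <- vector("list", nrow(schedule))
  labs <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    d <- schedule$duration_s[i]
    sseed <- seed + 977L * i
    seg <- switch(schedule$activity[i],
      walk = simulate_walk(params, d, fs, sseed, subject_id),
      nonwalk = simulate_nonwalk(nonwalk_intensity, d, fs, sseed,
                                 subject_id, config),
      inactive = simulate_nonwalk(inactive_intensity, d, fs, sseed,
                                  subject_id, config),
      nonwear = {
        n <- as.integer(round(d * fs))
        list(recording = triax_recording(rep(0, n), rep(0, n), rep(0, n),
                                         fs = fs,
                                         subject_id = subject_id),
             truth = data.frame(
               epoch = seq_len(n %/% as.integer(round(fs * config$epoch_s))),
               truth = "inactive"))
      })
    xs[[i]] <- seg$recording$x; ys[[i]] <- seg$recording$y
    zs[[i]] <- seg$recording$z
    labs[[i]] <- seg$truth$truth
  }
  rec <- triax_recording(unlist(xs), unlist(ys), unlist(zs), fs = fs,
                         subject_id = subject_id)
  truth <- data.frame(epoch = seq_along(unlist(labs)),
                      truth = unlist(labs))
  wear_h <- sum(schedule$duration_s[schedule$activity != "nonwear"]) / 3600
  counts <- epoch_counts_all(rec, config)
  labeled <- data.frame(epoch = truth$epoch, counts = counts$counts,
                        label = truth$truth)
  ts <- summarize_day(labeled, date = date, wear_time_h = wear_h,
                      config = config)
  list(recording = rec, truth = truth, truth_summary = ts)
}

#' Cohort specification for the summary-level simulator
#'
#' Between-subject distributions of daily category time (min/day) and
#' intensity (counts/min), defaulting to the published cohort structure of
#' healthy older adults: nonwalking 500 (97) min at 7.0 (1.2) counts/min,
#' short walks 106 (49) min at 20.9 (3.1), long walks 24 (17) min at
#' 23.3 (3.6).  PAL is generated from the configured prediction model
#' applied to each subject's true daily counts plus Gaussian noise.
#'
#' @param n_subjects Number of subjects (default 31, the energy-expenditure
#'   subgroup size).
#' @param n_days Monitored days per subject (default 14).
#' @param time_mean,time_sd Named numeric vectors (nonwalking, short_walk,
#'   long_walk) of daily minutes.
#' @param intensity_mean,intensity_sd Named numeric vectors of counts/min.
#' @param pal_model A `pal_model` used as the PAL generation rule.
#' @param pal_noise_sd SD of the PAL noise (default 0.13, the simple
#'   model's published SEE).
#' @param day_cv Within-subject day-to-day coefficient of variation of
#'   category times (default 0.2).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 31, n_days = 14,
                        time_mean = c(nonwalking = 500, short_walk = 106,
                                      long_walk = 24),
                        time_sd = c(nonwalking = 97, short_walk = 49,
                                    long_walk = 17),
                        intensity_mean = c(nonwalking = 7.0,
                                           short_walk = 20.9,
                                           long_walk = 23.3),
                        intensity_sd = c(nonwalking = 1.2,
                                         short_walk = 3.1,
                                         long_walk = 3.6),
                        pal_model = pal_model_simple(),
                        pal_noise_sd = 0.13, day_cv = 0.2, seed = 1) {
  stopifnot(n_subjects >= 2, n_days >= 1, all(time_sd >= 0),
            all(intensity_sd >= 0), pal_noise_sd >= 0)
  structure(list(n_subjects = n_subjects, n_days = n_days,
                 time_mean = time_mean, time_sd = time_sd,
                 intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd, pal_model = pal_model,
                 pal_noise_sd = pal_noise_sd, day_cv = day_cv,
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort at the summary level
#'
#' Draws per-subject mean daily category times and intensities from the
#' cohort distributions (truncated at zero), adds day-to-day variation,
#' aggregates to subject summaries, and generates each subject's PAL from
#' the spec's model applied to the true counts plus noise.  This is the
#' ground-truth machinery for regression parameter-recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `subjects` (one row per subject with category times,
#'   counts, intensities, derived walking/activity totals and `pal`) and
#'   `days` (the per-day draws).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cats <- names(spec$time_mean)
  subj_rows <- vector("list", spec$n_subjects)
  day_rows <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    subj_time <- pmax(0, stats::rnorm(length(cats), spec$time_mean,
                                      spec$time_sd))
    subj_int <- pmax(0, stats::rnorm(length(cats), spec$intensity_mean,
                                     spec$intensity_sd))
    names(subj_time) <- names(subj_int) <- cats
    dd <- do.call(rbind, lapply(seq_len(spec$n_days), function(d) {
      tm <- pmax(0, stats::rnorm(length(cats), subj_time,
                                 spec$day_cv * subj_time))
      data.frame(subject_id = sprintf("S%02d", s), day = d,
                 category = cats, time_min = tm,
                 counts = tm * subj_int)
    }))
    day_rows[[s]] <- dd
    row <- data.frame(subject_id = sprintf("S%02d", s),
                      n_valid_days = spec$n_days)
    for (categ in cats) {
      ds <- dd[dd$category == categ, ]
      row[[paste0(categ, "_min")]] <- mean(ds$time_min)
      row[[paste0(categ, "_counts")]] <- mean(ds$counts)
      row[[paste0(categ, "_cpm")]] <-
        if (mean(ds$time_min) > 0)
          mean(ds$counts) / mean(ds$time_min) else NA_real_
    }
    subj_rows[[s]] <- row
  }
  subjects <- do.call(rbind, subj_rows)
  subjects$walking_min <- subjects$short_walk_min + subjects$long_walk_min
  subjects$walking_counts <- subjects$short_walk_counts +
    subjects$long_walk_counts
  subjects$walking_cpm <- ifelse(subjects$walking_min > 0,
                                 subjects$walking_counts /
                                   subjects$walking_min, NA_real_)
  subjects$activity_min <- subjects$walking_min + subjects$nonwalking_min
  subjects$activity_counts <- subjects$walking_counts +
    subjects$nonwalking_counts
  subjects$activity_cpm <- ifelse(subjects$activity_min > 0,
                                  subjects$activity_counts /
                                    subjects$activity_min, NA_real_)
  subjects$pal <- predict_pal(spec$pal_model, subjects) +
    stats::rnorm(nrow(subjects), 0, spec$pal_noise_sd)
  list(subjects = subjects, days = do.call(rbind, day_rows))
}
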