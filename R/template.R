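#' Estimate the dominant gait-cycle length from autocorrelation
#'
#' The vector-magnitude signal of steady walking is quasi-periodic; its
#' autocorrelation peaks at multiples of the gait-cycle (stride) duration.
#' Because left and right steps are rarely identical, the stride lag
#' correlates more strongly than the single-step lag, so among all
#' significant autocorrelation peaks the smallest lag whose value is close
#' to the best peak is taken as the cycle length.  For a perfectly
#' symmetric periodic signal this reduces to its fundamental period.
#'
#' @param vm Vector-magnitude series (g).
#' @param fs Sampling rate in Hz.
#' @param min_peak Minimum autocorrelation a lag must reach to count as
#'   periodicity; below this the signal is judged non-periodic.
#' @return Cycle length in samples.
#' @keywords internal
estimate_cycle_length <- function(vm, fs, min_peak = 0.3) {
  if (stats::sd(vm) == 0 || length(vm) < fs)
    stop("calibration signal shows no periodicity (zero variance or too short)",
         call. = FALSE)
  max_lag <- min(length(vm) - 1L, as.integer(round(4 * fs)))
  ac <- as.numeric(stats::acf(vm, lag.max = max_lag, plot = FALSE,
                              demean = TRUE)$acf)
  # local maxima at lags >= fs / 3.5 (fastest plausible cycle)
  lag_min <- max(3L, as.integer(floor(fs / 3.5)))
  lags <- seq_len(max_lag)
  vals <- ac[lags + 1L]
  is_peak <- c(FALSE, diff(sign(diff(vals))) == -2, FALSE)
  cand <- lags[is_peak & lags >= lag_min & vals >= min_peak]
  if (length(cand) == 0L)
    stop("calibration signal shows no periodicity (no autocorrelation peak >= ",
         min_peak, ")", call. = FALSE)
  best <- max(vals[cand])
  L <- cand[vals[cand] >= 0.9 * best][1L]
  # step-vs-stride disambiguation: if the doubled lag correlates strictly
  # better, the signal alternates between two step shapes and the true
  # cycle is the stride; for a symmetric periodic signal acf decays with
  # lag and the doubled lag never wins.
  dbl <- cand[cand >= 1.8 * L & cand <= 2.2 * L]
  if (length(dbl) && max(vals[dbl]) > vals[L])
    L <- dbl[which.max(vals[dbl])]
  L
}

#' Extract individual gait cycles from a treadmill calibration recording
#'
#' Cycles are cut peak-to-peak on the vector-magnitude signal: the dominant
#' cycle length is estimated by autocorrelation (or taken from
#' `cadence_hint`), prominent peaks at least 0.7 cycle lengths apart are
#' located, and each inter-peak segment whose length lies within 30% of the
#' nominal cycle becomes one cycle, mean-removed.
#'
#' @param calibration A [triax_recording()] of steady walking (treadmill).
#' @param cadence_hint Optional dominant cycle frequency in Hz; when `NULL`
#'   it is estimated from the autocorrelation.
#' @return A list of numeric cycle waveforms (g, mean-removed), with the
#'   nominal cycle length in samples as attribute `cycle_len`.
#' @export
extract_gait_cycles <- function(calibration, cadence_hint = NULL) {
  stopifnot(inherits(calibration, "triax_recording"))
  vm <- vector_magnitude(calibration)
  fs <- calibration$fs
  cyc <- if (is.null(cadence_hint)) {
    estimate_cycle_length(vm, fs)
  } else {
    as.integer(round(fs / cadence_hint))
  }
  vmc <- vm - mean(vm)
  # light smoothing (quarter-cycle moving average) stabilizes peak picking
  w <- max(1L, as.integer(round(cyc / 4)))
  sm <- stats::filter(vmc, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  peaks <- which(c(FALSE, diff(sign(diff(sm))) == -2, FALSE))
  if (length(peaks) >= 2L) {
    # enforce minimum spacing, keeping the higher peak of any close pair
    ord <- peaks[order(sm[peaks], decreasing = TRUE)]
    keep <- logical(length(sm))
    taken <- integer(0)
    for (p in ord) {
      if (all(abs(taken - p) >= 0.7 * cyc)) taken <- c(taken, p)
    }
    peaks <- sort(taken)
  }
  if (length(peaks) < 2L)
    stop("calibration signal shows no usable gait cycles", call. = FALSE)
  cycles <- list()
  for (i in seq_len(length(peaks) - 1L)) {
    seg <- vmc[peaks[i]:(peaks[i + 1L] - 1L)]
    if (length(seg) >= 0.7 * cyc && length(seg) <= 1.3 * cyc)
      cycles[[length(cycles) + 1L]] <- seg - mean(seg)
  }
  if (length(cycles) == 0L)
    stop("calibration signal shows no usable gait cycles", call. = FALSE)
  attr(cycles, "cycle_len") <- cyc
  cycles
}

## Resample a waveform to n points (linear interpolation on [0, 1]).
resample_waveform <- function(v, n) {
  if (length(v) == n) return(v)
  stats::approx(seq(0, 1, length.out = length(v)), v,
                xout = seq(0, 1, length.out = n))$y
}

## Circular shift that best aligns `v` with `ref` (both same length).
align_to <- function(v, ref) {
  n <- length(v)
  scores <- vapply(0:(n - 1L), function(s) {
    sum(ref * v[((seq_len(n) - 1L + s) %% n) + 1L])
  }, numeric(1))
  s <- which.max(scores) - 1L
  v[((seq_len(n) - 1L + s) %% n) + 1L]
}

#' Build a personalized gait template from extracted cycles
#'
#' Cycles are resampled to the median cycle length, circularly aligned to
#' the first cycle by maximizing cross-correlation, averaged pointwise and
#' mean-removed.  Averaging cancels cycle-to-cycle noise, leaving the
#' subject's prototype gait waveform.
#'
#' @param cycles A list of cycle waveforms from [extract_gait_cycles()].
#' @param fs Sampling rate the cycles were recorded at (Hz).
#' @param subject_id Subject identifier.
#' @param source_speeds Optional treadmill speeds (km/h) the cycles came
#'   from, recorded for provenance.
#' @return An object of class `gait_template` with fields `waveform`
#'   (mean-removed, g), `cycle_len`, `n_cycles_used`, `fs`, `subject_id`,
#'   `source_speeds`.
#' @export
build_template <- function(cycles, fs = 60, subject_id = "S01",
                           source_speeds = numeric()) {
  if (length(cycles) == 0L)
    stop("need at least one gait cycle to build a template", call. = FALSE)
  len <- as.integer(round(stats::median(lengths(cycles))))
  if (len < 2L) stop("gait cycles too short", call. = FALSE)
  rs <- lapply(cycles, resample_waveform, n = len)
  ref <- rs[[1L]]
  aligned <- c(list(ref), lapply(rs[-1L], align_to, ref = ref))
  wf <- Reduce(`+`, aligned) / length(aligned)
  wf <- wf - mean(wf)
  structure(list(subject_id = as.character(subject_id), fs = fs,
                 waveform = wf, cycle_len = len,
                 n_cycles_used = length(cycles),
                 source_speeds = as.numeric(source_speeds)),
            class = "gait_template")
}

#' @export
print.gait_template <- function(x, ...) {
  cat(sprintf(
    "<gait_template> subject %s: cycle %d samples at %g Hz, from %d cycles\n",
    x$subject_id, x$cycle_len, x$fs, x$n_cycles_used))
  invisible(x)
}

#' Serialize a gait template to JSON
#'
#' Templates are small artifacts (one cycle of samples) written at full
#' precision so that calibration and daily-life processing can run as
#' separate invocations with bit-identical results.
#'
#' @param template A `gait_template`.
#' @param path File path.
#' @return `read_template()` returns a `gait_template`; `write_template()`
#'   returns `path` invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "gait_template"))
  jsonlite::write_json(unclass(template), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(subject_id = obj$subject_id, fs = obj$fs,
                 waveform = as.numeric(obj$waveform),
                 cycle_len = as.integer(obj$cycle_len),
                 n_cycles_used = as.integer(obj$n_cycles_used),
                 source_speeds = as.numeric(obj$source_speeds)),
            class = "gait_template")
}

## Full-overlap cross-correlation of a (mean-removed) signal with the
## template: cc[l] = sum_j s[l+j-1] w[j], l = 1 .. n-m+1.
crosscorr_full_overlap <- function(s, w) {
  n <- length(s); m <- length(w)
  if (m > n) stop("template longer than signal segment", call. = FALSE)
  y <- stats::filter(s, rev(w), sides = 1)
  as.numeric(y)[m:n]
}

## Population (n-denominator) standard deviation.
sd_pop <- function(v) sqrt(mean((v - mean(v))^2))

#' Classifier features of one epoch
#'
#' Two features summarize each 5-s epoch for walking recognition: `sd_s`,
#' the standard deviation of the epoch's vector-magnitude signal (signal
#' power), and `sd_cc`, the standard deviation of the cross-correlation of
#' the mean-removed epoch signal with the personalized gait template over
#' all full-overlap lags (periodicity and shape agreement).  Both use the
#' population (n) denominator.  The cross-correlation is the raw sliding
#' dot product, deliberately unnormalized: absolute amplitude carries
#' intensity information and any fixed monotone scaling is absorbed when
#' the likelihood densities are calibrated.
#'
#' @param epoch An epoch from [segment_epochs()].
#' @param template A `gait_template`.
#' @param config A [pipeline_config()].
#' @return A list with `sd_s` (g), `sd_cc`, and the epoch's `counts`,
#'   `rate`, `inactive` fields as from [epoch_counts()].
#' @export
epoch_features <- function(epoch, template, config = pipeline_config()) {
  stopifnot(inherits(epoch, "epoch"), inherits(template, "gait_template"))
  if (length(template$waveform) < 2L)
    stop("degenerate template", call. = FALSE)
  vmc <- epoch$vm - mean(epoch$vm)
  cc <- crosscorr_full_overlap(vmc, template$waveform)
  cnt <- epoch_counts(epoch, config)
  list(sd_s = sd_pop(epoch$vm), sd_cc = sd_pop(cc),
       counts = cnt$counts, rate = cnt$rate, inactive = cnt$inactive)
}

#' Feature table for every epoch of a recording
#'
#' Vectorized equivalent of [epoch_features()] over all complete epochs:
#' one `stats::filter` pass computes the running template dot product, and
#' per-epoch slices at full-overlap positions give `sd_cc`.
#'
#' @param recording A [triax_recording()].
#' @param template A `gait_template`.
#' @param config A [pipeline_config()].
#' @return A data.frame with one row per epoch: `epoch`, `sd_s`, `sd_cc`,
#'   `counts`, `rate`, `inactive`.
#' @export
epoch_feature_table <- function(recording, template,
                                config = pipeline_config()) {
  stopifnot(inherits(recording, "triax_recording"),
            inherits(template, "gait_template"))
  ct <- epoch_counts_all(recording, config)
  n_per <- as.integer(round(recording$fs * config$epoch_s))
  n_epochs <- nrow(ct)
  if (n_epochs == 0L)
    return(cbind(ct, sd_s = numeric(0), sd_cc = numeric(0)))
  used <- n_epochs * n_per
  vm <- vector_magnitude(recording)[seq_len(used)]
  grp <- rep(seq_len(n_epochs), each = n_per)
  mu <- rep(vapply(split(vm, grp), mean, numeric(1)), each = n_per)
  vmc <- vm - mu
  sd_s <- vapply(split(vm, grp), sd_pop, numeric(1))
  m <- length(template$waveform)
  run <- as.numeric(stats::filter(vmc, rev(template$waveform), sides = 1))
  # positions i where the window [i-m+1, i] lies inside epoch e
  sd_cc <- vapply(seq_len(n_epochs), function(e) {
    pos <- ((e - 1L) * n_per + m):(e * n_per)
    sd_pop(run[pos])
  }, numeric(1))
  out <- ct
  out$sd_s <- unname(sd_s)
  out$sd_cc <- sd_cc
  out
}
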