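#' Construct a triaxial accelerometer recording
#'
#' A recording holds three equal-length acceleration series in g units
#' sampled at a fixed rate.  Devices of the kind this pipeline targets
#' (hip/lower-back triaxial actigraphs) record nominally at 60 Hz.
#'
#' @param x,y,z Numeric acceleration series in g, equal length.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Subject identifier.
#' @param start_time Recording start, a `POSIXct` (defaults to the Unix
#'   epoch in UTC so purely synthetic recordings are reproducible).
#' @return An object of class `triax_recording`.
#' @export
#' @examples
#' rec <- triax_recording(x = rnorm(600, 0, 0.01), y = rnorm(600, 0, 0.01),
#'                        z = 1 + rnorm(600, 0, 0.01), fs = 60)
#' length(vector_magnitude(rec))
triax_recording <- function(x, y, z, fs = 60, subject_id = "S01",
                            start_time = as.POSIXct("1970-01-01",
                                                    tz = "UTC")) {
  if (!(length(x) == length(y) && length(y) == length(z)))
    stop("axis series must have equal length", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 start_time = start_time,
                 fs = as.numeric(fs),
                 x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
            class = "triax_recording")
}

#' @export
print.triax_recording <- function(x, ...) {
  cat(sprintf("<triax_recording> subject %s: %d samples at %g Hz (%.1f s)\n",
              x$subject_id, length(x$x), x$fs, length(x$x) / x$fs))
  invisible(x)
}

#' @export
length.triax_recording <- function(x) length(x$x)

#' Vector magnitude of a triaxial recording
#'
#' Pointwise Euclidean norm of the three axes, the one-dimensional signal
#' on which all template matching and feature extraction operates.
#'
#' @param recording A [triax_recording()].
#' @return Numeric vector, same length as the input axes, in g.
#' @export
vector_magnitude <- function(recording) {
  stopifnot(inherits(recording, "triax_recording"))
  if (!(length(recording$x) == length(recording$y) &&
        length(recording$y) == length(recording$z)))
    stop("axis series must have equal length", call. = FALSE)
  sqrt(recording$x^2 + recording$y^2 + recording$z^2)
}

#' Linearly resample a recording to a target rate
#'
#' The pipeline's epochs and templates assume a common rate; recordings at
#' other rates are interpolated linearly onto the target time grid.
#'
#' @param recording A [triax_recording()].
#' @param fs_out Target rate in Hz.
#' @return A `triax_recording` at `fs_out`.
#' @export
resample_recording <- function(recording, fs_out = 60) {
  stopifnot(inherits(recording, "triax_recording"), fs_out > 0)
  if (isTRUE(all.equal(recording$fs, fs_out))) return(recording)
  n_in <- length(recording$x)
  if (n_in < 2L) stop("recording too short to resample", call. = FALSE)
  t_in <- (seq_len(n_in) - 1) / recording$fs
  t_out <- seq(0, t_in[n_in], by = 1 / fs_out)
  interp <- function(v) stats::approx(t_in, v, xout = t_out)$y
  triax_recording(interp(recording$x), interp(recording$y),
                  interp(recording$z), fs = fs_out,
                  subject_id = recording$subject_id,
                  start_time = recording$start_time)
}

#' Segment a recording into fixed-length epochs
#'
#' Consecutive, non-overlapping windows of `epoch_s` seconds; a trailing
#' partial window is discarded (padding would bias the variance and count
#' statistics of the last epoch).
#'
#' @param recording A [triax_recording()].
#' @param epoch_s Epoch length in seconds.
#' @return A list of `epoch` objects, each with fields `index`, `fs`,
#'   `duration_s`, the three axis segments and the vector-magnitude segment
#'   `vm`.
#' @export
segment_epochs <- function(recording, epoch_s = 5) {
  stopifnot(inherits(recording, "triax_recording"))
  if (recording$fs <= 0) stop("fs must be positive", call. = FALSE)
  n_per <- recording$fs * epoch_s
  if (abs(n_per - round(n_per)) > 1e-9)
    stop("fs * epoch_s is not a whole number of samples; resample first",
         call. = FALSE)
  n_per <- as.integer(round(n_per))
  n_epochs <- length(recording$x) %/% n_per
  if (n_epochs == 0L) return(list())
  vm <- vector_magnitude(recording)
  lapply(seq_len(n_epochs), function(i) {
    idx <- ((i - 1L) * n_per + 1L):(i * n_per)
    structure(list(index = i, fs = recording$fs, duration_s = epoch_s,
                   x = recording$x[idx], y = recording$y[idx],
                   z = recording$z[idx], vm = vm[idx]),
              class = "epoch")
  })
}

## Detrend one axis segment: mean removal (default) or linear-trend removal.
detrend_axis <- function(v, method = "mean") {
  if (method == "mean") return(v - mean(v))
  t <- seq_along(v)
  stats::lsfit(t, v)$residuals
}

#' Activity counts of one epoch
#'
#' Counts are the time-integral of detrended, rectified acceleration:
#' per axis the epoch mean (or a linear trend) is removed, the absolute
#' value taken, and the result integrated over the epoch by the rectangular
#' rule (sum divided by the sampling rate).  The three per-axis integrals
#' are summed into a composite count in g-seconds.  Epochs whose count rate
#' falls below the inactivity threshold are flagged inactive and excluded
#' from all downstream activity aggregates.
#'
#' @param epoch An epoch from [segment_epochs()].
#' @param config A [pipeline_config()].
#' @return A list with `counts` (g s), `rate` (counts/s) and `inactive`.
#' @export
epoch_counts <- function(epoch, config = pipeline_config()) {
  stopifnot(inherits(epoch, "epoch"))
  expected <- round(epoch$fs * epoch$duration_s)
  if (length(epoch$x) != expected)
    stop("epoch does not have the full sample count", call. = FALSE)
  dt <- 1 / epoch$fs
  counts <- sum(abs(detrend_axis(epoch$x, config$detrend))) * dt +
    sum(abs(detrend_axis(epoch$y, config$detrend))) * dt +
    sum(abs(detrend_axis(epoch$z, config$detrend))) * dt
  rate <- counts / epoch$duration_s
  list(counts = counts, rate = rate,
       inactive = flag_inactive(rate, config))
}

#' Inactivity flag for a count rate
#'
#' Epochs producing fewer than `config$inactivity_rate` counts per second
#' (default 1e-3, strict less-than) carry no meaningful body movement and
#' are excluded from activity time and counts.
#'
#' @param rate Counts per second, non-negative.
#' @param config A [pipeline_config()].
#' @return Logical: `TRUE` iff the epoch is inactive.
#' @export
flag_inactive <- function(rate, config = pipeline_config()) {
  if (any(rate < 0)) stop("count rate cannot be negative", call. = FALSE)
  rate < config$inactivity_rate
}

## Vectorized epoch counts over a whole recording: returns a data.frame with
## one row per complete epoch.  Used by the pipeline fast path; agrees with
## epoch_counts() applied per epoch.
epoch_counts_all <- function(recording, config = pipeline_config()) {
  n_per <- as.integer(round(recording$fs * config$epoch_s))
  n_epochs <- length(recording$x) %/% n_per
  if (n_epochs == 0L)
    return(data.frame(epoch = integer(), counts = numeric(),
                      rate = numeric(), inactive = logical()))
  used <- n_epochs * n_per
  grp <- rep(seq_len(n_epochs), each = n_per)
  dt <- 1 / recording$fs
  axis_counts <- function(v) {
    v <- v[seq_len(used)]
    if (config$detrend == "mean") {
      mu <- rep(vapply(split(v, grp), mean, numeric(1)), each = n_per)
      dv <- v - mu
    } else {
      dv <- unlist(lapply(split(v, grp), detrend_axis, method = "linear"),
                   use.names = FALSE)
    }
    vapply(split(abs(dv), grp), sum, numeric(1)) * dt
  }
  counts <- axis_counts(recording$x) + axis_counts(recording$y) +
    axis_counts(recording$z)
  rate <- counts / config$epoch_s
  data.frame(epoch = seq_len(n_epochs), counts = unname(counts),
             rate = unname(rate),
             inactive = flag_inactive(unname(rate), config))
}
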