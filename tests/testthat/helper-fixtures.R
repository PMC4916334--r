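# Shared fixtures, built once per test run.

.fixtures <- new.env()

# Treadmill calibration (template + likelihood model) for one synthetic
# subject; reused across classifier, aggregation and pipeline tests.
get_calibration <- function() {
  if (is.null(.fixtures$cal)) {
    sess <- simulate_treadmill_session(seed = 11)
    .fixtures$sess <- sess
    .fixtures$cal <- calibrate_subject(sess$recording,
                                       source_speeds = sess$speeds)
  }
  .fixtures$cal
}

get_session <- function() {
  get_calibration()
  .fixtures$sess
}

# A recording whose vertical axis is a pure sinusoid (amplitude in g).
sinusoid_recording <- function(amp = 0.5, freq = 1, duration_s = 5,
                               fs = 60, x0 = 0, y0 = 0, z0 = 1) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  triax_recording(rep(x0, n), rep(y0, n), z0 + amp * sin(2 * pi * freq * t),
                  fs = fs)
}

# Independent bout oracle: scan the label sequence with an explicit loop.
bouts_oracle <- function(labels, epoch_s = 5, threshold_s = 60) {
  out <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (labels[i] == "walk") {
      j <- i
      while (j < n && labels[j + 1L] == "walk") j <- j + 1L
      dur <- (j - i + 1L) * epoch_s
      out[[length(out) + 1L]] <-
        data.frame(start_epoch = i, n_epochs = j - i + 1L,
                   duration_s = dur,
                   category = if (dur < threshold_s) "short" else "long")
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out) == 0L)
    return(data.frame(start_epoch = integer(), n_epochs = integer(),
                      duration_s = numeric(), category = character()))
  do.call(rbind, out)
}
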