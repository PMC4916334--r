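#' Calibrate a subject from a treadmill session
#'
#' Builds the personalized gait template from the calibration recording,
#' computes the two classifier features for every calibration epoch,
#' drops inactive epochs, and fits the walking likelihood model.
#'
#' @param calibration A [triax_recording()] of treadmill walking.
#' @param config A [pipeline_config()].
#' @param source_speeds Optional treadmill speeds, stored on the template.
#' @return A list with `template` (a `gait_template`), `model`
#'   (a `walk_model`) and `features` (the calibration epoch table).
#' @export
calibrate_subject <- function(calibration, config = pipeline_config(),
                              source_speeds = numeric()) {
  stopifnot(inherits(calibration, "triax_recording"))
  cal <- if (abs(calibration$fs - config$fs) > 1e-9)
    resample_recording(calibration, config$fs) else calibration
  cycles <- extract_gait_cycles(cal)
  template <- build_template(cycles, fs = cal$fs,
                             subject_id = cal$subject_id,
                             source_speeds = source_speeds)
  features <- epoch_feature_table(cal, template, config)
  active <- features[!features$inactive, , drop = FALSE]
  if (nrow(active) == 0L)
    stop("calibration recording contains no active epochs", call. = FALSE)
  model <- fit_likelihoods(active, config)
  list(template = template, model = model, features = features)
}

#' Process one free-living day
#'
#' Computes epoch features against the subject's template, classifies
#' every epoch, and reduces the day to a [summarize_day()] row.
#'
#' @param recording The day's [triax_recording()].
#' @param template The subject's `gait_template`.
#' @param model The subject's `walk_model`.
#' @param date Calendar date of the recording.
#' @param wear_time_h Wear time in hours (`NULL`: estimated from counts).
#' @param config A [pipeline_config()].
#' @return A list with `epochs` (the classified epoch table) and
#'   `summary` (a `daily_summary` row).
#' @export
process_day <- function(recording, template, model,
                        date = as.Date("1970-01-01"), wear_time_h = NULL,
                        config = pipeline_config()) {
  rec <- if (abs(recording$fs - config$fs) > 1e-9)
    resample_recording(recording, config$fs) else recording
  ft <- epoch_feature_table(rec, template, config)
  ft <- classify_epochs(ft, model)
  summary <- summarize_day(ft, date = date, wear_time_h = wear_time_h,
                           config = config)
  list(epochs = ft, summary = summary)
}

#' Run the full walking-recognition pipeline for one subject
#'
#' Chains calibration, per-day classification and aggregation:
#' template and likelihood model from the treadmill session, per-epoch
#' labels and daily summaries for every free-living day, and the subject
#' summary over valid days.  When `out_dir` is given, writes the template
#' and model artifacts, the per-day CSV, the subject CSV and a run
#' manifest.
#'
#' @param calibration Treadmill [triax_recording()] or a path to one.
#' @param days A list of free-living recordings (or paths).
#' @param config A [pipeline_config()].
#' @param dates Optional vector of dates, one per day.
#' @param wear_time_h Optional numeric vector of externally measured wear
#'   times (hours), one per day; `NA` entries are estimated from counts.
#' @param out_dir Optional output directory for artifacts.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A list with `template`, `model`, `daily` (stacked daily
#'   summaries), `epochs` (list of classified epoch tables) and `subject`
#'   (the subject summary; `NULL`, with a warning, when no day is valid).
#' @export
run_pipeline <- function(calibration, days, config = pipeline_config(),
                         dates = NULL, wear_time_h = NULL, out_dir = NULL,
                         seed = NULL) {
  input_paths <- character(0)
  if (is.character(calibration)) {
    input_paths <- c(input_paths, calibration)
    calibration <- read_recording(calibration)
  }
  if (length(days) == 0L) stop("need at least one day", call. = FALSE)
  days <- lapply(days, function(d) {
    if (is.character(d)) {
      input_paths <<- c(input_paths, d)
      read_recording(d)
    } else d
  })
  if (is.null(dates))
    dates <- as.Date("1970-01-01") + seq_along(days) - 1L
  cal <- calibrate_subject(calibration, config)
  processed <- lapply(seq_along(days), function(i) {
    wt <- if (is.null(wear_time_h) || is.na(wear_time_h[i])) NULL
          else wear_time_h[i]
    process_day(days[[i]], cal$template, cal$model, date = dates[i],
                wear_time_h = wt, config = config)
  })
  daily <- do.call(rbind, lapply(processed, `[[`, "summary"))
  subject <- tryCatch(
    summarize_subject(daily, subject_id = calibration$subject_id),
    walkcounts_no_valid_days = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_template(cal$template, file.path(out_dir, "template.json"))
    write_walk_model(cal$model, file.path(out_dir, "walk_model.json"))
    utils::write.csv(daily, file.path(out_dir, "daily.csv"),
                     row.names = FALSE)
    if (!is.null(subject))
      utils::write.csv(subject, file.path(out_dir, "subject.csv"),
                       row.names = FALSE)
    write_manifest(config, inputs = input_paths, seed = seed,
                   path = file.path(out_dir, "manifest.json"))
  }
  list(template = cal$template, model = cal$model, daily = daily,
       epochs = lapply(processed, `[[`, "epochs"), subject = subject)
}
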