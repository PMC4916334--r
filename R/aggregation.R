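#' Find walking bouts in a label sequence
#'
#' A bout is a maximal run of consecutive walk-labeled epochs; a single
#' non-walk epoch ends a bout (no gap tolerance).  Bouts strictly shorter
#' than the bout threshold (default 60 s, i.e. fewer than 12 five-second
#' epochs) are short walks; bouts lasting at least the threshold are long
#' walks.
#'
#' @param labels Character vector of per-epoch labels in time order
#'   (`"walk"`, `"nonwalk"`, `"inactive"`).
#' @param counts Optional per-epoch counts, summed per bout when given.
#' @param config A [pipeline_config()].
#' @return A data.frame with one row per bout: `start_epoch`, `n_epochs`,
#'   `duration_s`, `category` (`"short"`/`"long"`), `counts`.
#' @export
find_bouts <- function(labels, counts = NULL, config = pipeline_config()) {
  r <- rle(labels == "walk")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep))
    return(data.frame(start_epoch = integer(), n_epochs = integer(),
                      duration_s = numeric(), category = character(),
                      counts = numeric()))
  starts <- starts[keep]; n <- r$lengths[keep]
  dur <- n * config$epoch_s
  cnt <- if (is.null(counts)) rep(NA_real_, length(n)) else
    vapply(seq_along(starts),
           function(i) sum(counts[starts[i]:(starts[i] + n[i] - 1L)]),
           numeric(1))
  data.frame(start_epoch = starts, n_epochs = n, duration_s = dur,
             category = ifelse(dur < config$bout_threshold_s,
                               "short", "long"),
             counts = cnt)
}

#' Per-epoch activity categories
#'
#' Refines walk / nonwalk / inactive labels into the reporting taxonomy by
#' splitting walking epochs according to the bout they belong to:
#' `short_walk` (bout < 1 min), `long_walk` (bout >= 1 min), `nonwalking`,
#' `inactive`.
#'
#' @inheritParams find_bouts
#' @return Character vector of categories, same length as `labels`.
#' @export
bout_categories <- function(labels, config = pipeline_config()) {
  out <- ifelse(labels == "inactive", "inactive",
                ifelse(labels == "walk", NA_character_, "nonwalking"))
  b <- find_bouts(labels, config = config)
  if (nrow(b) > 0L)
    for (i in seq_len(nrow(b))) {
      idx <- b$start_epoch[i]:(b$start_epoch[i] + b$n_epochs[i] - 1L)
      out[idx] <- paste0(b$category[i], "_walk")
    }
  out
}

#' Detect non-wear epochs
#'
#' Non-wear is detected as runs of at least `config$nonwear_run_min`
#' consecutive minutes of zero-count epochs (an unworn device on a table
#' registers no body acceleration at all, unlike worn-but-idle epochs
#' which retain a noise floor).
#'
#' @param counts Per-epoch counts in time order.
#' @param config A [pipeline_config()].
#' @return Logical vector: `TRUE` for epochs inside a non-wear run.
#' @export
detect_nonwear <- function(counts, config = pipeline_config()) {
  zero <- counts <= 0
  r <- rle(zero)
  min_epochs <- config$nonwear_run_min * 60 / config$epoch_s
  rep(r$values & r$lengths >= min_epochs, r$lengths)
}

#' Wear time of a recorded day
#'
#' Wear time is the recorded duration minus detected non-wear runs; any
#' part of the calendar day not covered by the recording also counts as
#' non-wear.  An externally supplied wear log can be used instead by
#' passing `wear_time_h` directly to [summarize_day()].
#'
#' @param counts Per-epoch counts in time order.
#' @param config A [pipeline_config()].
#' @return Wear time in hours.
#' @export
wear_time_hours <- function(counts, config = pipeline_config()) {
  nw <- detect_nonwear(counts, config)
  sum(!nw) * config$epoch_s / 3600
}

day_summary_cols <- c("nonwalking", "short_walk", "long_walk",
                      "walking", "activity")

#' Daily summary of classified epochs
#'
#' Tallies one day of labeled epochs into the reporting taxonomy: time in
#' each category is the epoch length (5 s) times the number of epochs;
#' counts are summed over the category's epochs.  Inactive epochs
#' contribute to neither time nor counts.  Walking is the sum of short and
#' long walks, and activity the sum of walking and non-walking — these
#' identities hold exactly by construction.  The day is valid when wear
#' time reaches the wear minimum (10 h, inclusive) and no data are
#' missing.
#'
#' @param labeled A data.frame with per-epoch `epoch`, `counts` and
#'   `label` columns (from [classify_epochs()]), all from one date.
#' @param date The calendar date (any scalar; stored as given).
#' @param wear_time_h Wear time in hours; when `NULL` it is estimated from
#'   the counts via [wear_time_hours()].
#' @param missing_data `TRUE` when the day has gaps that should invalidate
#'   it regardless of wear time.
#' @param config A [pipeline_config()].
#' @return A one-row data.frame (class `daily_summary`) with `date`,
#'   `wear_time_h`, `valid`, `inactive_min`, and `<category>_min` /
#'   `<category>_counts` for nonwalking, short_walk, long_walk, walking,
#'   activity.
#' @export
summarize_day <- function(labeled, date = as.Date("1970-01-01"),
                          wear_time_h = NULL, missing_data = FALSE,
                          config = pipeline_config()) {
  if (anyDuplicated(labeled$epoch))
    stop("duplicated epochs in day input", call. = FALSE)
  if (is.unsorted(labeled$epoch))
    stop("epochs must be in time order", call. = FALSE)
  if (is.null(wear_time_h))
    wear_time_h <- wear_time_hours(labeled$counts, config)
  cat5 <- bout_categories(labeled$label, config)
  epoch_min <- config$epoch_s / 60
  tally <- function(categ) sum(cat5 == categ)
  csum <- function(categ) sum(labeled$counts[cat5 == categ])
  out <- data.frame(date = date, wear_time_h = wear_time_h,
                    valid = !missing_data &&
                      wear_time_h >= config$wear_min_h,
                    inactive_min = tally("inactive") * epoch_min)
  for (categ in c("nonwalking", "short_walk", "long_walk")) {
    out[[paste0(categ, "_min")]] <- tally(categ) * epoch_min
    out[[paste0(categ, "_counts")]] <- csum(categ)
  }
  out$walking_min <- out$short_walk_min + out$long_walk_min
  out$walking_counts <- out$short_walk_counts + out$long_walk_counts
  out$activity_min <- out$walking_min + out$nonwalking_min
  out$activity_counts <- out$walking_counts + out$nonwalking_counts
  class(out) <- c("daily_summary", class(out))
  out
}

#' Subject summary over valid days
#'
#' Averages daily times and counts over valid days only (treating daily
#' activity as an ergodic process, so dropping invalid days does not bias
#' the mean).  Category intensity is the ratio of the subject's mean daily
#' counts to mean daily time (counts per minute); a category with zero
#' mean time has undefined intensity, reported as `NA` rather than 0.
#'
#' @param days A data.frame of [summarize_day()] rows for one subject.
#' @param subject_id Subject identifier.
#' @return A one-row data.frame (class `subject_summary`) with
#'   `n_valid_days`, mean `<category>_min` and `<category>_counts`,
#'   `<category>_cpm` intensities, and `activity_time_h`.
#' @export
summarize_subject <- function(days, subject_id = "S01") {
  valid <- days[days$valid, , drop = FALSE]
  if (nrow(valid) == 0L)
    stop(errorCondition(
      paste0("subject ", subject_id, " has no valid days; excluded"),
      class = c("walkcounts_no_valid_days", "error")))
  out <- data.frame(subject_id = subject_id, n_valid_days = nrow(valid))
  for (categ in day_summary_cols) {
    tm <- mean(valid[[paste0(categ, "_min")]])
    ct <- mean(valid[[paste0(categ, "_counts")]])
    out[[paste0(categ, "_min")]] <- tm
    out[[paste0(categ, "_counts")]] <- ct
    out[[paste0(categ, "_cpm")]] <- if (tm > 0) ct / tm else NA_real_
  }
  out$activity_time_h <- out$activity_min / 60
  class(out) <- c("subject_summary", class(out))
  out
}

#' Cohort table of activity categories
#'
#' Cross-subject mean and SD of daily time (min/day), daily counts
#' (kcounts/day) and intensity (counts/minute) for each activity category.
#' Cohort intensity is the mean of the per-subject intensities (each a
#' ratio of that subject's means), not the ratio of cohort means.
#'
#' @param subjects A data.frame of [summarize_subject()] rows.
#' @return A data.frame with one row per category (activity, nonwalking,
#'   walking, short_walk, long_walk) and mean/SD columns for time, counts
#'   and intensity.
#' @export
cohort_table <- function(subjects) {
  if (nrow(subjects) < 2L)
    stop("cohort table needs at least 2 subjects", call. = FALSE)
  rows <- c("activity", "nonwalking", "walking", "short_walk", "long_walk")
  do.call(rbind, lapply(rows, function(categ) {
    tm <- subjects[[paste0(categ, "_min")]]
    ct <- subjects[[paste0(categ, "_counts")]] / 1000  # kcounts/day
    ins <- subjects[[paste0(categ, "_cpm")]]
    data.frame(category = categ,
               time_mean_min = mean(tm), time_sd_min = stats::sd(tm),
               counts_mean_kcounts = mean(ct),
               counts_sd_kcounts = stats::sd(ct),
               intensity_mean_cpm = mean(ins, na.rm = TRUE),
               intensity_sd_cpm = stats::sd(ins, na.rm = TRUE))
  }))
}
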