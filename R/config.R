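#' Pipeline configuration
#'
#' Collects every fixed numeric constant of the walking-recognition pipeline
#' in one place.  All downstream functions take their thresholds from a
#' config object, so a study can override any of them without touching code.
#'
#' @param fs Target sampling rate in Hz.  Recordings at other rates are
#'   linearly resampled to this rate before epoching.
#' @param epoch_s Epoch length in seconds.
#' @param inactivity_rate Counts-per-second threshold below which an epoch is
#'   labeled inactive and excluded from activity time and counts (strict
#'   less-than).
#' @param bout_threshold_s Walking-bout duration (seconds) separating short
#'   from long walks; bouts strictly shorter are short, others long.
#' @param wear_min_h Minimum daily wear time in hours for a day to be valid
#'   (days with strictly less are excluded).
#' @param k_numerator,k_factor Constants of the likelihood scaling
#'   k = k_numerator / (k_factor * max joint likelihood); the classification
#'   threshold is equivalently `joint > k_factor * max_joint`.
#' @param density Density family for the walking likelihoods: `"kde"`
#'   (Gaussian kernel, Silverman bandwidth) or `"lognormal"` (parametric fit).
#' @param tie_rule Label assigned when the walking score equals 0.5 exactly:
#'   `"nonwalk"` (default, conservative toward the majority class) or
#'   `"walk"`.
#' @param nonwear_run_min Minimum run of consecutive zero-count minutes
#'   counted as non-wear when wear time is estimated from the signal.
#' @param detrend Per-epoch detrending before rectification: `"mean"`
#'   (subtract the epoch mean per axis) or `"linear"` (remove a least-squares
#'   linear trend per axis).
#' @param stepwise_entry_p,stepwise_removal_p Entry and removal p-value
#'   thresholds for stepwise predictor selection.
#'
#' @return An object of class `walk_config` (a named list).
#' @seealso [read_config()], [write_config()]
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$inactivity_rate
pipeline_config <- function(fs = 60,
                            epoch_s = 5,
                            inactivity_rate = 1e-3,
                            bout_threshold_s = 60,
                            wear_min_h = 10,
                            k_numerator = 0.5,
                            k_factor = 0.14,
                            density = c("kde", "lognormal"),
                            tie_rule = c("nonwalk", "walk"),
                            nonwear_run_min = 60,
                            detrend = c("mean", "linear"),
                            stepwise_entry_p = 0.05,
                            stepwise_removal_p = 0.10) {
  density <- match.arg(density)
  tie_rule <- match.arg(tie_rule)
  detrend <- match.arg(detrend)
  num <- list(fs = fs, epoch_s = epoch_s, inactivity_rate = inactivity_rate,
              bout_threshold_s = bout_threshold_s, wear_min_h = wear_min_h,
              k_numerator = k_numerator, k_factor = k_factor,
              nonwear_run_min = nonwear_run_min,
              stepwise_entry_p = stepwise_entry_p,
              stepwise_removal_p = stepwise_removal_p)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  cfg <- c(num, list(density = density, tie_rule = tie_rule,
                     detrend = detrend))
  class(cfg) <- "walk_config"
  cfg
}

#' Read and write pipeline configuration
#'
#' Configs serialize to YAML and round-trip exactly (numbers are written at
#' full precision).
#'
#' @param config A `walk_config` object.
#' @param path File path.
#' @return `read_config()` returns a `walk_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "walk_config"))
  yaml::write_yaml(unclass(config), path,
                   precision = 17L, handlers = NULL)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @export
print.walk_config <- function(x, ...) {
  cat("<walk_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
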