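#' Fit the walking likelihood model from treadmill calibration epochs
#'
#' The classifier assumes naive conditional independence of the two epoch
#' features given walking, so the walking score of an epoch is
#' `k * P(sd_s | walk) * P(sd_cc | walk)`.  The two univariate likelihoods
#' are fit on treadmill walking epochs, by default as Gaussian kernel
#' density estimates with Silverman's bandwidth (a log-normal parametric
#' fit is available via `config$density`).  The scaling constant is
#' `k = 0.5 / (0.14 * max_joint)` where `max_joint` is the largest joint
#' likelihood attained by any calibration epoch, so the decision rule
#' "score > 0.5" is exactly "joint likelihood > 0.14 * max_joint".
#'
#' @param calibration_features A data.frame with columns `sd_s` and
#'   `sd_cc`, one row per treadmill walking epoch (inactive epochs should
#'   be removed first).
#' @param config A [pipeline_config()]; `k_numerator` (0.5) and `k_factor`
#'   (0.14) parameterize the scaling constant.
#' @return An object of class `walk_model`: the two densities (as sampled
#'   grids for `"kde"`, as meanlog/sdlog for `"lognormal"`), `max_joint`,
#'   `k` and the config constants used.
#' @export
fit_likelihoods <- function(calibration_features,
                            config = pipeline_config()) {
  sds <- calibration_features$sd_s
  sdcc <- calibration_features$sd_cc
  if (is.null(sds) || is.null(sdcc))
    stop("calibration features must have sd_s and sd_cc columns",
         call. = FALSE)
  if (length(sds) < 30L)
    warning("fewer than 30 calibration epochs; likelihoods may be unstable",
            call. = FALSE)
  if (stats::sd(sds) == 0 || stats::sd(sdcc) == 0)
    stop("zero-variance calibration feature: degenerate calibration",
         call. = FALSE)
  fit1 <- fit_density(sds, config$density)
  fit2 <- fit_density(sdcc, config$density)
  joint <- eval_density(fit1, sds) * eval_density(fit2, sdcc)
  max_joint <- max(joint)
  if (max_joint <= 0)
    stop("degenerate calibration: zero joint likelihood everywhere",
         call. = FALSE)
  structure(list(density = config$density, dens_sds = fit1,
                 dens_sdcc = fit2, max_joint = max_joint,
                 k_numerator = config$k_numerator,
                 k_factor = config$k_factor,
                 k = config$k_numerator / (config$k_factor * max_joint),
                 tie_rule = config$tie_rule,
                 n_calibration = length(sds)),
            class = "walk_model")
}

## One univariate likelihood: KDE grid or log-normal parameters.
fit_density <- function(v, family) {
  if (family == "kde") {
    d <- stats::density(v, bw = "nrd0", n = 1024L, cut = 4)
    list(family = "kde", x = d$x, y = d$y)
  } else {
    if (any(v <= 0)) stop("log-normal density needs positive features",
                          call. = FALSE)
    list(family = "lognormal", meanlog = mean(log(v)),
         sdlog = sd_pop(log(v)))
  }
}

## Evaluate a fitted likelihood at arbitrary points (0 outside a KDE grid).
eval_density <- function(fit, x) {
  if (fit$family == "kde") {
    stats::approx(fit$x, fit$y, xout = x, yleft = 0, yright = 0)$y
  } else {
    stats::dlnorm(x, fit$meanlog, fit$sdlog)
  }
}

#' @export
print.walk_model <- function(x, ...) {
  cat(sprintf(
    "<walk_model> %s densities from %d epochs; max joint %.4g, k = %.4g\n",
    x$density, x$n_calibration, x$max_joint, x$k))
  invisible(x)
}

#' Walking score of epochs
#'
#' Evaluates `k * P(sd_s | walk) * P(sd_cc | walk)`.  The score is an
#' unnormalized likelihood ratio, not a calibrated probability: at the
#' best-matching calibration epoch it equals `0.5 / 0.14` (about 3.57), so
#' it can exceed 1 and its complement can be negative.  Classification
#' therefore uses only the algebraically equivalent rule "score > 0.5".
#'
#' @param features A data.frame (or list) with `sd_s` and `sd_cc`.
#' @param model A `walk_model` from [fit_likelihoods()].
#' @return Numeric vector of non-negative walking scores.
#' @export
score_epoch <- function(features, model) {
  stopifnot(inherits(model, "walk_model"))
  model$k * eval_density(model$dens_sds, features$sd_s) *
    eval_density(model$dens_sdcc, features$sd_cc)
}

#' Classify epochs as walking or non-walking
#'
#' An epoch is labeled `walk` when its walking score exceeds 0.5 —
#' equivalently, when its joint feature likelihood exceeds
#' `k_factor * max_joint`.  An exact tie goes to the class named by the
#' model's tie rule (`nonwalk` by default).  Inactive epochs must be
#' excluded before classification; [classify_epochs()] handles that.
#'
#' @param features A data.frame (or list) with `sd_s` and `sd_cc`.
#' @param model A `walk_model`.
#' @return Character vector, `"walk"` or `"nonwalk"`.
#' @export
classify_epoch <- function(features, model) {
  p <- score_epoch(features, model)
  walk <- if (model$tie_rule == "walk") p >= 0.5 else p > 0.5
  ifelse(walk, "walk", "nonwalk")
}

#' Label every epoch of a feature table
#'
#' Adds `p_walk` and `label` columns to an epoch feature table.  Inactive
#' epochs bypass the classifier and are labeled `"inactive"`; their score
#' is `NA`.
#'
#' @param feature_table Output of [epoch_feature_table()].
#' @param model A `walk_model`.
#' @return The table with `p_walk` and `label` (walk / nonwalk / inactive).
#' @export
classify_epochs <- function(feature_table, model) {
  lab <- rep(NA_character_, nrow(feature_table))
  p <- rep(NA_real_, nrow(feature_table))
  act <- !feature_table$inactive
  if (any(act)) {
    p[act] <- score_epoch(feature_table[act, , drop = FALSE], model)
    lab[act] <- classify_epoch(feature_table[act, , drop = FALSE], model)
  }
  lab[!act] <- "inactive"
  feature_table$p_walk <- p
  feature_table$label <- lab
  feature_table
}

#' Serialize a walking likelihood model to JSON
#'
#' The density grids and constants are written at full precision, so a
#' read-back model reproduces every score bit-exactly and calibration and
#' classification can run as separate invocations.
#'
#' @param model A `walk_model`.
#' @param path File path.
#' @return `read_walk_model()` returns a `walk_model`;
#'   `write_walk_model()` returns `path` invisibly.
#' @export
write_walk_model <- function(model, path) {
  stopifnot(inherits(model, "walk_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_walk_model
#' @export
read_walk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(f) {
    f$family <- as.character(f$family)
    if (f$family == "kde") {
      f$x <- as.numeric(f$x); f$y <- as.numeric(f$y)
    }
    f
  }
  obj$dens_sds <- fix(obj$dens_sds)
  obj$dens_sdcc <- fix(obj$dens_sdcc)
  structure(obj, class = "walk_model")
}
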