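#' Physical activity level from energy expenditure
#'
#' PAL is the dimensionless ratio of total energy expenditure (TEE) to
#' basal metabolic rate (BMR).  Both must be expressed in the same unit
#' (e.g. MJ/day); the function never converts units silently.  Values
#' outside the physiologically plausible band 1.1–2.6 trigger a warning
#' (bedridden subjects sit near 1.2, elite endurance athletes near 2.5).
#'
#' @param tee Total energy expenditure (> 0).
#' @param bmr Basal metabolic rate (> 0), same unit as `tee`.
#' @return `tee / bmr`, vectorized.
#' @export
#' @examples
#' compute_pal(12.0, 6.0)
compute_pal <- function(tee, bmr) {
  if (any(!is.finite(tee)) || any(!is.finite(bmr)) ||
      any(tee <= 0) || any(bmr <= 0))
    stop("tee and bmr must be positive", call. = FALSE)
  pal <- tee / bmr
  if (any(pal < 1.1 | pal > 2.6))
    warning("PAL outside the plausible range [1.1, 2.6]", call. = FALSE)
  pal
}

#' Reference PAL prediction models
#'
#' The two published prediction equations shipped as package defaults: a
#' simple model on total daily activity counts
#' (PAL = 1.24 + 9.70e-5 x counts/day) and a multiple model on daily
#' non-walking and short-walk counts
#' (PAL = 1.17 + 10.92e-5 x nonwalking + 13.42e-5 x short-walk).
#' Predictors enter in counts/day (not kcounts) to match the 1e-5-scale
#' coefficients.
#'
#' @return A `pal_model` object with the reference coefficients.
#' @export
pal_model_simple <- function() {
  new_pal_model(name = "simple",
                predictors = "activity_counts",
                intercept = 1.24, coefficients = 9.70e-5,
                r2 = 0.53, see = 0.13, coef_sd = 1.71e-5, beta = 0.73)
}

#' @rdname pal_model_simple
#' @export
pal_model_multiple <- function() {
  new_pal_model(name = "multiple",
                predictors = c("nonwalking_counts", "short_walk_counts"),
                intercept = 1.17,
                coefficients = c(10.92e-5, 13.42e-5),
                r2 = 0.58, see = 0.12,
                coef_sd = c(1.99e-5, 3.64e-5), beta = c(0.68, 0.46))
}

new_pal_model <- function(name, predictors, intercept, coefficients,
                          r2 = NA_real_, see = NA_real_,
                          coef_sd = rep(NA_real_, length(coefficients)),
                          beta = rep(NA_real_, length(coefficients)),
                          p_values = rep(NA_real_, length(coefficients)),
                          incremental_r2 = NULL) {
  stopifnot(length(coefficients) == length(predictors))
  structure(list(name = name, predictors = predictors,
                 intercept = intercept,
                 coefficients = stats::setNames(coefficients, predictors),
                 r2 = r2, see = see,
                 coef_sd = stats::setNames(coef_sd, predictors),
                 beta = stats::setNames(beta, predictors),
                 p_values = stats::setNames(p_values, predictors),
                 incremental_r2 = incremental_r2),
            class = "pal_model")
}

#' @export
print.pal_model <- function(x, ...) {
  cat(sprintf("<pal_model> %s: PAL = %.4g", x$name, x$intercept))
  for (p in x$predictors)
    cat(sprintf(" + %.4g x %s", x$coefficients[[p]], p))
  cat(sprintf("\n  r2 = %.3g, SEE = %.3g\n", x$r2, x$see))
  invisible(x)
}

#' Predict PAL from daily counts
#'
#' `predict_pal()` evaluates any `pal_model` on a data.frame of daily
#' count predictors (counts/day).  `predict_pal_simple()` and
#' `predict_pal_multiple()` are shortcuts for the shipped reference
#' models.
#'
#' @param model A `pal_model`.
#' @param newdata A data.frame with the model's predictor columns, in
#'   counts/day.
#' @return Numeric vector of predicted PAL values.
#' @export
predict_pal <- function(model, newdata) {
  stopifnot(inherits(model, "pal_model"))
  missing <- setdiff(model$predictors, names(newdata))
  if (length(missing))
    stop("newdata lacks predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- rep(model$intercept, max(1L, nrow(as.data.frame(newdata))))
  for (p in model$predictors)
    out <- out + model$coefficients[[p]] * newdata[[p]]
  out
}

#' @rdname predict_pal
#' @param activity_counts Total daily activity counts (counts/day, >= 0).
#' @export
predict_pal_simple <- function(activity_counts) {
  stopifnot(all(activity_counts >= 0))
  predict_pal(pal_model_simple(),
              data.frame(activity_counts = activity_counts))
}

#' @rdname predict_pal
#' @param nonwalking_counts,short_walk_counts Daily non-walking and
#'   short-walk counts (counts/day, >= 0).
#' @export
predict_pal_multiple <- function(nonwalking_counts, short_walk_counts) {
  stopifnot(all(nonwalking_counts >= 0), all(short_walk_counts >= 0))
  predict_pal(pal_model_multiple(),
              data.frame(nonwalking_counts = nonwalking_counts,
                         short_walk_counts = short_walk_counts))
}

#' Fit a PAL prediction model by ordinary least squares
#'
#' Regresses per-subject PAL on a chosen subset of daily count predictors.
#' Reports the intercept and slopes, r-squared, the standard error of the
#' estimate (residual SD with n - p - 1 denominator), coefficient standard
#' deviations, standardized betas and two-sided coefficient p-values.  A
#' high condition number of the scaled predictor matrix triggers a
#' collinearity warning.
#'
#' @param pal Per-subject PAL values.
#' @param predictors A data.frame of per-subject daily counts (counts/day).
#' @param which Character vector naming the predictor columns to use
#'   (default: all columns).
#' @param name Model name.
#' @return A `pal_model` with fit statistics, plus attributes `fit` (the
#'   underlying `lm`) accessible via `attr(, "fit")`.
#' @export
fit_pal_model <- function(pal, predictors, which = names(predictors),
                          name = "fitted") {
  predictors <- as.data.frame(predictors)[, which, drop = FALSE]
  n <- length(pal)
  p <- ncol(predictors)
  if (n <= p + 1L)
    stop("need more subjects than predictors + 1", call. = FALSE)
  X <- as.matrix(predictors)
  if (p > 1L) {
    kappa_val <- kappa(scale(X), exact = TRUE)
    if (is.finite(kappa_val) && kappa_val > 30)
      warning("predictors are nearly collinear (condition number ",
              format(kappa_val, digits = 3), ")", call. = FALSE)
  }
  dat <- cbind(data.frame(pal = pal), predictors)
  fml <- stats::reformulate(names(predictors), response = "pal")
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit)))
    stop("predictors are exactly collinear; model not estimable",
         call. = FALSE)
  sm <- summary(fit)
  co <- sm$coefficients
  slopes <- co[-1L, 1L]
  beta <- slopes * apply(X, 2L, stats::sd) / stats::sd(pal)
  model <- new_pal_model(name = name, predictors = names(predictors),
                         intercept = co[1L, 1L], coefficients = slopes,
                         r2 = sm$r.squared, see = sm$sigma,
                         coef_sd = co[-1L, 2L], beta = beta,
                         p_values = co[-1L, 4L])
  attr(model, "fit") <- fit
  model
}

#' Stepwise selection of PAL predictors
#'
#' Classic p-value stepwise regression: at each step the candidate whose
#' addition has the smallest coefficient p-value enters if that p-value is
#' below the entry threshold (default 0.05); after every entry, included
#' terms whose p-value has risen above the removal threshold (default
#' 0.10) are dropped, worst first.  Iteration stops when no term can enter
#' or leave.  If no candidate ever enters, the intercept-only model is
#' returned with a warning.  The incremental r-squared contributed by each
#' entered term is recorded in entry order.
#'
#' @param pal Per-subject PAL values.
#' @param candidates A data.frame of candidate predictor columns
#'   (counts/day).
#' @param config A [pipeline_config()] supplying `stepwise_entry_p` and
#'   `stepwise_removal_p`.
#' @return A `pal_model` on the selected predictors (possibly none), with
#'   `incremental_r2` named by entry order.
#' @export
stepwise_select <- function(pal, candidates, config = pipeline_config()) {
  candidates <- as.data.frame(candidates)
  included <- character(0)
  inc_r2 <- numeric(0)
  prev_r2 <- 0
  repeat {
    changed <- FALSE
    pool <- setdiff(names(candidates), included)
    if (length(pool)) {
      trial_p <- vapply(pool, function(v) {
        m <- fit_pal_model(pal, candidates, which = c(included, v))
        m$p_values[[v]]
      }, numeric(1))
      best <- names(which.min(trial_p))
      if (trial_p[[best]] < config$stepwise_entry_p) {
        included <- c(included, best)
        m <- fit_pal_model(pal, candidates, which = included)
        inc_r2 <- c(inc_r2, stats::setNames(m$r2 - prev_r2, best))
        prev_r2 <- m$r2
        changed <- TRUE
      }
    }
    while (length(included)) {
      m <- fit_pal_model(pal, candidates, which = included)
      pv <- m$p_values[included]
      worst <- names(which.max(pv))
      if (pv[[worst]] > config$stepwise_removal_p) {
        included <- setdiff(included, worst)
        inc_r2 <- inc_r2[names(inc_r2) != worst]
        prev_r2 <- if (length(included))
          fit_pal_model(pal, candidates, which = included)$r2 else 0
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (!length(included)) {
    warning("no candidate met the entry criterion; intercept-only model",
            call. = FALSE)
    model <- new_pal_model(name = "stepwise", predictors = character(0),
                           intercept = mean(pal), coefficients = numeric(0),
                           r2 = 0,
                           see = stats::sd(pal),
                           coef_sd = numeric(0), beta = numeric(0),
                           p_values = numeric(0), incremental_r2 = numeric(0))
    return(model)
  }
  model <- fit_pal_model(pal, candidates, which = included,
                         name = "stepwise")
  model$incremental_r2 <- inc_r2
  model
}

#' Pearson correlation with significance test
#'
#' Sample Pearson correlation and the two-sided t-test p-value, via
#' [stats::cor.test()].  Zero variance in either variable is an error.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A list with `r` and `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("need two equal-length vectors with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation between model residuals and an auxiliary variable
#'
#' Residual diagnostics: correlates the OLS residuals of a fitted
#' `pal_model` with a per-subject auxiliary variable (e.g. the fraction of
#' walking time spent in short walks) to reveal structure the model does
#' not capture.
#'
#' @param model A `pal_model` returned by [fit_pal_model()] or
#'   [stepwise_select()] (must carry its `lm` fit).
#' @param aux Auxiliary per-subject variable, same subjects and order as
#'   the model was fitted on.
#' @return A list with `r` and `p` as in [pearson()].
#' @export
residual_correlation <- function(model, aux) {
  fit <- attr(model, "fit")
  if (is.null(fit))
    stop("model carries no fit; refit with fit_pal_model()", call. = FALSE)
  res <- stats::residuals(fit)
  if (length(res) != length(aux))
    stop("aux must match the fitted subjects", call. = FALSE)
  pearson(res, aux)
}

#' Serialize a PAL model to JSON
#'
#' @param model A `pal_model`.
#' @param path File path.
#' @return `read_pal_model()` returns a `pal_model`; `write_pal_model()`
#'   returns `path` invisibly.
#' @export
write_pal_model <- function(model, path) {
  stopifnot(inherits(model, "pal_model"))
  obj <- unclass(model)
  attr(obj, "fit") <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_pal_model
#' @export
read_pal_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  preds <- as.character(obj$predictors)
  # vectors are stored in predictor order; names are not kept in JSON
  num <- function(v) suppressWarnings(as.numeric(unlist(v)))
  inc <- if (length(obj$incremental_r2)) unlist(obj$incremental_r2)
         else NULL
  new_pal_model(name = obj$name, predictors = preds,
                intercept = obj$intercept,
                coefficients = num(obj$coefficients),
                r2 = obj$r2, see = obj$see,
                coef_sd = num(obj$coef_sd),
                beta = num(obj$beta),
                p_values = num(obj$p_values),
                incremental_r2 = inc)
}
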