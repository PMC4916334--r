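test_that("PAL is the TEE/BMR ratio with plausibility guard", {
  expect_warning(expect_equal(compute_pal(6.0, 6.0), 1.0), "plausible")
  expect_equal(compute_pal(12.0, 6.0), 2.0)
  expect_error(compute_pal(-1, 6), "positive")
  expect_error(compute_pal(6, 0), "positive")
  expect_warning(compute_pal(30, 6), "plausible")
})

test_that("reference simple model evaluates the published equation", {
  expect_equal(predict_pal_simple(0), 1.24)
  expect_equal(predict_pal_simple(6200), 1.24 + 9.70e-5 * 6200)
  expect_equal(predict_pal_simple(10000), 2.21)
  # linearity: prediction at the mean equals the mean prediction
  x <- c(1000, 5000, 9000, 2000)
  expect_equal(predict_pal_simple(mean(x)), mean(predict_pal_simple(x)))
})

test_that("reference multiple model evaluates the published equation", {
  expect_equal(predict_pal_multiple(0, 0), 1.17)
  expect_equal(predict_pal_multiple(3500, 2100),
               1.17 + 10.92e-5 * 3500 + 13.42e-5 * 2100)
  expect_equal(predict_pal_multiple(7000, 0), 1.9344)
})

test_that("OLS fit recovers exact linear data and its diagnostics", {
  set.seed(5)
  x <- data.frame(activity_counts = runif(20, 3000, 9000))
  pal <- 1.2 + 8e-5 * x$activity_counts
  # noise-free fit: lm warns that the fit is essentially perfect
  m <- suppressWarnings(fit_pal_model(pal, x))
  expect_equal(m$coefficients[["activity_counts"]], 8e-5)
  expect_equal(m$intercept, 1.2)
  expect_equal(m$r2, 1)
  expect_lt(m$see, 1e-10)
  # permutation invariance
  o <- sample(20)
  m2 <- suppressWarnings(fit_pal_model(pal[o], x[o, , drop = FALSE]))
  expect_equal(m2$coefficients, m$coefficients)
  # residuals sum to zero; fitted + residuals reproduce the data
  pal2 <- pal + rnorm(20, 0, 0.1)
  m3 <- fit_pal_model(pal2, x)
  fit <- attr(m3, "fit")
  expect_lt(abs(sum(residuals(fit))), 1e-10)
  expect_equal(unname(fitted(fit) + residuals(fit)), pal2)
  # collinear predictors trigger a warning
  x2 <- data.frame(a = x$activity_counts,
                   b = x$activity_counts + rnorm(20))
  expect_warning(fit_pal_model(pal2, x2), "collinear")
})

test_that("stepwise selection keeps strong effects and drops pure noise", {
  set.seed(6)
  n <- 40
  cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  pal <- 1.8 + 0.5 * cand$a + rnorm(n, 0, 0.1)
  m <- stepwise_select(pal, cand)
  expect_identical(m$predictors, "a")
  expect_named(m$incremental_r2, "a")
  # no signal at all: intercept-only with a warning
  pal0 <- rnorm(n, 1.8, 0.1)
  expect_warning(m0 <- stepwise_select(pal0, cand), "intercept-only")
  expect_length(m0$predictors, 0)
  expect_equal(m0$intercept, mean(pal0))
})

test_that("stepwise recovers the two-signal structure on small cohorts", {
  hits <- vapply(1:25, function(r) {
    co <- simulate_cohort(cohort_spec(pal_model = pal_model_multiple(),
                                      pal_noise_sd = 0.12,
                                      seed = 500 + r))
    m <- stepwise_select(co$subjects$pal,
                         co$subjects[c("nonwalking_counts",
                                       "short_walk_counts",
                                       "long_walk_counts")])
    setequal(m$predictors, c("nonwalking_counts", "short_walk_counts"))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("pearson matches its definition and null behavior", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(1, 5)), "zero-variance")
  null_r <- vapply(1:50, function(r) {
    set.seed(900 + r)
    abs(pearson(rnorm(42), rnorm(42))$r)
  }, numeric(1))
  expect_gte(mean(null_r < 0.4), 0.95)
})

test_that("residual diagnostics obey OLS orthogonality", {
  set.seed(9)
  x <- data.frame(a = rnorm(40), s = rnorm(40))
  pal <- 1.8 + 0.4 * x$a + 0.3 * x$s + rnorm(40, 0, 0.05)
  m <- fit_pal_model(pal, x, which = "a")
  # residuals correlate with the omitted variable, with its sign
  rc <- residual_correlation(m, x$s)
  expect_gt(rc$r, 0.5)
  # residuals are orthogonal to a fitted predictor
  full <- fit_pal_model(pal, x)
  expect_lt(abs(residual_correlation(full, x$a)$r), 1e-8)
  # and perfectly correlated with themselves
  expect_equal(residual_correlation(full,
                                    residuals(attr(full, "fit")))$r, 1)
})

test_that("PAL models round-trip through JSON", {
  m <- pal_model_multiple()
  path <- withr::local_tempfile(fileext = ".json")
  write_pal_model(m, path)
  back <- read_pal_model(path)
  expect_identical(back$coefficients, m$coefficients)
  expect_identical(back$intercept, m$intercept)
  nd <- data.frame(nonwalking_counts = 3500, short_walk_counts = 2100)
  expect_identical(predict_pal(back, nd), predict_pal(m, nd))
})
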