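library(walkcounts)
slopes <- vapply(1:200, function(r) {
  co <- simulate_cohort(cohort_spec(seed = r))
  fit_pal_model(co$subjects$pal, co$subjects["activity_counts"])$coefficients[[1]]
}, numeric(1))
se <- sd(slopes)/sqrt(200)
cat("mean:", mean(slopes), "se:", se, "z:", (mean(slopes)-9.7e-5)/se, "\n")
hits <- vapply(1:200, function(r) {
  co <- simulate_cohort(cohort_spec(pal_model = pal_model_multiple(), pal_noise_sd = 0.12, seed = r))
  m <- stepwise_select(co$subjects$pal, co$subjects[c("nonwalking_counts","short_walk_counts","long_walk_counts")])
  setequal(m$predictors, c("nonwalking_counts","short_walk_counts"))
}, logical(1))
cat("stepwise exact rate:", mean(hits), "\n")
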