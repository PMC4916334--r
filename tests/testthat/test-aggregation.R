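test_that("bout dichotomy splits at one minute", {
  b11 <- find_bouts(rep("walk", 11))
  expect_identical(b11$category, "short")
  b12 <- find_bouts(rep("walk", 12))
  expect_identical(b12$category, "long")
  expect_identical(nrow(find_bouts(rep("nonwalk", 30))), 0L)
  b <- find_bouts(c("walk", "walk", "nonwalk", "walk"))
  expect_equal(b$n_epochs, c(2L, 1L))
  expect_equal(b$start_epoch, c(1L, 4L))
  expect_identical(b$category, c("short", "short"))
})

test_that("find_bouts agrees with a brute-force scan on random sequences", {
  set.seed(12)
  for (i in seq_len(10000)) {
    n <- sample(1:40, 1)
    labels <- sample(c("walk", "nonwalk", "inactive"), n, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
    got <- find_bouts(labels)
    want <- bouts_oracle(labels)
    expect_identical(got$start_epoch, want$start_epoch)
    expect_identical(got$n_epochs, want$n_epochs)
    expect_identical(got$category, want$category)
  }
})

make_labeled <- function(labels, counts = NULL) {
  if (is.null(counts))
    counts <- ifelse(labels == "inactive", 0,
                     ifelse(labels == "walk", 1.7, 0.6))
  data.frame(epoch = seq_along(labels), counts = counts, label = labels)
}

test_that("daily summaries respect the wear-time validity rule", {
  lab <- make_labeled(rep(c("walk", "nonwalk"), c(12, 24)))
  expect_false(summarize_day(lab, wear_time_h = 9.5)$valid)
  expect_true(summarize_day(lab, wear_time_h = 10.0)$valid)
  expect_false(summarize_day(lab, wear_time_h = 12,
                             missing_data = TRUE)$valid)
  idle <- make_labeled(rep("inactive", 100))
  s <- summarize_day(idle, wear_time_h = 12)
  expect_true(s$valid)
  expect_equal(s$activity_min, 0)
  expect_equal(s$activity_counts, 0)
  expect_equal(s$inactive_min, 100 * 5 / 60)
})

test_that("daily additive identities hold exactly", {
  set.seed(3)
  for (i in 1:20) {
    labels <- sample(c("walk", "nonwalk", "inactive"), 200, replace = TRUE)
    s <- summarize_day(make_labeled(labels, counts = runif(200)),
                       wear_time_h = 12)
    expect_identical(s$walking_min, s$short_walk_min + s$long_walk_min)
    expect_identical(s$walking_counts,
                     s$short_walk_counts + s$long_walk_counts)
    expect_identical(s$activity_min, s$walking_min + s$nonwalking_min)
    expect_identical(s$activity_counts,
                     s$walking_counts + s$nonwalking_counts)
  }
  dup <- make_labeled(c("walk", "walk"))
  dup$epoch <- c(1L, 1L)
  expect_error(summarize_day(dup, wear_time_h = 12), "duplicated")
})

test_that("subject summary averages valid days only", {
  d1 <- summarize_day(make_labeled(rep("walk", 24),
                                   counts = rep(2000 / 24, 24)),
                      date = as.Date("2020-01-01"), wear_time_h = 12)
  d2 <- summarize_day(make_labeled(rep("walk", 24),
                                   counts = rep(3000 / 24, 24)),
                      date = as.Date("2020-01-02"), wear_time_h = 11)
  bad <- summarize_day(make_labeled(rep("nonwalk", 24)),
                       date = as.Date("2020-01-03"), wear_time_h = 5)
  s <- summarize_subject(rbind(d1, d2))
  expect_equal(s$walking_counts, 2500)
  expect_identical(s$n_valid_days, 2L)
  # invalid days are ignored entirely; day order is irrelevant
  s2 <- summarize_subject(rbind(bad, d2, d1))
  for (col in setdiff(names(s), "subject_id"))
    expect_equal(s2[[col]], s[[col]])
  s3 <- summarize_subject(rbind(d1, bad))
  expect_equal(s3$walking_counts, d1$walking_counts)
  # zero valid days signals exclusion
  expect_error(summarize_subject(rbind(bad)),
               class = "walkcounts_no_valid_days")
  # a category with zero time has undefined (NA) intensity, not 0
  expect_true(is.na(s$nonwalking_cpm))
})

test_that("cohort table uses the mean of per-subject intensities", {
  mk_subj <- function(id, cpm, minutes = 100) {
    d <- summarize_day(make_labeled(rep("walk", 24),
                                    counts = rep(cpm * 2 / 24, 24)),
                       wear_time_h = 12)
    summarize_subject(rbind(d), subject_id = id)
  }
  s1 <- mk_subj("A", 10); s2 <- mk_subj("B", 20)
  tab <- cohort_table(rbind(s1, s2))
  walk <- tab[tab$category == "walking", ]
  expect_equal(walk$intensity_mean_cpm, 15)
  # identical subjects: zero SD everywhere
  tab2 <- cohort_table(rbind(s1, s1))
  expect_equal(tab2$time_sd_min, rep(0, 5))
  expect_error(cohort_table(s1), "at least 2")
})

test_that("non-wear detection requires 60 consecutive zero minutes", {
  cfg <- pipeline_config()
  z60 <- rep(0, 720)      # 60 min of zero-count epochs
  act <- rep(1, 120)      # 10 min active
  nw <- detect_nonwear(c(act, z60, act))
  expect_equal(sum(nw), 720)
  nw2 <- detect_nonwear(c(act, rep(0, 719), act))
  expect_equal(sum(nw2), 0)
  expect_equal(wear_time_hours(c(act, z60, act)), 20 / 60)
})
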