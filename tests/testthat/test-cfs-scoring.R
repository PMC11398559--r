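test_that("window_vitals buckets samples into half-open 24-hour windows", {
  fx <- vitals_fixture(values = c(110, 132, 95), hours = c(2, 20, 30))
  wm <- window_vitals(fx$vitals, fx$admissions, n_days = 14)
  expect_equal(wm$value[wm$day_index == 0], 132)
  expect_equal(wm$value[wm$day_index == 1], 95)

  # a sample exactly at the 24h boundary belongs to day 1
  fx2 <- vitals_fixture(values = c(100, 120), hours = c(23.9999, 24))
  wm2 <- window_vitals(fx2$vitals, fx2$admissions, n_days = 2)
  expect_equal(wm2$value[wm2$day_index == 0], 100)
  expect_equal(wm2$value[wm2$day_index == 1], 120)
})

test_that("window_vitals handles empty input, pre-admission and out-of-range samples", {
  fx <- vitals_fixture(numeric(), numeric())
  expect_identical(nrow(window_vitals(fx$vitals, fx$admissions)), 0L)

  fx <- vitals_fixture(values = c(90, 110, 100), hours = c(-1, 5, 15 * 24))
  expect_warning(wm <- window_vitals(fx$vitals, fx$admissions, n_days = 14),
                 "earlier than admission")
  expect_equal(nrow(wm), 1L)   # only the in-range sample survives
  expect_equal(wm$value, 110)

  bad <- fx$vitals
  bad$timestamp <- c("2017-03-01T02:00:00", "not-a-time", "2017-03-02T02:00:00")
  expect_error(window_vitals(bad, fx$admissions), "unparseable")
})

test_that("window_vitals is invariant to sample ordering", {
  set.seed(5)
  fx <- vitals_fixture(values = runif(50, 60, 180), hours = runif(50, 0, 14 * 24))
  wm1 <- window_vitals(fx$vitals, fx$admissions)
  shuffled <- fx$vitals[sample.int(50), ]
  wm2 <- window_vitals(shuffled, fx$admissions)
  expect_equal(wm1, wm2)
})

test_that("14 days of generated vitals produce day indices 0 through 13", {
  co <- generate_cohort(cohort_config(n_patients = 3, seed = 11))
  wm <- window_vitals(co$vitals, co$admissions, n_days = 14)
  expect_setequal(unique(wm$day_index), 0:13)
})

test_that("vital-category scoring follows left-closed rubric bands", {
  hr <- make_rubric("HR", c(100, 120, 140))
  expect_equal(score_vital_category(125, hr), 2L)
  expect_equal(score_vital_category(60, hr), 0L)
  expect_equal(score_vital_category(140, hr), 3L)   # boundary enters the higher band
  expect_equal(score_vital_category(100, hr), 1L)
  expect_error(score_vital_category(0, hr), "positive")
  expect_error(score_vital_category(-3, hr), "positive")
})

test_that("vital-category scoring is monotone non-decreasing for any valid rubric", {
  set.seed(42)
  for (rep in 1:50) {
    cuts <- sort(runif(3, 10, 200))
    if (any(diff(cuts) <= 0)) next
    r <- make_rubric(sample(CFS_VITAL_CATEGORIES, 1), cuts)
    v <- sort(runif(40, 1, 250))
    s <- score_vital_category(v, r)
    expect_true(all(diff(s) >= 0))
    expect_true(all(s %in% 0:3))
  }
})

test_that("note-rule symptom scoring maps mention to 2 and absence to 0", {
  expect_identical(score_symptom_category(TRUE), 2L)
  expect_identical(score_symptom_category(FALSE), 0L)
  expect_identical(score_symptom_category(c(TRUE, FALSE, TRUE)), c(2L, 0L, 2L))
  expect_error(score_symptom_category(NA), "TRUE/FALSE")
})

test_that("daily CFS totals are the sum of six sub-scores", {
  rub <- default_rubrics()
  top <- daily_cfs(c(HR = 150, SBP = 190, RR = 35, TEMP = 40),
                   flags = list(sweating = TRUE, posturing = TRUE),
                   rubrics = rub)
  expect_equal(top$total, 16L)          # 3+3+3+3+2+2 under the note rule
  expect_equal(unname(top$sub_scores), c(3L, 3L, 3L, 3L, 2L, 2L))

  none <- daily_cfs(numeric(), flags = list(sweating = FALSE, posturing = FALSE),
                    rubrics = rub)
  expect_equal(none$total, 0L)
  expect_length(none$missing_categories, 4L)

  mid <- daily_cfs(c(HR = 125, SBP = 100, RR = 12, TEMP = 36),
                   flags = list(sweating = TRUE, posturing = FALSE),
                   rubrics = rub)
  expect_equal(mid$total, 4L)           # HR band 2 + sweating 2
})

test_that("daily CFS invariants hold on fuzzed inputs", {
  rub <- default_rubrics()
  set.seed(99)
  for (i in 1:100) {
    present <- sample(CFS_VITAL_CATEGORIES, sample(0:4, 1))
    vals <- setNames(runif(length(present), 1, 250), present)
    d <- daily_cfs(vals, flags = list(sweating = runif(1) < 0.5,
                                      posturing = runif(1) < 0.5),
                   rubrics = rub)
    expect_equal(d$total, sum(d$sub_scores))
    expect_true(d$total >= 0 && d$total <= 18)
    expect_true(all(d$sub_scores %in% 0:3))
    expect_true(all(d$sub_scores[c("SWEATING", "POSTURING")] %in% c(0L, 2L)))
    expect_setequal(d$missing_categories, setdiff(CFS_VITAL_CATEGORIES, present))
  }
})

test_that("trajectories drop day 0, span 13 days and impute missing days", {
  full <- data.frame(day_index = 0:13, total = c(9, 1:13),
                     scored = TRUE)
  tr <- build_trajectory(full)
  expect_length(tr$values, 13L)
  expect_equal(tr$values, as.numeric(1:13))   # day 0 dropped
  expect_length(tr$imputed_days, 0L)

  # interior missing day: linear interpolation between neighbours 4 and 6
  gap <- data.frame(day_index = 0:13,
                    total = c(9, 1, 2, 3, 4, 5, 4, 99, 6, 7, 8, 9, 10, 11),
                    scored = c(rep(TRUE, 7), FALSE, rep(TRUE, 6)))
  tr2 <- build_trajectory(gap)
  expect_equal(tr2$values[7], 5)   # midpoint of day-6 value 4 and day-8 value 6
  expect_equal(tr2$imputed_days, 7L)

  # boundary missing days carry the nearest scored value
  edge <- data.frame(day_index = 0:13,
                     total = c(9, 0, 0, 5, 6, 7, 8, 9, 10, 11, 12, 13, 0, 0),
                     scored = c(TRUE, FALSE, FALSE, rep(TRUE, 9), FALSE, FALSE))
  tr3 <- build_trajectory(edge)
  expect_equal(tr3$values[1:2], c(5, 5))
  expect_equal(tr3$values[12:13], c(13, 13))
  expect_setequal(tr3$imputed_days, c(1L, 2L, 12L, 13L))
})

test_that("patients with fewer than two scored days are excluded", {
  one <- data.frame(day_index = 0:13, total = c(9, 5, rep(0, 12)),
                    scored = c(TRUE, TRUE, rep(FALSE, 12)))
  expect_message(res <- build_trajectory(one), "excluded")
  expect_null(res)
})

test_that("DLT tally counts the 11 binary indicators", {
  expect_equal(dlt_tally(rep(FALSE, 11)), 0L)
  expect_equal(dlt_tally(rep(TRUE, 11)), 11L)
  expect_equal(dlt_tally(c(rep(TRUE, 4), rep(FALSE, 7))), 4L)
  expect_error(dlt_tally(rep(TRUE, 10)), "11")
  expect_error(dlt_tally(rep(TRUE, 12)), "11")
  expect_error(dlt_tally(c(rep(TRUE, 10), NA)), "missing")
})

test_that("cohort scoring matches generated targets exactly", {
  co <- generate_cohort(cohort_config(n_patients = 8, seed = 21))
  daily <- score_cohort(co$vitals, co$flags, co$admissions)
  expect_equal(nrow(daily), 8L * 14L)
  subs <- co$targets$sub_scores
  for (i in 1:8) {
    rows <- daily[daily$patient_id == sprintf("pt%04d", i), ]
    got <- as.matrix(rows[order(rows$day_index),
                          c("hr", "sbp", "rr", "temp", "sweating", "posturing")])
    expect_equal(unname(got), unname(subs[i, , ]), ignore_attr = TRUE)
  }
  tm <- trajectory_matrix(daily)
  expect_equal(dim(tm$matrix), c(8L, 13L))
  expect_length(tm$excluded, 0L)
})
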