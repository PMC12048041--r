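test_that("accuracy coding follows the slower-belt convention", {
  expect_equal(score_accuracy(100, "left"), 1L)
  expect_equal(score_accuracy(100, "right"), 0L)
  expect_equal(score_accuracy(-50, "left"), 0L)
  expect_equal(score_accuracy(-50, "right"), 1L)
  # null trials and non-responses have no accuracy
  expect_true(is.na(score_accuracy(0, "left")))
  expect_true(is.na(score_accuracy(100, "none")))
  # vectorized
  expect_equal(score_accuracy(c(100, 0, -50), c("left", "left", "left")),
               c(1L, NA_integer_, 0L))
})

test_that("filter_trials reproduces the published removal accounting on the
           planted fixture", {
  set.seed(101)
  cohort <- generate_cohort(population_spec(n_subjects = 39),
                            protocol_spec(window_strides = 1e6))
  set.seed(102)
  planted <- plant_nonresponses(cohort$trials, paper_nonresponse_counts)
  flt <- filter_trials(planted)
  expect_equal(flt$report$n_total, 6552)
  expect_equal(flt$report$n_nonresponse, 16)
  expect_equal(round(flt$report$pct_nonresponse, 2), 0.24)
  expect_equal(flt$report$n_first_after_break, 117)
  bym <- flt$report$nonresponse_by_magnitude
  expect_equal(bym$n_nonresponse[bym$abs_delta_v_mms == 0], 5)
  expect_equal(bym$n_nonresponse[bym$abs_delta_v_mms == 50], 3)
  expect_equal(bym$n_nonresponse[bym$abs_delta_v_mms == 300], 1)
  expect_equal(bym$n_nonresponse[bym$abs_delta_v_mms == 100], 0)
  # row conservation: included + excluded = input
  expect_equal(sum(flt$trials$excluded) + nrow(included_trials(flt)),
               nrow(planted))
  # exactly one reason per excluded row
  expect_true(all(!is.na(flt$trials$exclude_reason[flt$trials$excluded])))
  expect_true(all(is.na(flt$trials$exclude_reason[!flt$trials$excluded])))
})

test_that("a table without non-responses removes nothing for that reason", {
  trials <- make_choice_trials(0, 22.1, reps = 2)
  flt <- filter_trials(trials)
  expect_equal(flt$report$n_nonresponse, 0)
  expect_equal(sum(flt$trials$excluded), 0)
})

test_that("choice coding and exclusion reasons are consistent", {
  trials <- tibble::tibble(
    subject_id = 1L, block = 1L, trial_index = 1:4,
    delta_v_mms = c(100, -100, 0, 50),
    choice = c("left", "right", "none", "left"),
    rt_s = c(2, 3, NA, 4),
    first_after_break = c(TRUE, FALSE, FALSE, FALSE)
  )
  flt <- filter_trials(trials)
  expect_equal(flt$trials$choice_code, c(1L, 0L, NA_integer_, 1L))
  expect_equal(flt$trials$exclude_reason,
               c("first_after_break", NA, "non_response", NA))
  # a first-after-break non-response carries the first_after_break reason
  trials$choice[1] <- "none"; trials$rt_s[1] <- NA
  flt2 <- filter_trials(trials)
  expect_equal(flt2$trials$exclude_reason[1], "first_after_break")
  expect_equal(flt2$report$n_nonresponse, 1)  # only the within-block one
})

test_that("per-subject summaries pool correctly", {
  set.seed(103)
  trials <- make_choice_trials(0, 30, reps = 6)
  flt <- filter_trials(trials)
  sm <- summarize_subject(flt, 1)
  expect_equal(nrow(sm$by_stimulus), 13)
  expect_equal(nrow(sm$by_magnitude), 7)
  # accuracy undefined at the null stimulus, defined elsewhere
  expect_true(is.na(sm$by_stimulus$accuracy[sm$by_stimulus$delta_v_mms == 0]))
  expect_false(is.na(sm$by_stimulus$accuracy[
    sm$by_stimulus$delta_v_mms == 300]))
  # null trials still contribute mean RT
  expect_false(is.na(sm$by_stimulus$mean_rt_s[
    sm$by_stimulus$delta_v_mms == 0]))
  # pooled accuracy is the trial-weighted average of per-stimulus accuracy
  inc <- included_trials(flt)
  acc_weighted <- sum(sm$by_stimulus$accuracy *
                        sm$by_stimulus$n * !is.na(sm$by_stimulus$accuracy),
                      na.rm = TRUE) /
    sum(sm$by_stimulus$n[!is.na(sm$by_stimulus$accuracy)])
  expect_equal(sm$overall$accuracy, mean(inc$accuracy, na.rm = TRUE))
  expect_equal(acc_weighted, sm$overall$accuracy)
  expect_error(summarize_subject(flt, 99), "subject")
})

test_that("mean RT at the null stimulus matches the chronometric value
           without censoring", {
  link <- drift_link(beta0 = 0, beta1 = 22.1, sigma = 0.5,
                     non_decision = 0.9)
  sched <- tibble::tibble(block = 1L, trial_index = 1:10000,
                          delta_v_mms = 0, first_after_break = FALSE)
  set.seed(104)
  recs <- generate_trials(link, sched, window = Inf)
  recs <- tibble::add_column(recs, subject_id = 1L, .before = 1)
  flt <- filter_trials(recs)
  sm <- summarize_subject(flt, 1)
  m <- sm$by_stimulus$mean_rt_s[sm$by_stimulus$delta_v_mms == 0]
  se <- sm$by_stimulus$se_rt_s[sm$by_stimulus$delta_v_mms == 0]
  expect_lt(abs(m - 4.9), 3 * se)
})

test_that("per-stimulus accuracy weighting identity holds on a cohort subject", {
  cohort <- small_cohort()
  flt <- filter_trials(cohort$trials)
  for (s in c(1, 4)) {
    sm <- summarize_subject(flt, s)
    ok <- !is.na(sm$by_stimulus$accuracy)
    pooled <- sum(sm$by_stimulus$accuracy[ok] * sm$by_stimulus$n[ok]) /
      sum(sm$by_stimulus$n[ok])
    expect_equal(pooled, sm$overall$accuracy, tolerance = 1e-12)
  }
})
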