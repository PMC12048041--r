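test_that("per-subject logistic fit recovers generating parameters", {
  set.seed(201)
  # ~5,070 trials over a balanced design
  trials <- make_choice_trials(beta0 = 0, beta1 = 22.1, reps = 390)
  fit <- fit_logistic_subject(filter_trials(trials), 1)
  expect_false(fit$separation)
  expect_lt(abs(fit$beta1 - 22.1) / 22.1, 0.10)
  expect_lt(abs(fit$beta0), 0.15)
})

test_that("flat choice data yields a near-zero slope and undefined metrics", {
  # perfectly counterbalanced choices: slope exactly 0 at the MLE
  dv <- rep(c(-100, -50, 0, 50, 100), each = 4)
  choice <- rep(c("left", "left", "right", "right"), times = 5)
  trials <- tibble::tibble(subject_id = 1L, block = 1L,
                           trial_index = seq_along(dv), delta_v_mms = dv,
                           choice = choice, rt_s = 1,
                           first_after_break = FALSE)
  fit <- fit_logistic_subject(filter_trials(trials), 1)
  expect_lt(abs(fit$beta1), 1e-6)
  expect_error(pse(fit), "undefined")
  expect_error(jnd(fit), "undefined")
})

test_that("complete separation triggers the ridge fallback with finite
           estimates", {
  dv <- rep(c(-300, -200, -100, 100, 200, 300), each = 10)
  trials <- tibble::tibble(
    subject_id = 1L, block = 1L, trial_index = seq_along(dv),
    delta_v_mms = dv,
    choice = ifelse(dv > 0, "left", "right"),
    rt_s = 1, first_after_break = FALSE)
  fit <- fit_logistic_subject(filter_trials(trials), 1)
  expect_true(fit$separation)
  expect_true(is.finite(fit$beta0))
  expect_true(is.finite(fit$beta1))
  expect_gt(fit$beta1, 0)
})

test_that("fit preconditions are enforced", {
  one_level <- tibble::tibble(subject_id = 1L, block = 1L, trial_index = 1:10,
                              delta_v_mms = 100, choice = "left", rt_s = 1,
                              first_after_break = FALSE)
  expect_error(fit_logistic_subject(filter_trials(one_level), 1),
               "2 distinct")
  expect_error(fit_logistic_subject(filter_trials(one_level), 2),
               "not found")
})

test_that("PSE and JND are the stated transforms of the coefficients", {
  expect_equal(pse(psychometric_fit(0, 22.1))$estimate, 0)
  expect_equal(1000 * pse(psychometric_fit(-0.1, 26))$estimate, 3.846,
               tolerance = 1e-3)
  expect_equal(1000 * pse(psychometric_fit(-0.136, 24.7))$estimate, 5.506,
               tolerance = 1e-3)
  expect_equal(jnd(psychometric_fit(0, log(3)))$estimate, 1)
  expect_equal(1000 * jnd(psychometric_fit(0, 22.1))$estimate, 49.71,
               tolerance = 1e-3)
  expect_equal(1000 * jnd(psychometric_fit(0, 26))$estimate, 42.26,
               tolerance = 1e-3)
})

test_that("PSE confidence interval propagates the intercept CI at fixed slope", {
  v <- matrix(c(0.04, 0, 0, 4), 2, 2)
  fit <- psychometric_fit(-0.5, 25, vcov = v)
  res <- pse(fit)
  z <- qnorm(0.975)
  expect_equal(res$ci, sort(c(-(-0.5 + z * 0.2) / 25, -(-0.5 - z * 0.2) / 25)))
  expect_true(res$significant)  # CI excludes 0
  wide <- pse(psychometric_fit(-0.1, 25, vcov = matrix(c(0.04, 0, 0, 4), 2)))
  expect_false(wide$significant)
})

test_that("JND confidence interval transforms the slope CI edges (skewed)", {
  v <- matrix(c(0, 0, 0, 9), 2, 2)
  fit <- psychometric_fit(0, 25, vcov = v)
  res <- jnd(fit)
  z <- qnorm(0.975)
  expect_equal(res$ci, c(log(3) / (25 + 3 * z), log(3) / (25 - 3 * z)))
  # skew: upper arm longer than lower arm
  expect_gt(res$ci[2] - res$estimate, res$estimate - res$ci[1])
})

test_that("Weber fraction converts JND to percent of mean speed", {
  expect_equal(weber_fraction(0.0497, 1.05), 4.7)
  expect_equal(weber_fraction(0.0444, 1.05), 4.2)
  expect_equal(weber_fraction(0, 1.05), 0)
  expect_error(weber_fraction(0.05, 0), "positive")
})

test_that("PSE is equivariant and JND invariant under stimulus translation", {
  set.seed(202)
  trials <- make_choice_trials(beta0 = -0.3, beta1 = 25, reps = 40)
  flt <- filter_trials(trials)
  fit <- fit_logistic_subject(flt, 1)
  shift_mms <- 50
  shifted <- trials
  shifted$delta_v_mms <- shifted$delta_v_mms + shift_mms
  fit2 <- fit_logistic_subject(filter_trials(shifted), 1)
  expect_equal(pse(fit2)$estimate, pse(fit)$estimate + shift_mms / 1000,
               tolerance = 1e-6)
  expect_equal(jnd(fit2)$estimate, jnd(fit)$estimate, tolerance = 1e-6)
})

test_that("the hierarchical fit recovers fixed effects and degenerates
           gracefully", {
  set.seed(203)
  subs <- draw_subjects(population_spec(n_subjects = 12, beta0_sd = 0.2,
                                        beta1_sd = 4))
  sched <- build_protocol(protocol_spec(), n_subjects = 12)
  trials <- make_choice_cohort(subs, sched)
  gf <- fit_mixed_logistic(filter_trials(trials))
  b1 <- gf$fixed[gf$fixed$term == "dv", ]
  expect_lt(abs(b1$estimate - 22.1), 4 * b1$se)
  expect_lt(b1$p, 0.001)
  expect_named(gf$random_sd)
  # identical subjects: random-effect SDs shrink toward zero
  set.seed(204)
  subs0 <- draw_subjects(population_spec(n_subjects = 8, beta0_sd = 0,
                                         beta1_sd = 0))
  sched0 <- build_protocol(protocol_spec(), n_subjects = 8)
  trials0 <- make_choice_cohort(subs0, sched0)
  gf0 <- fit_mixed_logistic(filter_trials(trials0))
  expect_lt(unname(gf0$random_sd[grep("Intercept", names(gf0$random_sd))]),
            0.25)
  # a single subject is rejected
  expect_error(fit_mixed_logistic(filter_trials(trials[
    trials$subject_id == 1, ])), "2 subjects")
})

test_that("group psychometric view supports PSE/JND extraction", {
  set.seed(205)
  subs <- draw_subjects(population_spec(n_subjects = 8, beta0_sd = 0.1,
                                        beta1_sd = 3))
  sched <- build_protocol(protocol_spec(), n_subjects = 8)
  gf <- fit_mixed_logistic(filter_trials(make_choice_cohort(subs, sched)))
  pf <- group_psychometric(gf)
  expect_s3_class(pf, "psychometric_fit")
  expect_gt(pf$beta1, 0)
  j <- jnd(pf)
  expect_true(j$ci[1] < j$estimate && j$estimate < j$ci[2])
})

test_that("the exogenous-factor model needs its schema and rejects a
           constant stimulus", {
  trials <- make_choice_trials(0, 22.1, reps = 3)
  flt <- filter_trials(trials)
  no_block <- flt$trials[, setdiff(names(flt$trials), "block")]
  expect_error(fit_full_model(no_block), "block")
  const <- flt$trials
  const$delta_v_mms <- 0
  expect_error(fit_full_model(const), "degenerate")
})

test_that("a planted laterality effect is detected by the full model", {
  # strong |dv| term planted in the Bernoulli generator; the coefficient's
  # sampling SE at this cohort size is ~1.1, so a planted 4 is detectable
  hits <- 0L
  for (s in 301:303) {
    set.seed(s)
    subs <- draw_subjects(population_spec(n_subjects = 20, beta0_sd = 0.2,
                                          beta1_sd = 4))
    sched <- build_protocol(protocol_spec(), n_subjects = 20)
    trials <- make_choice_cohort(subs, sched, beta4 = 4)
    gf <- fit_full_model(filter_trials(trials))
    p4 <- gf$fixed$p[gf$fixed$term == "abs_dv"]
    if (p4 < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})
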