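# Shared fixtures, built in code.

# Balanced choice-only trial table simulated directly from the logistic
# psychometric model (Bernoulli draws, no DDM involved): an independent
# generative route for testing the choice-based fitters.
make_choice_trials <- function(beta0, beta1,
                               dv_mms = c(0, 25, 50, 100, 150, 200, 300),
                               reps = 10, subject_id = 1L, blocks = 1L) {
  dv_signed <- sort(unique(c(dv_mms, -dv_mms)))
  grid <- expand.grid(delta_v_mms = dv_signed, rep = seq_len(reps),
                      block = seq_len(blocks))
  p_left <- plogis(beta0 + beta1 * grid$delta_v_mms / 1000)
  choice <- ifelse(rbinom(nrow(grid), 1, p_left) == 1, "left", "right")
  tibble::tibble(
    subject_id = subject_id,
    block = grid$block,
    trial_index = stats::ave(grid$block, grid$block, FUN = seq_along),
    delta_v_mms = grid$delta_v_mms,
    choice = choice,
    rt_s = 1,
    first_after_break = FALSE
  )
}

# Multi-subject Bernoulli choice table with optional exogenous laterality
# term on the logit (abs(dv) coefficient beta4, per m/s).
make_choice_cohort <- function(subjects, schedule, beta4 = 0) {
  out <- lapply(subjects$subject_id, function(s) {
    sub <- schedule[schedule$subject_id == s, ]
    row <- subjects[subjects$subject_id == s, ]
    dv <- sub$delta_v_mms / 1000
    mu <- row$beta0 + row$beta1 * dv + beta4 * abs(dv)
    choice <- ifelse(rbinom(length(mu), 1, plogis(mu)) == 1, "left", "right")
    tibble::tibble(
      subject_id = s, block = sub$block, trial_index = sub$trial_index,
      delta_v_mms = sub$delta_v_mms, choice = choice, rt_s = 1,
      first_after_break = sub$first_after_break
    )
  })
  do.call(rbind, out)
}

# Small default-parameter cohort shared by several tests (cached per run).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(4242)
      cache <<- generate_cohort(population_spec(n_subjects = 6),
                                protocol_spec())
    }
    cache
  }
})

paper_nonresponse_counts <- c("0" = 5, "25" = 5, "50" = 3, "150" = 2,
                              "300" = 1)
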