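#' Population specification for synthetic cohorts
#'
#' Across-subject distribution of the four generative parameters. Each
#' subject's psychometric intercept `beta0`, sensitivity `beta1`, diffusion
#' rate `sigma` and non-decision time `t_nd` are drawn from independent
#' Gaussians (truncated where noted). Defaults are calibrated to the
#' population this package models: `sigma ~ N(0.5, 0.1)` and
#' `t_nd ~ N(0.9 s, 0.7 s)` match reported group-level DDM estimates;
#' `beta1 ~ N(22.1, 8)` per m/s places the mean just-noticeable difference at
#' `ln(3) / 22.1 = 49.7` mm/s with a realistic spread; `beta0 ~ N(0, 0.4)`
#' yields small, subject-specific response biases.
#'
#' @param n_subjects Number of subjects (default 39).
#' @param beta0_mean,beta0_sd Intercept distribution (dimensionless).
#' @param beta1_mean,beta1_sd Sensitivity distribution, per m/s; draws are
#'   truncated to be positive.
#' @param sigma_mean,sigma_sd Diffusion-rate distribution; truncated > 0.
#' @param tnd_mean,tnd_sd Non-decision-time distribution in seconds;
#'   truncated >= 0.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 39,
                            beta0_mean = 0, beta0_sd = 0.4,
                            beta1_mean = 22.1, beta1_sd = 8,
                            sigma_mean = 0.5, sigma_sd = 0.1,
                            tnd_mean = 0.9, tnd_sd = 0.7) {
  sds <- c(beta0_sd, beta1_sd, sigma_sd, tnd_sd)
  if (any(sds < 0)) stop("population SDs must be >= 0")
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  structure(
    list(n_subjects = as.integer(n_subjects),
         beta0_mean = beta0_mean, beta0_sd = beta0_sd,
         beta1_mean = beta1_mean, beta1_sd = beta1_sd,
         sigma_mean = sigma_mean, sigma_sd = sigma_sd,
         tnd_mean = tnd_mean, tnd_sd = tnd_sd),
    class = "population_spec"
  )
}

# Truncated-normal draws by rejection; sd = 0 collapses to the mean
# (clamped into the support).
rnorm_trunc <- function(n, mean, sd, lower = -Inf) {
  if (sd == 0) {
    return(rep(max(mean, lower), n))
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower)
  }
  out
}

#' Draw subject-level generative parameters
#'
#' Samples `n_subjects` parameter sets from a [population_spec()]. `beta1`
#' and `sigma` are truncated strictly positive, `t_nd` non-negative.
#' Reproducible under `set.seed()`.
#'
#' @param pop A [population_spec()].
#' @return A [tibble::tibble] with columns `subject_id`, `beta0`, `beta1`,
#'   `sigma`, `t_nd`. Use [subject_link()] to turn a row into a
#'   [drift_link()].
#' @export
draw_subjects <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  n <- pop$n_subjects
  tibble::tibble(
    subject_id = seq_len(n),
    beta0 = rnorm(n, pop$beta0_mean, pop$beta0_sd),
    beta1 = rnorm_trunc(n, pop$beta1_mean, pop$beta1_sd,
                        lower = .Machine$double.eps),
    sigma = rnorm_trunc(n, pop$sigma_mean, pop$sigma_sd,
                        lower = .Machine$double.eps),
    t_nd = rnorm_trunc(n, pop$tnd_mean, pop$tnd_sd, lower = 0)
  )
}

#' Drift link for one subject row
#'
#' @param subjects A tibble from [draw_subjects()].
#' @param subject A subject id present in `subjects`.
#' @return A [drift_link()] with that subject's parameters.
#' @export
subject_link <- function(subjects, subject) {
  row <- subjects[subjects$subject_id == subject, ]
  if (nrow(row) != 1) stop("subject ", subject, " not found (or duplicated)")
  drift_link(row$beta0, row$beta1, row$sigma, row$t_nd)
}

#' Simulate one subject's trials over a schedule
#'
#' Runs the DDM trial simulator for every scheduled stimulus, adds the
#' non-decision time, and censors at the response window: trials whose
#' reaction time would exceed `window` are recorded with `choice = "none"`
#' and a missing RT, mirroring participants failing to answer within the
#' response window. Censored trials are kept in the table -- removing them is
#' preprocessing's job.
#'
#' @param link A [drift_link()] for the subject.
#' @param schedule Schedule rows for one subject ([build_protocol()] subset),
#'   with `block`, `trial_index`, `delta_v_mms`, `first_after_break`.
#' @param window Response window in seconds (must exceed the subject's
#'   non-decision time); `Inf` disables censoring.
#' @param dt Euler step for the simulator (s).
#' @return A [tibble::tibble] of trial records: `block`, `trial_index`,
#'   `delta_v_mms`, `choice` ("left"/"right"/"none"), `rt_s` (NA when
#'   `choice == "none"`), `first_after_break`.
#' @export
generate_trials <- function(link, schedule, window = 8, dt = 1e-3) {
  stopifnot(inherits(link, "drift_link"))
  if (window <= link$non_decision) {
    stop("`window` must exceed the subject's non-decision time")
  }
  dv <- schedule$delta_v_mms / 1000
  sim <- ddm_simulate_trials(link, delta_v = dv, dt = dt)
  rt <- sim$rt
  choice <- sim$choice
  censored <- rt > window
  choice[censored] <- "none"
  rt[censored] <- NA_real_
  tibble::tibble(
    block = schedule$block,
    trial_index = schedule$trial_index,
    delta_v_mms = schedule$delta_v_mms,
    choice = choice,
    rt_s = rt,
    first_after_break = schedule$first_after_break
  )
}

#' Generate a full synthetic cohort
#'
#' Draws a cohort from the population model, builds the shared stimulus
#' schedule, and simulates every trial through the DDM with response-window
#' censoring. Deterministic under `set.seed()`.
#'
#' @param pop A [population_spec()].
#' @param spec A [protocol_spec()]; the response window is taken from it.
#' @param dt Euler step for the simulator (s).
#' @param first_trial_handling Passed to [build_protocol()].
#' @return A list of class `cohort_sim` with elements `trials` (trial table
#'   with `subject_id` first), `subjects` (generating parameters), `schedule`
#'   and the two specs.
#' @examples
#' set.seed(7)
#' pop <- population_spec(n_subjects = 2)
#' cohort <- generate_cohort(pop, protocol_spec())
#' nrow(cohort$trials)  # 2 * 168
#' @export
generate_cohort <- function(pop, spec = protocol_spec(), dt = 1e-3,
                            first_trial_handling = "flag") {
  stopifnot(inherits(pop, "population_spec"))
  subjects <- draw_subjects(pop)
  schedule <- build_protocol(spec, pop$n_subjects,
                             first_trial_handling = first_trial_handling)
  window <- response_window(spec)
  trials <- lapply(subjects$subject_id, function(s) {
    link <- subject_link(subjects, s)
    recs <- generate_trials(link, schedule[schedule$subject_id == s, ],
                            window = window, dt = dt)
    tibble::add_column(recs, subject_id = s, .before = 1)
  })
  structure(
    list(trials = tibble::as_tibble(do.call(rbind, trials)),
         subjects = subjects, schedule = schedule,
         protocol = spec, population = pop),
    class = "cohort_sim"
  )
}

#' Overwrite chosen trials as non-responses
#'
#' Fixture builder for exclusion-rule tests: for each absolute stimulus
#' magnitude in `counts`, marks the requested number of randomly chosen
#' responded, non-first trials as `choice = "none"` with missing RT.
#'
#' @param trials A trial table (as in `generate_cohort()$trials`).
#' @param counts Named numeric vector: names are absolute magnitudes in mm/s,
#'   values the number of trials to censor (e.g.
#'   `c("0" = 5, "25" = 5, "50" = 3, "150" = 2, "300" = 1)`).
#' @return The modified trial table.
#' @export
plant_nonresponses <- function(trials, counts) {
  if (length(counts) == 0) return(trials)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("`counts` must be named by absolute stimulus magnitude (mm/s)")
  }
  for (nm in names(counts)) {
    mag <- as.numeric(nm)
    k <- counts[[nm]]
    if (k == 0) next
    eligible <- which(abs(trials$delta_v_mms) == mag &
                        trials$choice != "none" &
                        !trials$first_after_break)
    if (length(eligible) < k) {
      stop("requested ", k, " non-responses at |delta_v| = ", mag,
           " mm/s but only ", length(eligible), " eligible trials")
    }
    pick <- if (length(eligible) == 1L) eligible else sample(eligible, k)
    trials$choice[pick] <- "none"
    trials$rt_s[pick] <- NA_real_
  }
  trials
}

#' Write / read the trial-table CSV dialect
#'
#' Columns: `subject_id`, `block`, `trial_index`, `delta_v_mms`, `choice`
#' (left/right/none), `rt_s` (empty for non-responses), `first_after_break`
#' (0/1). UTF-8, '.' decimal, header row.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `read_trial_table()` returns the trial [tibble::tibble].
#' @export
write_trial_table <- function(trials, path) {
  out <- trials[, c("subject_id", "block", "trial_index", "delta_v_mms",
                    "choice", "rt_s", "first_after_break")]
  out$first_after_break <- as.integer(out$first_after_break)
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df$choice[is.na(df$choice) | df$choice == ""] <- "none"
  df$rt_s <- as.numeric(df$rt_s)
  df$first_after_break <- as.logical(df$first_after_break)
  tibble::as_tibble(df)
}
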