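#' Construct a psychometric fit object
#'
#' Container for a fitted logistic psychometric function
#' `P(left) = plogis(beta0 + beta1 * delta_v)` with `delta_v` in m/s. Used
#' both by the fitting routines and directly when metrics are needed for
#' known coefficients.
#'
#' @param beta0 Intercept (dimensionless).
#' @param beta1 Slope per m/s.
#' @param vcov 2x2 coefficient covariance matrix (default zero).
#' @param logLik Maximized log-likelihood (optional).
#' @param n_trials Number of trials fitted (optional).
#' @param converged,separation Diagnostic flags.
#' @return An object of class `psychometric_fit`.
#' @export
psychometric_fit <- function(beta0, beta1, vcov = matrix(0, 2, 2),
                             logLik = NA_real_, n_trials = NA_integer_,
                             converged = TRUE, separation = FALSE) {
  structure(
    list(beta0 = beta0, beta1 = beta1, vcov = vcov, logLik = logLik,
         n_trials = n_trials, converged = converged, separation = separation),
    class = "psychometric_fit"
  )
}

#' @method print psychometric_fit
#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Logistic psychometric fit: P(left) = plogis(beta0 + beta1 * dv)\n")
  cat(sprintf("  beta0 = %.4f   beta1 = %.3f per m/s   n = %s\n",
              x$beta0, x$beta1, x$n_trials))
  if (x$separation) cat("  (separation: ridge-penalized estimates)\n")
  if (!x$converged) cat("  (warning: fit did not converge)\n")
  invisible(x)
}

# Ridge-penalized logistic MLE (penalty lambda/2 * beta1^2 on the slope
# only). Used as a fallback when plain maximum likelihood diverges under
# complete separation; lambda is small enough to leave well-identified fits
# essentially untouched.
logistic_ridge <- function(y, x, lambda = 1e-4, max_iter = 200L,
                           tol = 1e-10) {
  beta <- c(0, 0)
  X <- cbind(1, x)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    grad <- drop(crossprod(X, y - p)) - c(0, lambda * beta[2])
    H <- crossprod(X * w, X) + diag(c(0, lambda))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, vcov = solve(H),
       logLik = sum(y * log(p + 1e-300) + (1 - y) * log(1 - p + 1e-300)))
}

#' Fit a subject's psychometric function by maximum likelihood
#'
#' Fits `choice_code ~ delta_v` (logit link, binomial likelihood) to one
#' subject's included, responded trials -- the standard per-subject logistic
#' psychometric fit. Stimuli are converted from mm/s to m/s internally, so
#' `beta1` is on the per-m/s scale. Under complete separation (deterministic
#' choices) the unpenalized MLE diverges; the fit then falls back to a weak
#' ridge penalty on the slope (`lambda = 1e-4`) and is flagged.
#'
#' @param clean Output of [filter_trials()] (or its `trials` element, or any
#'   table with `subject_id`, `delta_v_mms`, `choice_code` and, optionally,
#'   `excluded`).
#' @param subject Subject id.
#' @return A [psychometric_fit()].
#' @seealso [pse()], [jnd()], [weber_fraction()]
#' @export
fit_logistic_subject <- function(clean, subject) {
  if (is.list(clean) && !is.data.frame(clean) && !is.null(clean$trials)) {
    clean <- clean$trials
  }
  sub <- clean[clean$subject_id == subject, ]
  if (nrow(sub) == 0) stop("subject ", subject, " not found")
  if (!is.null(sub$excluded)) sub <- sub[!sub$excluded, ]
  sub <- sub[!is.na(sub$choice_code), ]
  dv <- sub$delta_v_mms / 1000
  y <- sub$choice_code
  if (length(unique(dv)) < 2) {
    stop("need responses at >= 2 distinct stimulus levels")
  }
  separation <- FALSE
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ dv, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(coef(fit))
  # complete/quasi separation: the stimulus ranges of the two responses do
  # not overlap, so the unpenalized MLE diverges
  separated <- (warned || !fit$converged) &&
    any(y == 1) && any(y == 0) &&
    (min(dv[y == 1]) >= max(dv[y == 0]) ||
       max(dv[y == 1]) <= min(dv[y == 0]))
  if (separated) {
    separation <- TRUE
    rf <- logistic_ridge(y, dv)
    return(psychometric_fit(rf$beta[1], rf$beta[2], vcov = rf$vcov,
                            logLik = rf$logLik, n_trials = length(y),
                            converged = TRUE, separation = TRUE))
  }
  psychometric_fit(beta[1], beta[2], vcov = unname(vcov(fit)),
                   logLik = as.numeric(logLik(fit)), n_trials = length(y),
                   converged = fit$converged, separation = FALSE)
}

check_slope <- function(fit) {
  if (!inherits(fit, "psychometric_fit")) stop("not a `psychometric_fit`")
  if (!is.finite(fit$beta1) || fit$beta1 <= 1e-8) {
    stop("psychometric slope beta1 must be positive: PSE/JND undefined ",
         "for a flat or inverted psychometric function")
  }
}

#' Point of subjective equality
#'
#' The stimulus at which both choices are equally likely,
#' `PSE = -beta0 / beta1`. The 95% confidence interval is propagated from the
#' Wald CI of `beta0` holding `beta1` fixed at its estimate; the PSE is a
#' significant bias when this interval excludes 0.
#'
#' @param fit A [psychometric_fit()] with `beta1 > 0`.
#' @param level Confidence level (default 0.95).
#' @return List with `estimate` (m/s), `ci` (length 2, m/s), `significant`.
#' @export
pse <- function(fit, level = 0.95) {
  check_slope(fit)
  z <- qnorm(1 - (1 - level) / 2)
  se0 <- sqrt(fit$vcov[1, 1])
  est <- -fit$beta0 / fit$beta1
  ci <- sort(c(-(fit$beta0 + z * se0) / fit$beta1,
               -(fit$beta0 - z * se0) / fit$beta1))
  list(estimate = est, ci = ci, significant = ci[1] > 0 || ci[2] < 0)
}

#' Just-noticeable difference
#'
#' Half the distance between the stimuli producing 25% and 75% choice rates
#' under the logistic model: `JND = ln(3) / beta1`. The confidence interval
#' applies the same transformation to the edges of the Wald CI of `beta1`,
#' giving a skewed interval.
#'
#' @param fit A [psychometric_fit()] with `beta1 > 0`.
#' @param level Confidence level (default 0.95).
#' @return List with `estimate` (m/s) and `ci` (length 2, m/s).
#' @examples
#' jnd(psychometric_fit(0, 22.1))$estimate * 1000  # 49.7 mm/s
#' @export
jnd <- function(fit, level = 0.95) {
  check_slope(fit)
  z <- qnorm(1 - (1 - level) / 2)
  se1 <- sqrt(fit$vcov[2, 2])
  lo <- fit$beta1 - z * se1
  hi <- fit$beta1 + z * se1
  est <- log(3) / fit$beta1
  ci <- c(log(3) / hi, if (lo > 0) log(3) / lo else Inf)
  list(estimate = est, ci = ci)
}

#' Weber fraction
#'
#' The JND expressed as a percentage of the reference (mean belt) speed,
#' reported to one decimal place.
#'
#' @param jnd JND in m/s (or any unit shared with `mean_speed`).
#' @param mean_speed Reference speed (> 0), same unit as `jnd`.
#' @return Weber fraction in percent, rounded to one decimal.
#' @examples
#' weber_fraction(0.0497, 1.05)  # 4.7
#' @export
weber_fraction <- function(jnd, mean_speed = 1.05) {
  if (!is.numeric(mean_speed) || mean_speed <= 0) {
    stop("`mean_speed` must be positive")
  }
  round(100 * jnd / mean_speed, 1)
}

#' Hierarchical (mixed-effects) psychometric fit
#'
#' Fits the group-level logistic psychometric model with subject-level
#' random effects: `choice_code ~ delta_v + (1 + delta_v || subject_id)`,
#' binomial family, Laplace approximation to the marginal likelihood (lme4).
#' Random intercept and slope are modeled as independent (diagonal
#' covariance). Fixed effects estimate the population-mean intercept and
#' sensitivity; Wald tests give their p-values.
#'
#' @param clean Output of [filter_trials()] (or its `trials` element).
#' @return An object of class `group_fit`: `fixed` (tibble: term, estimate,
#'   se, z, p), `random_sd` (named vector), `fit` (the underlying
#'   `glmerMod`), `converged`, `messages`.
#' @export
fit_mixed_logistic <- function(clean) {
  d <- mixed_model_data(clean)
  if (length(unique(d$subject_id)) < 2) {
    stop("mixed-effects fit requires >= 2 subjects")
  }
  fit <- lme4::glmer(choice_code ~ dv + ((1 + dv) || subject_id),
                     data = d, family = binomial(),
                     control = lme4::glmerControl(calc.derivs = FALSE))
  as_group_fit(fit)
}

mixed_model_data <- function(clean) {
  if (is.list(clean) && !is.data.frame(clean) && !is.null(clean$trials)) {
    clean <- clean$trials
  }
  if (is.null(clean$choice_code)) {
    stop("run filter_trials() first: no `choice_code` column")
  }
  d <- clean
  if (!is.null(d$excluded)) d <- d[!d$excluded, ]
  d <- d[!is.na(d$choice_code), ]
  d$dv <- d$delta_v_mms / 1000
  d$subject_id <- factor(d$subject_id)
  d
}

as_group_fit <- function(fit) {
  sm <- summary(fit)$coefficients
  fixed <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    z = sm[, "z value"],
    p = sm[, "Pr(>|z|)"]
  )
  vc <- lme4::VarCorr(fit)
  sds <- unlist(lapply(vc, function(v) attr(v, "stddev")))
  msgs <- fit@optinfo$conv$lme4$messages
  structure(
    list(fixed = fixed, random_sd = sds, fit = fit,
         converged = length(msgs) == 0,
         messages = if (is.null(msgs)) character() else msgs),
    class = "group_fit"
  )
}

#' @method print group_fit
#' @export
print.group_fit <- function(x, ...) {
  cat("Hierarchical logistic psychometric fit (Laplace)\n")
  print(as.data.frame(x$fixed), row.names = FALSE)
  cat("Random-effect SDs:\n")
  print(x$random_sd)
  if (!x$converged) cat("Convergence messages:", x$messages, sep = "\n  ")
  invisible(x)
}

#' Psychometric fit view of a group fit's fixed effects
#'
#' @param gfit A `group_fit` from [fit_mixed_logistic()].
#' @return A [psychometric_fit()] built from the fixed effects (for passing
#'   to [pse()] / [jnd()]).
#' @export
group_psychometric <- function(gfit) {
  stopifnot(inherits(gfit, "group_fit"))
  fx <- gfit$fixed[gfit$fixed$term %in% c("(Intercept)", "dv"), ]
  b0 <- fx$estimate[fx$term == "(Intercept)"]
  b1 <- fx$estimate[fx$term == "dv"]
  v <- as.matrix(vcov(gfit$fit))[c("(Intercept)", "dv"),
                                 c("(Intercept)", "dv")]
  psychometric_fit(b0, b1, vcov = unname(v),
                   n_trials = stats::nobs(gfit$fit))
}

#' Full exogenous-factor choice model
#'
#' Extends the hierarchical psychometric model with three exogenous
#' regressors: habituation (`dv_prev`, the previous trial's stimulus, 0 with
#' no predecessor at a block start), task learning (`dv` interacted with
#' block-2 and block-3 indicators) and laterality (`|dv|`, a systematic
#' difference between stimuli of equal magnitude and opposite sign).
#' Exogenous terms enter as fixed effects; subject-level random intercept and
#' `dv` slope as in [fit_mixed_logistic()]. Wald p-values at alpha = 0.05 are
#' the significance criterion.
#'
#' @param clean Output of [filter_trials()]; must carry `block` and
#'   `trial_index`.
#' @return A `group_fit` whose `fixed` table includes the exogenous terms.
#' @export
fit_full_model <- function(clean) {
  if (is.list(clean) && !is.data.frame(clean) && !is.null(clean$trials)) {
    clean <- clean$trials
  }
  for (col in c("block", "trial_index", "choice_code")) {
    if (is.null(clean[[col]])) stop("full model needs column `", col, "`")
  }
  # previous-stimulus regressor follows the *presented* order, including
  # trials later excluded from the response analysis
  d <- clean[order(clean$subject_id, clean$block, clean$trial_index), ]
  d$dv <- d$delta_v_mms / 1000
  prev <- c(0, d$dv[-nrow(d)])
  new_block <- c(TRUE, d$subject_id[-1] != d$subject_id[-nrow(d)] |
                   d$block[-1] != d$block[-nrow(d)])
  prev[new_block] <- 0
  d$dv_prev <- prev
  if (!is.null(d$excluded)) d <- d[!d$excluded, ]
  d <- d[!is.na(d$choice_code), ]
  d$subject_id <- factor(d$subject_id)
  if (length(unique(d$dv)) < 2) {
    stop("stimulus column is constant: full model is degenerate")
  }
  d$block2 <- as.integer(d$block == 2)
  d$block3 <- as.integer(d$block == 3)
  d$abs_dv <- abs(d$dv)
  fit <- lme4::glmer(
    choice_code ~ dv + dv_prev + dv:block2 + dv:block3 + abs_dv +
      ((1 + dv) || subject_id),
    data = d, family = binomial(),
    control = lme4::glmerControl(calc.derivs = FALSE))
  as_group_fit(fit)
}
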