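#' Per-stimulus mean reaction times for one subject
#'
#' Mean RT over included, responded trials at each signed stimulus level
#' (null trials included -- their mean RT, `t_nd + 1/sigma^2` at the PSE,
#' pins down the diffusion rate in the chronometric fit).
#'
#' @param clean Output of [filter_trials()] (or its `trials` element).
#' @param subject Subject id.
#' @return Tibble: `delta_v_mms`, `mean_rt_s`, `n`, `se`.
#' @export
mean_rt_by_stimulus <- function(clean, subject) {
  inc <- included_trials(clean)
  sub <- inc[inc$subject_id == subject & !is.na(inc$rt_s), ]
  if (nrow(sub) == 0) stop("no responded trials for subject ", subject)
  st <- stat_by(sub$delta_v_mms, sub$rt_s)
  tibble::tibble(delta_v_mms = st$levels, mean_rt_s = st$mean, n = st$n,
                 se = st$se)
}

# chronometric prediction: E[RT] at logit mu, diffusion sigma, latency tnd
chronometric_rt <- function(mu, sigma, tnd) {
  tnd + tanhc(mu / 2) / sigma^2
}

#' Fit the four-parameter DDM to mean reaction times
#'
#' Least-squares fit of the chronometric function
#' `E[RT](dv) = t_nd + E[t_d](r(dv), sigma)` with the linear drift link
#' `mu = beta0 + beta1 * dv`, `drift = -(sigma^2/2) * mu`, to a subject's
#' per-stimulus mean RTs. Four free parameters: `t_nd` in `[0, min RT]`,
#' `sigma > 0`, `beta0` unconstrained, and `beta1 >= 0` -- the positive-slope
#' bound breaks the sign symmetry of the RT surface by asserting that
#' subjects respond *more* accurately, not less, to larger stimuli. The
#' optimizer is bounded L-BFGS-B from a deterministic grid of 6 starts
#' spanning `t_nd` in {0, min RT / 2} and `sigma` in {0.25, 0.5, 1}; the
#' lowest-RSS solution wins and is polished once more from the winner.
#'
#' @param mean_rts Tibble from [mean_rt_by_stimulus()] (columns
#'   `delta_v_mms`, `mean_rt_s`; an optional `n` is used when
#'   `weighted = TRUE`).
#' @param weighted If TRUE, weight squared errors by `n` (inverse-variance
#'   style); default FALSE (plain least squares).
#' @return An object of class `ddm_fit`: parameters `t_nd`, `sigma`,
#'   `beta0`, `beta1`; `rss`; `fitted` (per-stimulus observed/predicted RT
#'   and predicted left-choice probability); `pse`, `jnd` (m/s; NA when
#'   `beta1 = 0`); `flat` flag.
#' @export
fit_ddm_subject <- function(mean_rts, weighted = FALSE) {
  dv <- mean_rts$delta_v_mms / 1000
  rt <- mean_rts$mean_rt_s
  ok <- is.finite(dv) & is.finite(rt)
  dv <- dv[ok]; rt <- rt[ok]
  if (length(unique(dv)) < 5) {
    stop("need mean RTs at >= 5 distinct stimulus levels to identify ",
         "4 DDM parameters")
  }
  w <- if (weighted && !is.null(mean_rts$n)) mean_rts$n[ok] else
    rep(1, length(dv))
  obj <- function(par) {
    pred <- chronometric_rt(par[3] + par[4] * dv, par[2], par[1])
    sum(w * (rt - pred)^2)
  }
  min_rt <- min(rt)
  if (diff(range(rt)) < 1e-12) {
    # flat chronometric curve: no stimulus information in the RTs
    fit <- list(par = c(min_rt - 1 / 0.25^2, 0.25, 0, 0))
    # keep t_nd in bounds for degenerate case
    fit$par[1] <- max(fit$par[1], 0)
    return(new_ddm_fit(fit$par, dv, rt, rss = obj(fit$par), flat = TRUE))
  }
  lower <- c(0, 1e-3, -50, 0)
  upper <- c(min_rt, 100, 50, 1e4)
  starts <- expand.grid(tnd = c(0, min_rt / 2), sigma = c(0.25, 0.5, 1))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(starts$tnd[i], starts$sigma[i], 0, 20)
    res <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) stop("DDM least-squares fit failed from every start")
  polish <- tryCatch(
    optim(best$par, obj, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 1000, factr = 1e1)),
    error = function(e) best)
  if (polish$value <= best$value) best <- polish
  new_ddm_fit(best$par, dv, rt, rss = best$value,
              flat = best$par[4] <= 1e-8)
}

new_ddm_fit <- function(par, dv, rt, rss, flat) {
  tnd <- par[1]; sigma <- par[2]; b0 <- par[3]; b1 <- par[4]
  mu <- b0 + b1 * dv
  fitted <- tibble::tibble(
    delta_v_mms = dv * 1000,
    mean_rt_s = rt,
    pred_rt_s = chronometric_rt(mu, sigma, tnd),
    pred_choice_left = plogis(mu)
  )
  structure(
    list(t_nd = tnd, sigma = sigma, beta0 = b0, beta1 = b1, rss = rss,
         fitted = fitted,
         pse = if (b1 > 1e-8) -b0 / b1 else NA_real_,
         jnd = if (b1 > 1e-8) log(3) / b1 else NA_real_,
         flat = flat),
    class = "ddm_fit"
  )
}

#' @method print ddm_fit
#' @export
print.ddm_fit <- function(x, ...) {
  cat("DDM chronometric fit (least squares on mean RTs)\n")
  cat(sprintf("  t_nd = %.3f s  sigma = %.3f  beta0 = %.3f  beta1 = %.2f\n",
              x$t_nd, x$sigma, x$beta0, x$beta1))
  cat(sprintf("  RSS = %.4g;  PSE = %.1f mm/s;  JND = %.1f mm/s\n",
              x$rss, 1000 * x$pse, 1000 * x$jnd))
  if (x$flat) cat("  (flat fit: beta1 = 0, RTs carry no stimulus signal)\n")
  invisible(x)
}

#' Psychometric curve predicted from reaction times alone
#'
#' Converts a chronometric [fit_ddm_subject()] fit into the choice
#' probabilities it implies: through the DDM equivalence `mu = -2 r / sigma^2`
#' the left-choice probability is `plogis(beta0 + beta1 * dv)` with the
#' coefficients estimated purely from mean RTs. Also reports the RT-derived
#' PSE and JND.
#'
#' @param fit A `ddm_fit`.
#' @param delta_v Stimulus grid in m/s.
#' @return List: `curve` (tibble `delta_v`, `p_left`), `pse`, `jnd` (m/s).
#' @export
predict_psychometric <- function(fit, delta_v) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (fit$beta1 <= 1e-8) {
    stop("beta1 = 0: JND undefined, RTs carry no stimulus signal")
  }
  tibble_curve <- tibble::tibble(
    delta_v = delta_v,
    p_left = plogis(fit$beta0 + fit$beta1 * delta_v)
  )
  list(curve = tibble_curve, pse = fit$pse, jnd = fit$jnd)
}

#' Parameter-recovery experiment
#'
#' For each seed: simulate a cohort from the generative model, preprocess,
#' fit every subject both ways -- logistic psychometric fit to choices and
#' DDM chronometric fit to mean RTs -- and compare the recovered PSE/JND to
#' the generating truth. Summarizes bias and RMSE per estimator and reports
#' the per-seed Pearson correlation between choice-based and RT-based JND
#' estimates across subjects (both estimate the same generative quantity, so
#' the correlation is expected to be positive).
#'
#' @param pop A [population_spec()].
#' @param spec A [protocol_spec()].
#' @param seeds Integer vector of seeds (one cohort per seed).
#' @param dt Euler step for simulation (s).
#' @return List: `per_subject` (tibble with truth and both estimates),
#'   `summary` (bias/RMSE per method and metric), `jnd_correlation`
#'   (per-seed tibble: seed, r, p).
#' @export
recovery_experiment <- function(pop, spec = protocol_spec(),
                                seeds = 1:5, dt = 1e-3) {
  rows <- list()
  for (sd_i in seeds) {
    set.seed(sd_i)
    cohort <- generate_cohort(pop, spec, dt = dt)
    clean <- filter_trials(cohort$trials)
    for (s in cohort$subjects$subject_id) {
      truth <- cohort$subjects[cohort$subjects$subject_id == s, ]
      psy <- tryCatch(fit_logistic_subject(clean, s), error = function(e) NULL)
      dfit <- tryCatch(fit_ddm_subject(mean_rt_by_stimulus(clean, s)),
                       error = function(e) NULL)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = sd_i, subject_id = s,
        jnd_true = log(3) / truth$beta1,
        pse_true = -truth$beta0 / truth$beta1,
        jnd_choice = if (!is.null(psy) && psy$beta1 > 1e-8)
          log(3) / psy$beta1 else NA_real_,
        pse_choice = if (!is.null(psy) && psy$beta1 > 1e-8)
          -psy$beta0 / psy$beta1 else NA_real_,
        jnd_ddm = if (!is.null(dfit)) dfit$jnd else NA_real_,
        pse_ddm = if (!is.null(dfit)) dfit$pse else NA_real_,
        sigma_ddm = if (!is.null(dfit)) dfit$sigma else NA_real_,
        tnd_ddm = if (!is.null(dfit)) dfit$t_nd else NA_real_
      )
    }
  }
  per_subject <- tibble::as_tibble(do.call(rbind, rows))
  summarize_err <- function(est, true) {
    e <- est - true
    e <- e[is.finite(e)]
    c(bias = mean(e), rmse = sqrt(mean(e^2)))
  }
  summary <- tibble::tibble(
    method = rep(c("choice", "ddm"), each = 2),
    metric = rep(c("jnd", "pse"), 2),
    bias = c(summarize_err(per_subject$jnd_choice, per_subject$jnd_true)["bias"],
             summarize_err(per_subject$pse_choice, per_subject$pse_true)["bias"],
             summarize_err(per_subject$jnd_ddm, per_subject$jnd_true)["bias"],
             summarize_err(per_subject$pse_ddm, per_subject$pse_true)["bias"]),
    rmse = c(summarize_err(per_subject$jnd_choice, per_subject$jnd_true)["rmse"],
             summarize_err(per_subject$pse_choice, per_subject$pse_true)["rmse"],
             summarize_err(per_subject$jnd_ddm, per_subject$jnd_true)["rmse"],
             summarize_err(per_subject$pse_ddm, per_subject$pse_true)["rmse"])
  )
  jnd_cor <- do.call(rbind, lapply(unique(per_subject$seed), function(sd_i) {
    d <- per_subject[per_subject$seed == sd_i, ]
    ok <- is.finite(d$jnd_choice) & is.finite(d$jnd_ddm)
    ct <- cor.test(d$jnd_choice[ok], d$jnd_ddm[ok])
    tibble::tibble(seed = sd_i, r = unname(ct$estimate), p = ct$p.value)
  }))
  list(per_subject = per_subject, summary = summary,
       jnd_correlation = tibble::as_tibble(jnd_cor))
}
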