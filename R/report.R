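#' Pearson correlation with two-sided test
#'
#' Standard Pearson product-moment correlation with the t-distribution
#' p-value, as used for the cohort-level associations between perceptual
#' sensitivity (JND), overall accuracy and mean reaction time.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite, each with
#'   non-zero variance.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return List: `r`, `p`, `n`, `significant`.
#' @examples
#' correlate(1:10, 2 * (1:10) + 1)$r  # 1
#' @export
correlate <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("`x` and `y` must be finite")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance in input")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       significant = ct$p.value < alpha)
}

#' Cohort-level summary table and correlations
#'
#' Runs the full per-subject analysis over a trial table: preprocessing,
#' logistic psychometric fit (PSE, JND, Weber fraction with CIs), overall
#' accuracy and mean RT, and the DDM chronometric fit. Assembles the
#' per-subject table, group means +/- SD, and the three Pearson correlations
#' (JND vs accuracy, accuracy vs mean RT, JND vs mean RT). With fewer than 3
#' subjects the correlation block is empty.
#'
#' @param trials A trial table (e.g. `generate_cohort()$trials` or
#'   [read_trial_table()] output).
#' @param mean_speed Mean belt speed in m/s, for the Weber fraction.
#' @param fit_ddm If TRUE (default) include per-subject DDM chronometric
#'   fits.
#' @return An object of class `cohort_summary`: `per_subject` (tibble),
#'   `group` (tibble of mean/sd per measure), `correlations` (tibble:
#'   pair, r, p, n, significant; zero rows when undefined), `removal_report`.
#' @export
build_summary <- function(trials, mean_speed = 1.05, fit_ddm = TRUE) {
  flt <- filter_trials(trials)
  clean <- flt$trials
  subjects <- sort(unique(clean$subject_id))
  rows <- lapply(subjects, function(s) {
    psy <- tryCatch(fit_logistic_subject(clean, s), error = function(e) NULL)
    overall <- summarize_subject(flt, s)$overall
    has_slope <- !is.null(psy) && is.finite(psy$beta1) && psy$beta1 > 1e-8
    pse_v <- if (has_slope) pse(psy) else NULL
    jnd_v <- if (has_slope) jnd(psy) else NULL
    dfit <- if (fit_ddm) {
      tryCatch(fit_ddm_subject(mean_rt_by_stimulus(flt, s)),
               error = function(e) NULL)
    }
    tibble::tibble(
      subject_id = s,
      beta0 = if (!is.null(psy)) psy$beta0 else NA_real_,
      beta1 = if (!is.null(psy)) psy$beta1 else NA_real_,
      pse_mms = if (has_slope) 1000 * pse_v$estimate else NA_real_,
      pse_lo_mms = if (has_slope) 1000 * pse_v$ci[1] else NA_real_,
      pse_hi_mms = if (has_slope) 1000 * pse_v$ci[2] else NA_real_,
      pse_significant = if (has_slope) pse_v$significant else NA,
      jnd_mms = if (has_slope) 1000 * jnd_v$estimate else NA_real_,
      jnd_lo_mms = if (has_slope) 1000 * jnd_v$ci[1] else NA_real_,
      jnd_hi_mms = if (has_slope) 1000 * jnd_v$ci[2] else NA_real_,
      wf_pct = if (has_slope) weber_fraction(jnd_v$estimate, mean_speed)
               else NA_real_,
      accuracy = overall$accuracy,
      mean_rt_s = overall$mean_rt_s,
      ddm_tnd_s = if (!is.null(dfit)) dfit$t_nd else NA_real_,
      ddm_sigma = if (!is.null(dfit)) dfit$sigma else NA_real_,
      ddm_jnd_mms = if (!is.null(dfit) && !dfit$flat) 1000 * dfit$jnd
                    else NA_real_,
      ddm_pse_mms = if (!is.null(dfit) && !dfit$flat) 1000 * dfit$pse
                    else NA_real_
    )
  })
  per_subject <- tibble::as_tibble(do.call(rbind, rows))
  num_cols <- c("pse_mms", "jnd_mms", "wf_pct", "accuracy", "mean_rt_s",
                "ddm_tnd_s", "ddm_sigma", "ddm_jnd_mms", "ddm_pse_mms")
  group <- tibble::tibble(
    measure = num_cols,
    mean = unname(vapply(num_cols, function(cl)
      mean(per_subject[[cl]], na.rm = TRUE), numeric(1))),
    sd = unname(vapply(num_cols, function(cl)
      sd(per_subject[[cl]], na.rm = TRUE), numeric(1)))
  )
  pairs <- list(
    c("jnd_mms", "accuracy"),
    c("accuracy", "mean_rt_s"),
    c("jnd_mms", "mean_rt_s")
  )
  cor_rows <- list()
  for (pr in pairs) {
    ok <- is.finite(per_subject[[pr[1]]]) & is.finite(per_subject[[pr[2]]])
    res <- if (sum(ok) >= 3) {
      tryCatch(correlate(per_subject[[pr[1]]][ok], per_subject[[pr[2]]][ok]),
               error = function(e) NULL)
    }
    if (!is.null(res)) {
      cor_rows[[length(cor_rows) + 1L]] <- tibble::tibble(
        pair = paste(pr[1], pr[2], sep = " ~ "),
        r = res$r, p = res$p, n = res$n, significant = res$significant)
    }
  }
  correlations <- if (length(cor_rows)) {
    tibble::as_tibble(do.call(rbind, cor_rows))
  } else {
    tibble::tibble(pair = character(), r = numeric(), p = numeric(),
                   n = integer(), significant = logical())
  }
  structure(
    list(per_subject = per_subject, group = group,
         correlations = correlations, removal_report = flt$report),
    class = "cohort_summary"
  )
}

#' @method print cohort_summary
#' @export
print.cohort_summary <- function(x, ...) {
  n <- nrow(x$per_subject)
  cat(sprintf("Cohort summary: %d subjects, %d trials (%d non-responses, %.2f%%)\n",
              n, x$removal_report$n_total, x$removal_report$n_nonresponse,
              x$removal_report$pct_nonresponse))
  g <- function(m) {
    r <- x$group[x$group$measure == m, ]
    sprintf("%.1f +/- %.1f", r$mean, r$sd)
  }
  cat("  PSE  (choice):", g("pse_mms"), "mm/s\n")
  cat("  JND  (choice):", g("jnd_mms"), "mm/s;  Weber fraction:",
      g("wf_pct"), "%\n")
  cat("  JND  (DDM-RT):", g("ddm_jnd_mms"), "mm/s\n")
  cat(sprintf("  DDM sigma: %s;  t_nd: %s s\n", g("ddm_sigma"),
              g("ddm_tnd_s")))
  if (nrow(x$correlations)) {
    cat("Correlations:\n")
    for (i in seq_len(nrow(x$correlations))) {
      cat(sprintf("  %-24s r = %6.3f  p = %.3g\n", x$correlations$pair[i],
                  x$correlations$r[i], x$correlations$p[i]))
    }
  }
  invisible(x)
}
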