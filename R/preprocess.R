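#' Accuracy coding for 2AFC trials
#'
#' A response is correct (1) when it names the slower belt: with
#' `delta_v = V_R - V_L`, positive stimuli mean the left belt is slower, so
#' `delta_v > 0` with a "left" choice scores 1, and symmetrically for
#' `delta_v < 0`. Accuracy is undefined (NA) for null trials (no correct
#' answer exists) and for non-responses.
#'
#' @param delta_v Signed stimulus (any consistent unit); vectorized.
#' @param choice Character vector: "left", "right" or "none".
#' @return Integer vector of 1/0/NA.
#' @examples
#' score_accuracy(c(100, 0, -50), c("left", "left", "left"))  # 1 NA 0
#' @export
score_accuracy <- function(delta_v, choice) {
  out <- rep(NA_integer_, length(delta_v))
  resp <- choice %in% c("left", "right") & delta_v != 0
  out[resp] <- as.integer((delta_v[resp] > 0) == (choice[resp] == "left"))
  out
}

#' Apply trial-exclusion rules and derive analysis columns
#'
#' Adds `choice_code` (1 = left, 0 = right, NA = none), `accuracy`
#' (see [score_accuracy()]) and an exclusion flag with a single reason per
#' excluded row: the first trial of each block after a break
#' (`first_after_break`) or a trial with no response inside the window
#' (`non_response`). When both apply, `first_after_break` takes precedence:
#' the removal report counts non-responses *within* blocks only, matching
#' the accounting convention in which first-trial misses are tallied
#' separately. No rows are dropped; downstream fits subset on `!excluded`.
#'
#' @param trials Trial table with `subject_id`, `block`, `trial_index`,
#'   `delta_v_mms`, `choice`, `rt_s`, `first_after_break`.
#' @return A list with `trials` (the input plus derived columns) and
#'   `report`: `n_total`, `n_nonresponse`, `pct_nonresponse` (percent of all
#'   trials), `nonresponse_by_magnitude` (tibble keyed by `abs_delta_v_mms`),
#'   `n_first_after_break`.
#' @export
filter_trials <- function(trials) {
  needed <- c("subject_id", "block", "trial_index", "delta_v_mms", "choice",
              "rt_s", "first_after_break")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  }
  choice_code <- ifelse(trials$choice == "left", 1L,
                        ifelse(trials$choice == "right", 0L, NA_integer_))
  accuracy <- score_accuracy(trials$delta_v_mms, trials$choice)
  reason <- rep(NA_character_, nrow(trials))
  reason[trials$choice == "none"] <- "non_response"
  reason[trials$first_after_break] <- "first_after_break"
  clean <- tibble::as_tibble(trials)
  clean$choice_code <- choice_code
  clean$accuracy <- accuracy
  clean$excluded <- !is.na(reason)
  clean$exclude_reason <- reason
  nonresp <- clean[!is.na(reason) & reason == "non_response", ]
  mags <- sort(unique(abs(clean$delta_v_mms)))
  by_mag <- tibble::tibble(
    abs_delta_v_mms = mags,
    n_nonresponse = vapply(mags, function(m) {
      sum(abs(nonresp$delta_v_mms) == m)
    }, integer(1))
  )
  list(
    trials = clean,
    report = list(
      n_total = nrow(clean),
      n_nonresponse = nrow(nonresp),
      pct_nonresponse = 100 * nrow(nonresp) / nrow(clean),
      nonresponse_by_magnitude = by_mag,
      n_first_after_break = sum(trials$first_after_break)
    )
  )
}

#' Included (analysis) trials of a clean table
#'
#' @param clean Either the list returned by [filter_trials()] or its
#'   `trials` element.
#' @return The non-excluded trial rows.
#' @export
included_trials <- function(clean) {
  if (is.list(clean) && !is.data.frame(clean) && !is.null(clean$trials)) {
    clean <- clean$trials
  }
  if (is.null(clean$excluded)) {
    stop("run filter_trials() first: no `excluded` column present")
  }
  clean[!clean$excluded, ]
}

# shared helper: mean/se/n over a grouping of included trials
stat_by <- function(key, values) {
  levels <- sort(unique(key))
  n <- vapply(levels, function(l) sum(key == l & !is.na(values)), integer(1))
  m <- vapply(levels, function(l) mean(values[key == l], na.rm = TRUE),
              numeric(1))
  s <- vapply(levels, function(l) {
    v <- values[key == l & !is.na(values)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  list(levels = levels, n = n, mean = ifelse(n > 0, m, NA_real_), se = s)
}

#' Per-subject outcome summaries
#'
#' Means over *included* responded trials: per signed stimulus (13 levels in
#' the default protocol) and pooled over absolute magnitude (7 levels), for
#' reaction time, accuracy and left-choice fraction, with standard errors;
#' plus the subject's overall mean RT and overall accuracy. Null trials
#' contribute RT and choice fraction but never accuracy.
#'
#' @param clean Output of [filter_trials()] (or its `trials` element).
#' @param subject Subject id.
#' @return A list with tibbles `by_stimulus`, `by_magnitude`, and a one-row
#'   `overall`.
#' @export
summarize_subject <- function(clean, subject) {
  inc <- included_trials(clean)
  sub <- inc[inc$subject_id == subject, ]
  if (nrow(sub) == 0) stop("no included trials for subject ", subject)
  rt <- stat_by(sub$delta_v_mms, sub$rt_s)
  acc <- stat_by(sub$delta_v_mms, sub$accuracy)
  chc <- stat_by(sub$delta_v_mms, sub$choice_code)
  by_stimulus <- tibble::tibble(
    delta_v_mms = rt$levels, n = rt$n,
    mean_rt_s = rt$mean, se_rt_s = rt$se,
    accuracy = acc$mean, se_accuracy = acc$se,
    choice_left = chc$mean, se_choice_left = chc$se
  )
  rt_m <- stat_by(abs(sub$delta_v_mms), sub$rt_s)
  acc_m <- stat_by(abs(sub$delta_v_mms), sub$accuracy)
  by_magnitude <- tibble::tibble(
    abs_delta_v_mms = rt_m$levels, n = rt_m$n,
    mean_rt_s = rt_m$mean, se_rt_s = rt_m$se,
    accuracy = acc_m$mean, se_accuracy = acc_m$se
  )
  overall <- tibble::tibble(
    subject_id = subject,
    n_trials = nrow(sub),
    mean_rt_s = mean(sub$rt_s, na.rm = TRUE),
    accuracy = mean(sub$accuracy, na.rm = TRUE)
  )
  list(by_stimulus = by_stimulus, by_magnitude = by_magnitude,
       overall = overall)
}
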