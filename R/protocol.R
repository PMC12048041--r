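#' Stimulus-protocol specification
#'
#' Describes the 2AFC testing protocol: walking at a mean belt speed, signed
#' belt-speed differences `delta_v = V_R - V_L` drawn from a fixed stimulus
#' set, presented in balanced pseudo-random blocks, with a response window of
#' a fixed number of strides. Defaults reproduce the study design this
#' package targets: stimuli {0, +/-25, +/-50, +/-100, +/-150, +/-200, +/-300}
#' mm/s at a mean speed of 1.05 m/s, 4 repetitions of every signed non-zero
#' magnitude and 8 null trials per block (56 trials/block), 3 blocks, and an
#' 8-stride (~8 s) response window.
#'
#' @param mean_speed Mean belt speed in m/s (default 1.05).
#' @param nonzero_magnitudes Positive stimulus magnitudes in mm/s; each is
#'   presented with both signs.
#' @param reps_per_nonzero Presentations of each signed magnitude per block;
#'   must be divisible by 4 (the block is built from 4 sequence variants).
#' @param null_reps Null-trial (0 mm/s) presentations per block; divisible
#'   by 4.
#' @param blocks Number of testing blocks.
#' @param window_strides Response-window length in strides.
#' @param stride_duration Stride duration in seconds (window =
#'   `window_strides * stride_duration`).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(mean_speed = 1.05,
                          nonzero_magnitudes = c(25, 50, 100, 150, 200, 300),
                          reps_per_nonzero = 4,
                          null_reps = 8,
                          blocks = 3,
                          window_strides = 8,
                          stride_duration = 1) {
  if (mean_speed <= 0) stop("`mean_speed` must be positive")
  if (length(nonzero_magnitudes) < 1 || any(nonzero_magnitudes <= 0) ||
      anyDuplicated(nonzero_magnitudes)) {
    stop("`nonzero_magnitudes` must be distinct positive values (mm/s)")
  }
  if (reps_per_nonzero %% 4 != 0 || reps_per_nonzero < 4) {
    stop("`reps_per_nonzero` must be a positive multiple of 4: each block ",
         "is assembled from 4 variants of a base sequence")
  }
  if (null_reps %% 4 != 0 || null_reps < 0) {
    stop("`null_reps` must be a non-negative multiple of 4")
  }
  if (blocks < 1) stop("`blocks` must be >= 1")
  if (window_strides <= 0 || stride_duration <= 0) {
    stop("`window_strides` and `stride_duration` must be positive")
  }
  structure(
    list(mean_speed = mean_speed,
         nonzero_magnitudes = sort(nonzero_magnitudes),
         reps_per_nonzero = reps_per_nonzero,
         null_reps = null_reps,
         blocks = blocks,
         window_strides = window_strides,
         stride_duration = stride_duration),
    class = "protocol_spec"
  )
}

#' Response-window duration of a protocol, in seconds
#' @param spec A [protocol_spec()].
#' @export
response_window <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  spec$window_strides * spec$stride_duration
}

#' Trials per block implied by a protocol
#' @param spec A [protocol_spec()].
#' @export
trials_per_block <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  2L * length(spec$nonzero_magnitudes) * spec$reps_per_nonzero +
    spec$null_reps
}

#' Build one pseudo-random testing block
#'
#' Constructs a base pseudo-random sequence containing each signed magnitude
#' `reps_per_nonzero / 4` times and `null_reps / 4` null trials, then emits
#' four variants -- the base, its mirror image (all signs negated), the base
#' with presentation order flipped (reversed), and the mirrored-and-flipped
#' sequence -- concatenated into one block. The construction guarantees exact
#' balance: every `+m` occurs as often as `-m` within the block. Uses the
#' current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param spec A [protocol_spec()].
#' @return A [tibble::tibble] with columns `trial_index` and `delta_v_mms`
#'   (signed, mm/s).
#' @examples
#' set.seed(1)
#' blk <- build_block(protocol_spec())
#' nrow(blk)                     # 56
#' sum(blk$delta_v_mms == 0)     # 8
#' @export
build_block <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  signed <- c(spec$nonzero_magnitudes, -spec$nonzero_magnitudes)
  base <- c(rep(signed, spec$reps_per_nonzero / 4),
            rep(0, spec$null_reps / 4))
  base <- sample(base)
  seq56 <- c(base, -base, rev(base), rev(-base))
  tibble::tibble(trial_index = seq_along(seq56), delta_v_mms = seq56)
}

#' Build the full cohort schedule
#'
#' Builds `spec$blocks` testing blocks (each via [build_block()]) and
#' replicates the identical stimulus order across all subjects, mirroring the
#' design in which the same pseudo-random order was used for every
#' participant. The first trial of every block is flagged
#' `first_after_break`: participants frequently miss the first task after the
#' treadmill restarts, and preprocessing excludes it.
#'
#' `first_trial_handling` controls whether the first trial's stimulus is
#' additionally re-appended at the end of each block (`"append"`), so that
#' per-magnitude repetition counts are preserved after the first-trial drop,
#' at the cost of one extra presented trial per block; the default `"flag"`
#' keeps blocks at exactly `trials_per_block(spec)` rows.
#'
#' @param spec A [protocol_spec()].
#' @param n_subjects Number of subjects (>= 1).
#' @param first_trial_handling `"flag"` (default) or `"append"`; see Details.
#' @return A [tibble::tibble] schedule with columns `subject_id`, `block`,
#'   `trial_index` (1-based within block), `delta_v_mms`,
#'   `first_after_break` (logical).
#' @examples
#' set.seed(1)
#' sched <- build_protocol(protocol_spec(), n_subjects = 2)
#' nrow(sched)  # 2 * 3 * 56
#' @export
build_protocol <- function(spec, n_subjects,
                           first_trial_handling = c("flag", "append")) {
  stopifnot(inherits(spec, "protocol_spec"))
  first_trial_handling <- match.arg(first_trial_handling)
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop("`n_subjects` must be >= 1")
  }
  n_subjects <- as.integer(n_subjects)
  blocks <- lapply(seq_len(spec$blocks), function(b) {
    blk <- build_block(spec)
    if (first_trial_handling == "append") {
      blk <- tibble::add_row(blk, trial_index = nrow(blk) + 1L,
                             delta_v_mms = blk$delta_v_mms[1])
    }
    tibble::tibble(block = b,
                   trial_index = blk$trial_index,
                   delta_v_mms = blk$delta_v_mms,
                   first_after_break = blk$trial_index == 1L)
  })
  one_subject <- do.call(rbind, blocks)
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    tibble::add_column(one_subject, subject_id = s, .before = 1)
  }))
  tibble::as_tibble(out)
}

#' Validate a schedule against its protocol
#'
#' Tabulates per-(subject, block, stimulus) presentation counts and lists
#' every deviation from the protocol's prescribed composition
#' (`reps_per_nonzero` for each signed magnitude, `null_reps` for 0 mm/s).
#'
#' @param schedule A schedule as returned by [build_protocol()] (or any table
#'   with `subject_id`, `block`, `delta_v_mms`).
#' @param spec The [protocol_spec()] the schedule should satisfy.
#' @return A list with `counts` (tibble: subject_id, block, delta_v_mms, n)
#'   and `violations` (tibble: subject_id, block, delta_v_mms, expected,
#'   observed); `violations` has zero rows iff the schedule conforms.
#' @export
validate_schedule <- function(schedule, spec = protocol_spec()) {
  stopifnot(inherits(spec, "protocol_spec"))
  expected_levels <- c(-rev(spec$nonzero_magnitudes), 0,
                       spec$nonzero_magnitudes)
  expected_n <- ifelse(expected_levels == 0, spec$null_reps,
                       spec$reps_per_nonzero)
  if (nrow(schedule) == 0) {
    counts <- tibble::tibble(subject_id = integer(), block = integer(),
                             delta_v_mms = numeric(), n = integer())
    violations <- tibble::tibble(subject_id = NA_integer_, block = NA_integer_,
                                 delta_v_mms = expected_levels,
                                 expected = expected_n, observed = 0L)
    return(list(counts = counts, violations = violations))
  }
  groups <- unique(schedule[, c("subject_id", "block")])
  counts_list <- list()
  viol_list <- list()
  for (i in seq_len(nrow(groups))) {
    sub <- schedule[schedule$subject_id == groups$subject_id[i] &
                      schedule$block == groups$block[i], ]
    obs <- vapply(expected_levels,
                  function(m) sum(sub$delta_v_mms == m), integer(1))
    counts_list[[i]] <- tibble::tibble(
      subject_id = groups$subject_id[i], block = groups$block[i],
      delta_v_mms = expected_levels, n = obs)
    bad <- obs != expected_n
    if (any(bad)) {
      viol_list[[length(viol_list) + 1L]] <- tibble::tibble(
        subject_id = groups$subject_id[i], block = groups$block[i],
        delta_v_mms = expected_levels[bad],
        expected = expected_n[bad], observed = obs[bad])
    }
  }
  list(
    counts = tibble::as_tibble(do.call(rbind, counts_list)),
    violations = if (length(viol_list)) {
      tibble::as_tibble(do.call(rbind, viol_list))
    } else {
      tibble::tibble(subject_id = integer(), block = integer(),
                     delta_v_mms = numeric(), expected = integer(),
                     observed = integer())
    }
  )
}
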