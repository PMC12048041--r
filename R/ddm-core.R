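#' Drift-diffusion model parameters
#'
#' Bundle the four parameters of the simplest two-barrier drift-diffusion
#' model (DDM): a Wiener process with drift `r`, diffusion rate `sigma`,
#' symmetric absorbing barriers at `+barrier` and `-barrier`, and an additive
#' non-decision latency `non_decision`. The model is scale invariant --
#' multiplying `drift`, `sigma` and `barrier` by a common factor leaves choice
#' probabilities and the decision-time distribution unchanged -- so the
#' barrier is conventionally normalized to 1 and only exposed here to make
#' that invariance testable.
#'
#' Sign convention: the "left" choice (left belt reported slower) is the
#' barrier reached with probability `1 / (1 + exp(2 * drift / sigma^2))`,
#' i.e. the *lower* barrier. Under the linear drift link (see
#' [drift_link()]), a positive logit `mu = beta0 + beta1 * delta_v` maps to a
#' negative drift, so stimuli with the left belt slower drive the walk toward
#' the left-choice barrier. The expected decision time depends on `|drift|`
#' only, so this labelling has no effect on reaction-time predictions.
#'
#' @param drift Drift rate `r`, evidence units per second (signed).
#' @param sigma Diffusion rate, evidence units per sqrt-second; must be > 0.
#' @param barrier Barrier magnitude `a` (> 0). Default 1 (normalization).
#' @param non_decision Non-decision time in seconds (>= 0).
#' @return An object of class `ddm_params`.
#' @seealso [ddm_choice_probability()], [ddm_expected_decision_time()],
#'   [ddm_simulate_trials()]
#' @examples
#' p <- ddm_params(drift = 0.5, sigma = 0.5)
#' ddm_choice_probability(p)
#' @export
ddm_params <- function(drift, sigma, barrier = 1, non_decision = 0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` (diffusion rate) must be a single positive number")
  }
  if (!is.numeric(barrier) || length(barrier) != 1L || barrier <= 0) {
    stop("`barrier` must be a single positive number")
  }
  if (!is.numeric(non_decision) || length(non_decision) != 1L ||
      non_decision < 0) {
    stop("`non_decision` must be a single non-negative number")
  }
  if (!is.numeric(drift) || length(drift) != 1L || !is.finite(drift)) {
    stop("`drift` must be a single finite number")
  }
  structure(
    list(drift = drift, sigma = sigma, barrier = barrier,
         non_decision = non_decision),
    class = "ddm_params"
  )
}

#' Linear stimulus-to-drift link
#'
#' Parametrizes the DDM drift rate as a linear function of the belt-speed
#' difference `delta_v` (in m/s): the choice logit is
#' `mu(delta_v) = beta0 + beta1 * delta_v` and the drift driving the walk is
#' `drift = -(sigma^2 / 2) * mu`, so that the DDM left-choice probability is
#' exactly the logistic `plogis(mu)` of the psychometric model. `beta0`
#' captures response bias, `beta1` (units 1 / (m/s)) perceptual sensitivity;
#' `sigma` and `non_decision` are stimulus independent.
#'
#' @param beta0 Intercept of the choice logit (dimensionless).
#' @param beta1 Slope of the choice logit per m/s of belt-speed difference.
#' @param sigma Diffusion rate (> 0).
#' @param non_decision Non-decision time in seconds (>= 0).
#' @return An object of class `drift_link`.
#' @examples
#' link <- drift_link(beta0 = 0, beta1 = 22.1, sigma = 0.5, non_decision = 0.9)
#' ddm_expected_rt(link, delta_v = 0)  # 0.9 + 1/sigma^2 = 4.9 s
#' @export
drift_link <- function(beta0, beta1, sigma, non_decision) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` (diffusion rate) must be a single positive number")
  }
  if (!is.numeric(non_decision) || length(non_decision) != 1L ||
      non_decision < 0) {
    stop("`non_decision` must be a single non-negative number")
  }
  structure(
    list(beta0 = beta0, beta1 = beta1, sigma = sigma,
         non_decision = non_decision),
    class = "drift_link"
  )
}

#' Drift rate implied by a drift link at a stimulus
#'
#' @param link A [drift_link()] object.
#' @param delta_v Belt-speed difference(s) in m/s.
#' @return Drift rate(s) `-(sigma^2 / 2) * (beta0 + beta1 * delta_v)`.
#' @export
link_drift <- function(link, delta_v) {
  stopifnot(inherits(link, "drift_link"))
  -(link$sigma^2 / 2) * (link$beta0 + link$beta1 * delta_v)
}

#' Probability of the left choice under the DDM
#'
#' Closed-form absorption probability of the left-choice barrier for a Wiener
#' process with drift between symmetric barriers:
#' `p_left = 1 / (1 + exp(2 * r * a / sigma^2))`. With the drift link
#' `drift = -(sigma^2 / 2) * mu` and unit barrier this is identically the logistic
#' `plogis(mu)`, which is how the DDM generates the logistic psychometric
#' function.
#'
#' @param params A [ddm_params()] object.
#' @return `p_left` in (0, 1); the right-choice probability is `1 - p_left`.
#' @examples
#' ddm_choice_probability(ddm_params(drift = 0, sigma = 0.5))  # 0.5
#' @export
ddm_choice_probability <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  # plogis(-x) = 1/(1+exp(x)): numerically stable for large |drift|
  plogis(-2 * params$drift * params$barrier / params$sigma^2)
}

#' Expected decision time under the DDM
#'
#' Closed-form mean first-passage time to either barrier,
#' `E[t_d] = (a / r) * tanh(r * a / sigma^2)`, an even function of the drift.
#' A fourth-order Taylor branch is used for `|r * a / sigma^2| < 1e-4` so the
#' function is continuous at zero drift, where the limit is `barrier^2 / sigma^2`.
#'
#' @param params A [ddm_params()] object.
#' @return Mean decision time in seconds (> 0); excludes non-decision time.
#' @examples
#' ddm_expected_decision_time(ddm_params(drift = 0.5, sigma = 0.5)) # 2*tanh(2)
#' @export
ddm_expected_decision_time <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  a <- params$barrier
  z <- params$drift * a / params$sigma^2
  (a^2 / params$sigma^2) * tanhc(z)
}

# tanh(z)/z with a series branch near 0 (vectorized)
tanhc <- function(z) {
  out <- numeric(length(z))
  small <- abs(z) < 1e-4
  out[small] <- 1 - z[small]^2 / 3 + 2 * z[small]^4 / 15
  out[!small] <- tanh(z[!small]) / z[!small]
  out
}

#' Expected reaction time as a function of the stimulus
#'
#' The chronometric function implied by a [drift_link()]: non-decision time
#' plus the expected decision time at the stimulus-dependent drift. It is
#' maximal at `delta_v = -beta0 / beta1` (the point of subjective equality,
#' where the drift vanishes and `E[t_d] = 1 / sigma^2`) and strictly
#' decreasing in `|beta0 + beta1 * delta_v|`.
#'
#' @param link A [drift_link()] object.
#' @param delta_v Belt-speed difference(s) in m/s; vectorized.
#' @return Expected reaction time(s) in seconds.
#' @export
ddm_expected_rt <- function(link, delta_v) {
  stopifnot(inherits(link, "drift_link"))
  mu <- link$beta0 + link$beta1 * delta_v
  link$non_decision + tanhc(mu / 2) / link$sigma^2
}

#' Simulate DDM trials by Euler-Maruyama integration
#'
#' Integrates `dx = r dt + sigma dw` from `x = 0` until `|x|` reaches the
#' barrier, in steps of `dt`, and records the barrier hit and the decision
#' time. The left choice is the lower barrier (see [ddm_params()] for the
#' sign convention). Uses R's RNG stream, so results are reproducible with
#' `set.seed()`.
#'
#' @param params A [ddm_params()] object, or a [drift_link()] together with
#'   `delta_v`.
#' @param n Number of trials (ignored when `delta_v` supplies one drift per
#'   trial).
#' @param delta_v Optional vector of stimuli (m/s), one trial each, when
#'   `params` is a `drift_link`.
#' @param dt Euler step in seconds (default 1e-3).
#' @param max_steps Hard cap on steps per trial; exceeding it is an error
#'   (practically unreachable for sensible parameters).
#' @return A [tibble::tibble] with columns `choice` ("left"/"right"),
#'   `barrier` (+1 upper, -1 lower), `decision_time` and `rt` (seconds).
#' @examples
#' set.seed(1)
#' ddm_simulate_trials(ddm_params(drift = 0, sigma = 0.5), n = 5)
#' @export
ddm_simulate_trials <- function(params, n = 1L, delta_v = NULL, dt = 1e-3,
                                max_steps = 1e6L) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number")
  }
  if (inherits(params, "drift_link")) {
    if (is.null(delta_v)) {
      stop("supply `delta_v` (one stimulus per trial) with a `drift_link`")
    }
    drift <- link_drift(params, delta_v)
    sigma <- params$sigma
    barrier <- 1
    t_nd <- params$non_decision
  } else {
    stopifnot(inherits(params, "ddm_params"))
    drift <- rep(params$drift, n)
    sigma <- params$sigma
    barrier <- params$barrier
    t_nd <- params$non_decision
  }
  sim <- simulate_fp_cpp(as.numeric(drift), sigma, barrier, dt,
                         as.integer(max_steps))
  tibble::tibble(
    choice = ifelse(sim$barrier < 0, "left", "right"),
    barrier = sim$barrier,
    decision_time = sim$decision_time,
    rt = sim$decision_time + t_nd
  )
}
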