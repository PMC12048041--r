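---
title: "Modeling the perception of belt-speed differences in split-belt walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the perception of belt-speed differences in split-belt walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beltddm)
```

## The scientific problem

On a split-belt treadmill the two belts can move each leg at different
speeds. How small a difference $\Delta V = V_R - V_L$ can a walking person
detect? `beltddm` implements a complete analysis pipeline for
two-alternative forced-choice (2AFC) experiments that answer this question:
on each trial the participant feels some belt-speed difference and must
press a key for "left belt slower" or "right belt slower" within a response
window of about 8 strides. Three quantities characterize perception here:

* **PSE** (point of subjective equality): the stimulus at which both
  responses are equally likely — a measure of response bias;
* **JND** (just-noticeable difference): half the distance between the
  stimuli producing 25% and 75% choice rates — a measure of sensitivity;
* **Weber fraction**: the JND as a percentage of the mean belt speed.

The package provides two routes to these quantities — a psychometric route
through the choices, and a chronometric route through the reaction times —
plus a synthetic-data generator so that every stage is testable without any
experimental data.

## The psychometric model

Choices are Bernoulli draws with left-choice probability

$$
P(\text{left} \mid \Delta V) \;=\;
\frac{1}{1 + e^{-\mu(\Delta V)}}, \qquad
\mu(\Delta V) = \beta_0 + \beta_1 \Delta V,
$$

with $\Delta V$ in m/s, so $\beta_1$ has units of 1/(m/s). Positive
$\Delta V$ (right belt faster) means the left belt is the slower one, so a
"left" choice is then correct. From the coefficients,

$$
\mathrm{PSE} = -\beta_0/\beta_1, \qquad
\mathrm{JND} = \ln(3)/\beta_1,
$$

the latter because the logit spans $\pm\ln 3$ between the 25% and 75%
points. `fit_logistic_subject()` estimates $(\beta_0, \beta_1)$ per subject
by maximum likelihood (`glm`, binomial/logit); `fit_mixed_logistic()`
estimates population means with subject-level Gaussian random effects via
the Laplace approximation (`lme4::glmer`). `pse()` and `jnd()` apply the
transforms above with the confidence-interval conventions described below.

## The drift-diffusion model

The same choices, and additionally the reaction times, are modeled as the
outcome of noisy evidence accumulation: a Wiener process
$dx = r\,dt + \sigma\,dw$ starting at 0 between absorbing barriers $\pm a$.
The barrier reached determines the choice; the first-passage time is the
decision time $t_d$, and the observable reaction time is
$RT = t_d + t_{nd}$ with a non-decision latency $t_{nd}$ (stimulus encoding
and motor execution). The model is scale invariant in $(r, \sigma, a)$, so
$a = 1$ throughout. Closed forms used by the package:

$$
p_{\text{left}} = \frac{1}{1 + e^{2ra/\sigma^2}}, \qquad
E[t_d] = \frac{a}{r}\tanh\!\left(\frac{ra}{\sigma^2}\right).
$$

The drift is linear in the stimulus, expressed so that the DDM reproduces
the psychometric model exactly: $r(\Delta V) = -(\sigma^2/2)\,\mu(\Delta V)$
makes $p_\text{left} = \mathrm{logistic}(\mu)$, an identity
`ddm_choice_probability()` satisfies to machine precision. $E[t_d]$ depends
only on $|r|$, so the chronometric function

$$
E[RT](\Delta V) \;=\; t_{nd} +
\frac{1}{\sigma^2}\,\frac{\tanh\!\big(\mu(\Delta V)/2\big)}{\mu(\Delta V)/2}
$$

peaks at the PSE (where it equals $t_{nd} + 1/\sigma^2$) and falls toward
$t_{nd}$ for large $|\Delta V|$. `fit_ddm_subject()` fits the four
parameters $(t_{nd}, \sigma, \beta_0, \beta_1)$ to a subject's per-stimulus
mean RTs by least squares, after which `predict_psychometric()` yields a
full choice curve — and therefore PSE and JND — obtained *from reaction
times alone*. Null trials are included in the fit deliberately: their mean
RT pins down $\sigma$ through the peak value $t_{nd} + 1/\sigma^2$.

### Sign convention

The first-passage formula above assigns probability
$1/(1+e^{2ra/\sigma^2})$ to the *lower* barrier of a walk with drift $r$.
The package therefore labels the lower barrier as the "left" choice: with
$r = -(\sigma^2/2)\mu$, a stimulus with the left belt slower ($\mu > 0$)
drives the walk downward, toward the left-choice barrier. Since $E[t_d]$ is
even in $r$, RT predictions are unaffected by the labelling; only the
internal pairing of barrier and label depends on it, and
`ddm_simulate_trials()` returns both the label and the signed barrier.

## Tunable parameters

| Parameter | Units | Default | Role |
|---|---|---|---|
| `beta0` | — | 0 (population mean) | response bias on the logit |
| `beta1` | 1/(m/s) | 22.1 | sensitivity; JND $= \ln 3/\beta_1 \approx 49.7$ mm/s |
| `sigma` | 1/$\sqrt{s}$ (evidence units) | 0.5 | diffusion rate; sets the RT peak $t_{nd} + 1/\sigma^2$ |
| `t_nd` | s | 0.9 | non-decision latency |
| `mean_speed` | m/s | 1.05 | reference speed for the Weber fraction |
| `window_strides` × `stride_duration` | s | 8 × 1.0 | response window; longer RTs are censored |
| `dt` | s | $10^{-3}$ | Euler step of the trial simulator |

Population SDs (`population_spec()`): 0.4 for $\beta_0$, 8 for $\beta_1$,
0.1 for $\sigma$, 0.7 s for $t_{nd}$ — chosen so that simulated cohorts
reproduce the between-subject spread a split-belt 2AFC study reports:
group-mean DDM estimates of about $0.5 \pm 0.1$ for $\sigma$ and
$0.9 \pm 0.7$ s for $t_{nd}$, and a JND distribution centered near 50 mm/s
(≈ 4.7% Weber fraction at 1.05 m/s) with an SD near 23 mm/s. $\beta_1$ and
$\sigma$ are truncated positive, $t_{nd}$ non-negative.

## The stimulus protocol

`protocol_spec()` encodes the block design: stimuli
$\{0, \pm25, \pm50, \pm100, \pm150, \pm200, \pm300\}$ mm/s; each block is
built from a pseudo-random 14-trial base sequence (each signed magnitude
once, two nulls) emitted four ways — base, mirrored (signs negated),
flipped (order reversed), mirrored + flipped — giving 56 trials per block
with exact sign balance: 4 of each signed magnitude and 8 nulls. Three
blocks per subject, identical stimulus order across subjects. With 39
subjects this is 6,552 trials.

The first trial of each block is flagged `first_after_break` and excluded
from analysis (participants often miss the first task after the treadmill
restarts). The design decision with no single right answer is what to do
about the lost repetition: re-appending the first stimulus at the block end
preserves per-magnitude counts among analyzed trials but makes the block 57
presentations long, which breaks the 56 × blocks × subjects accounting.
The default (`first_trial_handling = "flag"`) keeps 56-trial blocks and
accepts one missing repetition of one stimulus per block;
`"append"` restores the counts at the cost of the extra trial. Both are
tested.

## What the generator emulates — and what it does not

`generate_cohort()` draws subjects from the population model, simulates
every scheduled trial through the DDM, and censors responses slower than
the window as `choice = "none"` (kept in the table; removal is
preprocessing's job, mirroring the experimental bookkeeping). It
deliberately does **not** model: stride events or belt accelerations,
perceptual adaptation or aftereffects, within-block breaks, lapse/guessing
asymptotes, or across-trial drift variability. Under the default
parameters the 8-s window censors a few percent of trials, concentrated on
null and small stimuli — the qualitative pattern real cohorts show, though
a well-practiced cohort misses far fewer trials (fractions of a percent).
Tests that need an exact non-response count therefore plant it with
`plant_nonresponses()` rather than relying on the censoring tail. Passing
recovery tests on these synthetic cohorts demonstrates that the estimators
are correct under the generative assumptions; they cannot certify
robustness to real-data features the generator omits (sequential effects,
fatigue, RT outliers).

## Numerical choices

* **Simulator.** Euler–Maruyama with step `dt = 1e-3` s. Discrete
  monitoring alone misses within-step barrier crossings and biases
  first-passage times upward by $O(\sqrt{dt})$ — measurably (+5–7 SE at
  $10^5$ trials) against the closed forms. Each step therefore adds the
  standard Brownian-bridge crossing check (absorb with probability
  $\exp(-2 d_0 d_1 / \sigma^2 dt)$ for each barrier, $d_0, d_1$ the
  endpoint distances); with it, hit fractions and mean decision times agree
  with the closed forms within Monte-Carlo error. A hard cap of $10^6$
  steps per trial guards against non-termination.
* **$E[t_d]$ near zero drift.** $(a/r)\tanh(ra/\sigma^2)$ is evaluated as
  $(a^2/\sigma^2)\,\mathrm{tanhc}(z)$ with a fourth-order Taylor branch for
  $|z| < 10^{-4}$, making the function continuous at $r = 0$.
* **Separation.** A subject with deterministic choices has a divergent
  logistic MLE. Detection is exact (disjoint stimulus ranges of the two
  responses after an IRLS warning); the fallback is a ridge penalty
  $\lambda = 10^{-4}$ on the slope only, flagged in the fit object.
* **DDM least squares.** Bounded L-BFGS-B from 6 deterministic starts
  ($t_{nd} \in \{0, \min RT/2\}$, $\sigma \in \{0.25, 0.5, 1\}$,
  $\beta_0 = 0$, $\beta_1 = 20$), best-RSS winner polished once more with a
  tight tolerance. Bounds: $t_{nd} \in [0, \min RT]$, $\sigma > 0$,
  $\beta_1 \ge 0$. The positive-$\beta_1$ bound breaks the exact
  $\beta_1 \mapsto -\beta_1$ symmetry of the RT objective, choosing the
  solution in which accuracy improves with stimulus size; the RT
  *asymmetry* then identifies the sign of $\beta_0$. Noiseless data at the
  13 protocol stimuli are inverted to all four parameters within $10^{-3}$
  relative error. A flat RT table returns a flagged $\beta_1 = 0$ fit.
* **Confidence intervals.** Wald, 95%. The PSE interval propagates the
  $\beta_0$ CI holding $\beta_1$ at its estimate; the JND interval
  transforms the edges of the $\beta_1$ CI (hence skewed). These
  conventions are simple, fast, and exactly reproducible from the reported
  coefficients.
* **Mixed models.** Random intercept and slope are independent (diagonal
  covariance, `(1 + dv || subject)`): the data cannot usually identify the
  correlation at these trial counts, and the generator draws them
  independently. In the exogenous-factor model the habituation
  (`dv_prev`), learning (`dv:block2`, `dv:block3`) and laterality
  (`abs_dv`) terms enter as fixed effects. `dv_prev` follows the presented
  trial order (including later-excluded trials) and is 0 at block starts,
  where no predecessor exists.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
cohort <- generate_cohort(population_spec(n_subjects = 10), protocol_spec())
summary10 <- build_summary(cohort$trials)
print(summary10)

# RT-only route for one subject
flt <- filter_trials(cohort$trials)
dfit <- fit_ddm_subject(mean_rt_by_stimulus(flt, 1))
predict_psychometric(dfit, seq(-0.3, 0.3, by = 0.05))
```

## Problem sizes used by the test suite

The package's tests were sized to be informative while remaining quick:
Monte-Carlo validation of the closed forms uses $10^5$ trials per drift
condition; logistic recovery uses ~5,000 trials per subject; hierarchical
recovery uses one 39-subject cohort at the full protocol (6,552 trials);
the type-I calibration of the exogenous terms uses twenty 20-subject
cohorts; the Pearson type-I calibration uses 1,000 replicates at $n = 39$.

## Known limitations

* The chronometric fit uses mean RTs only; it ignores censoring (fitting
  plain means of responded trials introduces a small downward bias at slow
  stimuli) and discards distributional information that quantile-based DDM
  fitting would use.
* Wald intervals and p-values are asymptotic; at 4–8 repetitions per
  signed stimulus per subject, per-subject JND estimates are noisy and
  their CIs approximate.
* The generator's Gaussian population with independent components is a
  modeling convenience, not an empirical claim about real cohorts.
* No lapse-rate parameter: a subject who occasionally presses at random
  biases $\beta_1$ downward in both routes.
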