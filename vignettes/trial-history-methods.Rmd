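---
title: "Trial-history models of antisaccade performance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-history models of antisaccade performance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antiseq)
```

## The scientific question

In the antisaccade task (AST) a peripheral target demands a saccade to the
opposite hemifield; glancing toward the target is an inhibitory error.
Healthy adults err on roughly a fifth of trials and almost always correct
themselves; in Alzheimer's disease (AD) errors are far more frequent and
often remain uncorrected, with mild cognitive impairment (MCI) in between.
`antiseq` implements the *sequential* analysis of this task: whether the
probability of an error on the current trial depends on what happened on
the preceding trials — the previous trial's outcome, whether a previous
error was corrected, and the length of the run of identical outcomes — and
whether errors and correct responses share a common latency mechanism.

## The trial-history model

Let $y_{ij}$ be 1 when participant $i$'s trial $j$ matches the reference
outcome and 0 otherwise, with success probability $p_{ij}$. The model is a
Bernoulli multilevel regression with a logit link:

$$\operatorname{logit}(p_{ij}) = \beta_0 + u_i + \beta_1 x_{1,ij} +
\beta_2 x_{2,ij} + \dots, \qquad u_i \sim N(0, \sigma_u^2).$$

The fixed covariates are treatment-coded group indicators (control as
reference) plus either (a) the previous trial's three-way outcome
(correct / corrected error / uncorrected error), or (b) two run-length
counts: `n_prev_success`, the number of immediately preceding consecutive
correct trials, and `n_prev_fail`, the analogous count of consecutive
errors. Exactly one of the two counts is non-zero after a participant's
first trial and both are zero on trial 1 — the only reading under which a
run of one reduces to "the previous trial", making the run-length and
previous-outcome analyses consistent. The random intercept $u_i$ absorbs
each participant's baseline propensity, which in these cohorts is large:
the generating value used throughout is $\sigma_u = 1.374$, bigger than
any fixed effect.

**Response coding.** Published coefficient tables for this design carry a
sign ambiguity: a *positive* control intercept around 0.74 together with a
*positive* previous-success slope is only consistent with the observed
control error rate (~30%) and with error probability falling after success
runs if the linear predictor parameterises the probability of a *correct*
trial. The package therefore defaults to correct-coded responses
(`response_coding = "correct"`, and `reference_outcome = "correct"` in the
generator) and exposes a single flag to flip the coding; the likelihood is
invariant under the flip with all coefficients negated, which the test
suite asserts.

## Estimation

The marginal likelihood integrates each participant's random intercept out
of a product of Bernoulli terms. With a single scalar random effect the
integral is one-dimensional, so the package maximises it directly by
**adaptive Gauss–Hermite quadrature**: per participant, a safeguarded
(step-halved, hence monotone) Newton iteration locates the mode of the
integrand, the quadrature grid is centred there and scaled by the local
curvature, and 15 nodes (`n_quad`, convergent to < 1e-6 against 41 nodes
and against brute-force 2001-point grid integration on test data) evaluate
the integral in a numerically stabilised log-sum-exp form. The likelihood
and its analytic gradient are implemented in C++; optimisation is
L-BFGS-B over $(\beta, \sigma_u)$ with $\sigma_u \ge 0$, started at the
plain logistic-regression solution with $\sigma_u = 1$. Standard errors
come from the inverse observed information (numerically differentiated
gradient at the optimum).

Two numerical edge cases are handled explicitly. When $\hat\sigma_u$
collapses below 0.01 the model has degenerated to ordinary logistic
regression; the fit is then replaced by the exact `glm` solution and
flagged `boundary = TRUE` (the likelihood is continuous there, which the
degenerate-limit test verifies to 1e-6). And when L-BFGS-B reports an
abnormal line-search termination at what is in fact a stationary point,
convergence is judged by the gradient norm (accepted below 0.05 on the
negative log-likelihood scale, about 2e-5 relative) rather than the
optimiser's exit code.

Nested models are compared with likelihood-ratio (`deviance_test()`)
statistics against a chi-squared reference; when the comparison removes
the random intercept the null value lies on the boundary of the parameter
space and the chi-squared reference is conservative, which the function
reports. The test suite checks the null calibration of the fixed-effect
test by simulation (100 replicate null cohorts, Kolmogorov–Smirnov against
$\chi^2_2$).

Uncertainty in $\sigma_u$ is summarised by a **parametric bootstrap**
(`bootstrap_sigma_ci()`): the fitted model re-generates each participant's
outcome sequence — the run-length covariates are dynamic functions of past
responses, so sequences are re-rolled trial by trial rather than resampled
— and the 2.5/97.5 percentiles of the re-estimated $\sigma_u$ values form
the interval. The user-facing default is B = 500 replicates; the
repeated-coverage experiments in the tests use B = 99 with warm-started
refits, which the coverage test shows is adequate at those cohort sizes.

## The synthetic-data generator

No raw data accompany the analyses this package implements, so the
generator is a first-class module and defines the study conditions:

- **Cohort structure**: 95 control, 65 MCI and 42 AD participants. A
  participant completes the full 24 trials with probability 0.792;
  otherwise the length is drawn from 11–23 with probability 0.9 on
  {21, 22, 23}. The near-full mass is the one generator constant not fixed
  by the emulated cohort's two printed completion facts (79.2% full
  sequences; over 95% of participants with more than 20 trials); 0.9 makes
  the second fact hold for essentially every seed at n = 202, where a
  smaller value leaves it to chance.
- **Outcome process**: the fitted run-length model is adopted as the
  generative truth — control intercept 0.741, MCI offset −0.200, AD offset
  −0.344, +0.047 per preceding consecutive success, −0.040 per preceding
  consecutive failure, $\sigma_u = 1.374$ — so that model fitting becomes
  a parameter-recovery experiment with known answers. (The
  previous-outcome variant of the model carries its own random-intercept
  scale, 1.524, as a separate configuration.)
- **Error correction**: an error is corrected with a constant per-group
  probability — 0.828 control, 0.763 MCI, 0.717 AD, the exact prevalence
  ratios of corrected vs uncorrected previous-error conditions in the
  reconstructed contingency cells. Whether correction probability should
  itself depend on run history is unknowable from the published summaries;
  it is held constant per group.
- **Latencies**: a rise-to-threshold race caricature. Each trial's latency
  is `onset_delay + threshold / r` with rate
  $r \sim N(\mu, \sigma)$ truncated positive, using the prosaccade unit for
  errors and the antisaccade unit for correct trials
  ($\mu = 1/126$ vs $1/230$ threshold-units/ms, CV 0.25, 50 ms onset
  delay, clipped to the 80–700 ms admissible window). This puts the median
  error latency near 176 ms and the median correct latency near 280 ms — a
  ~104 ms gap, inside the 92–106 ms range the emulated cohorts show. By
  default the race is *outcome-conditional* (the logit model draws the
  outcome, the race only supplies a latency), so the logit coefficients
  remain exactly recoverable; an optional race mode lets the faster unit
  decide the outcome instead. Corrective saccades follow the primary after
  70 ms plus a lognormal reprogramming delay (median 60 ms), keeping them
  outside the event-merge window of the classifier.
- **Reproducibility**: every participant draws from a private RNG
  sub-stream derived from the root seed and a per-group counter, so a
  cohort is bit-identical for a given (config, seed) and group-level
  streams do not shift when another group's size changes.

**What the generator does not emulate**: blinks, pupil artefacts, drift
and calibration error in gaze traces; vertical gaze components; any
dependence of latency on group, trial index, fatigue or history; learning
or attention drift across the session; and the demographic covariates of
real cohorts. Passing tests therefore demonstrate that the estimators
recover the stated generative structure, not that real recordings are this
clean; on real data the classifier thresholds and the latency model would
deserve re-examination.

## Gaze classification choices

The event parser of the original recordings is proprietary, so the package
implements a conventional velocity-threshold detector: central-difference
point velocities, events where |v| ≥ 30 deg/s, events separated by less
than 20 ms merged, and onsets refined backwards to where velocity falls
below a third of the threshold (limited to two samples, requiring a
monotone decrease so position noise cannot walk the onset away). On
noise-free synthetic traces this recovers outcome labels on ≥ 99% of
trials and latencies within ±4 ms (two samples at 500 Hz).

Spike filtering removes frames whose velocity exceeds 1,500 deg/s or whose
acceleration exceeds 100,000 deg/s². A literal per-frame central
difference cannot remove "exactly the spiked frame": at an isolated spike
the central-difference velocity of the spike frame itself is near zero
while its neighbours' explodes. The filter therefore scores each frame by
a two-sided statistic (the smaller of the backward and forward point
velocities, which is large only for the spike itself) plus a
second-difference acceleration criterion guarded to the locally dominant
frame, and removes the single worst frame per pass, recomputing
differences over the surviving timestamps. Constructed fixtures with k
injected spikes lose exactly k frames.

A trial is excluded when any saccade begins before 80 ms (anticipatory) or
none begins by 700 ms (delayed). An error counts as corrected only when a
later saccade carries gaze across the midline into the opposite hemifield;
a direction-reversal-only rule is available as a configuration option for
recordings where gaze rarely crosses fully.

## Sequence statistics conventions

Excluded trials are dropped *before* pairing, each participant's first
usable trial conditions nothing, and the current-trial outcome is always
binarised (corrected and uncorrected errors both count as errors on the
current side) while the previous-trial condition keeps all three classes.
Run-length bins are {1, 2, 3, 4, 5, 6+}. Log-odds ratios use natural
logarithms with SE $\sqrt{1/a + 1/b + 1/c + 1/d}$; zero cells fall back to
the Haldane–Anscombe +0.5 correction with a warning. The one-sample Wald
test against chance evaluates the variance at the *observed* proportion —
the variant that reproduces the published Z family (−5.87, −7.15, 2.23);
the null-variance variant is available but is not the published
convention. No multiplicity adjustment is applied, matching
per-comparison reporting. `reconstruct_total()` inverts printed
(count, proportion) pairs; the inversion is provably non-unique once the
total grows past roughly a thousand at three printed digits, so the
function verifies the printed proportion is reproduced and warns when it
cannot be.

## Reaction-time survival

Kaplan–Meier curves treat each trial's first saccade as the event, so
$S(t)$ is the fraction of trials still without a response at $t$; trials
are the unit of analysis (participant-level curves would need the raw
data's within-participant ordering, and a flag documents the choice). All
latencies inside the 80–700 ms window are observed events, so censoring is
structurally absent, though the estimator accepts censor flags. The median
is the smallest event time with $S(t) \le 0.5$ — note `survival::survfit`
averages the two central times when $S$ hits 0.5 exactly, so the package
derives the median from the curve itself — with a log–log
(Brookmeyer–Crowley-style) confidence interval, the published tables' CI
method being unstated. The log-latency comparison uses Welch's t with
Satterthwaite degrees of freedom; Cohen's d uses the pooled-SD formula
(documented as possibly not the published variant, whose formula is
unstated) and the variance explained is the identity
$r^2 = t^2/(t^2 + \mathrm{df})$.

## Problem sizes in the tests

The test suite runs every stochastic check at a scale chosen to make the
assertions sharp yet routine on a laptop: parameter recovery uses 50
replicate cohorts of the full 202 × 24 design with B = 99 bootstrap
replicates per cohort; bootstrap coverage uses 25 replicate 50-participant
cohorts, also at B = 99; the null-calibration of the deviance test uses 100
replicate 30-participant cohorts; distribution-level latency checks use
10,000 draws. The acceptance script's recovery experiment re-runs the 50
replicate full-size cohorts.

## Known limitations

- The between-group SE column of the published previous-outcome table
  (e.g. 0.259, 0.286, 0.091, 0.112) is not reproducible from the
  reciprocal-cell-count formula (which gives ≈ 0.247 for the first); its
  provenance is unknown and the package reproduces only the point
  estimates. Likewise the published Cramér's V normalisation and the
  Cohen's d variant are unstated; the package documents the standard
  definitions it uses.
- The published median latencies themselves are not reproducible without
  the raw recordings; they calibrate the generator and are asserted only
  as patterns (error < correct; gap size).
- One Gaussian random intercept per participant is the only random term;
  crossed or nested designs and a Gaussian multilevel model for log
  latency are out of scope.
- `fit_glmm()` requires participants' rows to be contiguous after
  sorting by id, which the pipeline guarantees; it treats each
  participant's trials as conditionally independent given $u_i$ and the
  history covariates.
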