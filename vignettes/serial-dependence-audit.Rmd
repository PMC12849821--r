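---
title: "Auditing n-back serial-dependence analyses for response autocorrelation"
author: "serialdep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing n-back serial-dependence analyses for response autocorrelation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In continuous reproduction tasks (for instance, orientation
reproduction), the error on the current trial is attracted toward
recently seen stimuli and recently given responses — *serial
dependence*. The standard way to quantify it is the *n-back analysis*:
regress the current error `e[n]` on the difference between a past
stimulus (or response) and the current stimulus, using the
derivative-of-Gaussian (DoG) tuning curve

    dog(x; a, w) = x * a * w * c * exp(-(w x)^2),

where `x` is the signed difference in degrees, `a` is the amplitude
(the height of the curve's peak, in degrees), `w` is the inverse width
(per degree), and `c` is a normalization constant. With
`c = sqrt(2e)` (the package default, `dog_norm_const()`), the maximum
of the curve over `x` equals `a` exactly — the property that makes the
amplitude directly interpretable as the height of the curve's peak and
valley. `c` remains an explicit field of `dog_params()` so that other
normalization conventions can be evaluated.

The audit this package implements addresses a subtle pitfall of the
n-back analysis. Responses, unlike stimuli, are serially dependent
*on themselves*: if the current response is attracted toward the
previous response, a perturbation propagates across many trials. A
regression of the current error on the *2-back stimulus* can then
detect a real — but mechanistically trivial — association that exists
only because the 2-back stimulus shaped the 1-back response, which in
turn shaped the current response. The package quantifies how often
this happens, implements a correction, and re-runs the full analysis
pipeline used for empirical cohorts.

## Generative systems and impulse responses

Three recursions are implemented in `simulate_series()`:

* stimulus feedback (`delta_s`): `y[n] = dog(x[n-1] - x[n]) + x[n] + eps`
* response feedback (`delta_r`): `y[n] = dog(y[n-1] - x[n]) + x[n] + eps`
* both plus a genuine 2-back stimulus term (`delta_rs`).

Stimuli are uniform on `[0, 180)` degrees; the trial noise is Gaussian
with sd 1 (both configurable); a simulated run is 1000 trials; the
first trial of a run has no serial term (undefined lagged terms
contribute zero). `impulse_response()` drives the noise-free recursion
with a unit one-sample input and zero pre-history: the stimulus-feedback
system returns to zero after one step, while the response-feedback
system decays geometrically with rate `dog'(0) = a w c`, which is the
mechanism that generates spurious n-back associations. When
`a w c > 1` the feedback overshoots and the impulse response
alternates in sign; on the audit grid this happens only in the most
extreme corner, and the package places no positivity assumption on the
tail.

A consequence worth noting, verified in the test suite: under raw
(unwrapped) differences the lag-1 autocorrelation of the errors of a
response-feedback run is *negative* — the DoG slope averaged over the
±180° difference distribution is negative — while its magnitude decays
slowly across lags. The slow decay, not the sign, is what matters for
the audit.

The recursions use raw arithmetic differences by default, matching the
generative equations literally; `wrap_differences = TRUE` wraps every
difference into `(-90, 90]` and is the default only in the empirical
pipeline, where orientation is genuinely circular.

## The n-back fit and its significance rule

`fit_dog()` estimates `(a, w)` by nonlinear least squares with `a`
free and `w` constrained to `[0, 1]`. Implementation choices here are
part of the method's operating characteristics — the spurious-significance
probabilities the audit measures depend on them — so each is fixed and
documented:

* **Local optimization.** The optimizer is the damped Gauss-Newton
  method of `stats::nls()`, started at `(a, w) = (1, 0.05)`. The
  profiled sum of squares is multimodal in `w` under noise; a global
  search over widths acts as an implicit multiple comparison (pick the
  width with the most spurious correlation) and roughly doubles the
  null significance rate. A local fit from a fixed start is what
  standard fitting tools do, and it keeps the significance rule's
  operating characteristics close to nominal.
* **Failures are informative.** Fits that end with a singular
  gradient, step-size collapse, or the iteration limit are returned
  with `converged = FALSE` (estimates at the start values, infinite
  amplitude CI) and counted as non-significant by the Monte-Carlo
  harness — mirroring how a standard scripted pipeline behaves when a
  fit does not converge. A `multistart` argument retries from
  `w0 in {0.01, 0.05, 0.2}`, but it is off by default: retrying until
  convergence selectively rescues exactly those datasets in which some
  width shows a stronger apparent signal, biasing the audit upward.
* **Wald t intervals.** CIs come from the Jacobian at the optimum with
  residual variance `SSE/(n - p)` and `n - p` degrees of freedom, the
  output of every standard NLS implementation.
* **Attraction-signed significance.** `is_significant()` defaults to
  requiring the amplitude CI to lie entirely *above* zero. Serial
  dependence is an attractive bias, and only attractive amplitudes
  count as (spuriously) detecting it — a repulsive amplitude is a
  different phenomenon. Counting both signs would simply double the
  null rate of the audit. `sign = "two_sided"` is available.
* `w` estimates beyond the upper bound are projected onto the bound
  and refit linearly in `a` (flagged `boundary`); a negative `w` is
  sign-canonicalized, since the curve is identical under
  `(a, w) -> (-a, -w)`. `nls`'s zero-residual failure mode is handled
  with a unit `scaleOffset`, so noiseless generative data are
  recovered exactly.

## The containment correction

`corrected_fit()` implements residualization, the analogue of partial
correlation for this setting: fit the 1-back *response* difference
onto the current error, take the residuals, and fit the n-back
*stimulus* difference onto those residuals. The stage-2 amplitude CI
is the corrected test. Trials invalid in either design are excluded
from stage 2, and the Monte-Carlo harness counts an iteration as
failed if either stage fails to converge.

## Monte-Carlo audits

`spurious_cell()` / `recovery_cell()` / `run_grid()` run the three
simulation studies: spurious-significance probability under a
1-back-only generator, the same after correction, and coverage of a
genuine 2-back amplitude under the combined generator (truth
`a = 5, w = 0.04`, coverage of the value 5 by the amplitude CI). The
default grid is `a = 0.25, 0.50, ..., 5.00` by `w = 0.01, ..., 0.10` —
amplitudes spanning sub-degree to strong biases, widths spanning broad
to narrow tuning, the ranges in which orientation-reproduction
estimates fall; both grids are user-configurable.

Seeds are derived deterministically from a master seed and the grid
coordinates, so cells are independent and any execution order gives
identical results. Estimates are binomial proportions `k / n_iter`;
at the full audit scale (`n_iter = 1000`) their standard error is at
most about 0.016.

## The empirical pipeline

`preprocess()` applies, in the stated order: per-subject degree-9
polynomial debiasing of the errors as a function of stimulus
orientation (idiosyncratic orientation biases are low-frequency, so a
9th-degree polynomial absorbs them without touching the DoG-scale
structure); flagging of trials beyond 3 sd of the subject mean plus
the immediately following trial in the same block (its 1-back
predictor is contaminated); and removal of the first 2 trials of every
block (2 is the maximum lag analyzed; the value is configurable).
Outlier statistics are computed over all of a subject's debiased
errors, which makes the rule idempotent. Trials removed by the
outlier rule are also barred from serving as lagged predictors, while
block-start trials may still serve as predictors — they are removed
only as outcomes.

`fit_dog_nlmem()` fits the cohort-level model
`e_ij = b_i + dog(delta_ij; a_i, w) + eps_ij` with per-subject
Gaussian deviations on amplitude and intercept (uncorrelated — the
generative description lists individual-level and group-error
components separately, but as written they are statistically
redundant, so the package implements a single deviation per subject
per parameter) and one shared `w`. Estimation delegates to
`nlme::nlme()` (Lindstrom-Bates first-order conditional estimation,
REML by default, `maxIter = 200`, `tolerance = 1e-4`, starting values
`a0 = 2, w = 0.05`), with `w` kept in `(0, 1)` through a logistic
reparameterization. Two deliberate deviations from the naive output:

* **Between-subject degrees of freedom for `a0`.** The amplitude has
  per-subject random loadings, so its effective sample size is the
  number of subjects. With 4-subject cohorts the amplitude variance
  component is pinned at zero in a noticeable fraction of fits, and
  the residual-df Wald interval undercovers (about 0.88-0.90 at
  nominal 0.95 in the package's own replicate studies); a t quantile
  with `n_subjects - 1` df restores nominal coverage. This makes the
  package's CIs wider — hence more conservative — than those of
  MATLAB's `nlparci`, the routine cohort analyses of this kind have
  typically relied on.
* **Robust restarts.** Non-convergent fits are retried from several
  width starts and the alternative objective before falling back to a
  pooled fixed-effects fit flagged `converged = FALSE`; one-subject
  tables reduce exactly to intercept-augmented NLS.

`two_stage_nlmem()` chains stage 1 (1-back response on errors), stage
2 (lag-N stimulus on stage-1 conditional residuals) and the reference
model (lag-N stimulus on raw errors). `permutation_test()` tests
whether the reference amplitude exceeds the corrected one: each of the
`B` permutations shuffles the error values within each subject
(sampling without replacement, balanced per subject), reconstructs
responses as `stimulus + shuffled error` so that response-derived
predictors stay consistent with `y = x + e`, reruns the full two-stage
analysis, and the p-value is the proportion of null differences
strictly exceeding the observed one (`(k+1)/(B+1)` available via
`plus_one`). Shuffling destroys the 1-back structure, so the null
distribution is exchangeable by construction; permutations with failed
fits are dropped and reported.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a small
orientation-reproduction study: by default 4 subjects, 10 blocks of 80
trials (800 per subject), group amplitude `a0 = 2` and width
`w = 0.05` with between-subject sds 0.5 (amplitude) and 0.3
(intercept), trial noise sd 5 degrees, response feedback with wrapped
differences, feedback reset at block boundaries (which is why the
pipeline trims block starts), an optional planted polynomial
orientation bias, an optional genuine 2-back stimulus term, and
optional injected outliers (additive contamination of 5-8 noise sds
with random sign, large enough that the 3-sd rule catches nearly all
of them). The defaults are in the range of published
orientation-reproduction estimates (amplitudes of a few degrees,
widths of a few hundredths per degree, a handful of participants with
several hundred trials each).

What the generator does *not* emulate: stimulus-dependent noise,
lapses, drifts in bias over the session, and response clipping. Tests
that pass on these cohorts therefore validate the estimators under the
model's own assumptions — parameter recovery, CI calibration, null
behavior of the corrected test — not robustness to real-data
violations of them.

## Problem sizes and numerical choices

The test suite runs the Monte-Carlo replication checks at
`n_iter = 200` per cell with tolerances widened to three binomial
standard errors at that size, the containment-dominance property on a
4x4 subgrid, and the mixed-model calibration on 50 replicate cohorts
of the default size; the acceptance script recomputes every audited
quantity at the full audit scale (`n_iter = 1000`, 1000 trials per
series). Degenerate inputs are handled explicitly: `w = 0` is a valid
(zero) curve for evaluation but rejected by `dog_peak()`; all-equal
predictors and undersized designs raise errors; constant outcomes
yield zero amplitudes with degenerate CIs rather than optimizer
failures.

## Limitations

The audit is a mathematical statement about the analysis, not about
mechanism: it shows that 1-back response feedback alone inflates
n-back stimulus tests and that residualization contains the inflation,
but it cannot attribute the feedback to decision inertia, working
memory, or anything else. Effects beyond 5 trials back are out of
scope. The mixed-model CI convention deliberately differs from the
residual-df intervals of standard mixed-model routines (see above); with very
few subjects the two can disagree about borderline significance calls,
which is itself a reason to prefer the calibrated convention.
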