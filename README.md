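# serialdep

Serial dependence is the attraction of the current perceptual judgment
toward recent stimuli and responses. In reproduction tasks it is
measured with the *n-back analysis*: the current error is regressed on
the difference between a past stimulus (or response) and the current
stimulus through a derivative-of-Gaussian (DoG) tuning curve

```
dog(x; a, w) = x · a · w · c · exp(−(w·x)²),        c = √(2e)
```

with amplitude `a` (degrees; the height of the curve's peak) and
inverse width `w` (1/degree). Because responses feed back on
themselves, a 1-back *response* effect decays slowly across trials and
can masquerade as a 2-back (or more remote) *stimulus* effect.
`serialdep` is a toolkit for psychophysicists who use n-back analyses
and want to know how much of a remote effect is real:

* generative simulators of trial series with stimulus feedback
  (`delta_s`), response feedback (`delta_r`), or response feedback plus
  a genuine 2-back stimulus term (`delta_rs`), and their noise-free
  impulse responses;
* DoG nonlinear least-squares n-back fits with Wald confidence
  intervals (`fit_dog`), and a residualization ("containment")
  correction that removes the 1-back response effect before testing a
  remote stimulus effect (`corrected_fit`);
* Monte-Carlo audits of the probability of spurious n-back
  significance, before and after correction, over an (a, w) grid
  (`spurious_cell`, `recovery_cell`, `run_grid`);
* an empirical pipeline for orientation-reproduction cohorts:
  preprocessing (degree-9 polynomial debiasing, 3-sd outlier removal
  with followers, block-start trimming), nonlinear mixed-effects DoG
  models with per-subject random amplitude and intercept
  (`fit_dog_nlmem`, via `nlme`), the two-stage corrected analysis
  (`two_stage_nlmem`), and a within-subject permutation test of the
  containment effect (`permutation_test`);
* a synthetic cohort generator (`generate_cohort`) emulating a small
  orientation-reproduction study, so the whole pipeline is testable
  without any external data.

## Worked example

```r
library(serialdep)

## A response-feedback system, 1000 trials, unit noise
cfg <- generator_config("delta_r", dog_params(5, 0.01), seed = 1)
s   <- simulate_series(cfg)

## Naive 2-back stimulus fit: looks "significant"
f <- fit_dog(nback_design(s, lag = 2, source = "stimulus"))
f
#> DoG nonlinear least-squares fit
#>   design: lag-2 stimulus predictor, 998 trials
#>   a = 3.3382  [1.7218, 4.9546]  (95% CI)
#>   w = 0.0036  [0.0012, 0.0059]
#>   residual sd = 3.3766 on 996 df
is_significant(f)
#> [1] TRUE

## After removing the 1-back response effect the "effect" vanishes
cf <- corrected_fit(s, lag = 2)
cf$stage2
#> DoG nonlinear least-squares fit
#>   design: lag-2 stimulus predictor, 998 trials
#>   a = -0.0359  [-0.2083, 0.1364]  (95% CI)
#>   w = 0.0512  [-0.1402, 0.2426]
#>   residual sd = 1.0350 on 996 df
is_significant(cf$stage2)
#> [1] FALSE
```

The naive fit detects an attractive 2-back amplitude of over 3
degrees with a CI excluding zero, although the generator contains no
2-back term at all — the association is carried entirely by the slowly
decaying 1-back response feedback. Residualizing the 1-back response
first (stage 2 above) brings the amplitude back to noise level.

The same logic at cohort level, on synthetic data:

```r
tab <- preprocess(generate_cohort(cohort_config(seed = 42)))
two_stage_nlmem(tab, lag = 2)
#> Two-stage corrected 2-back mixed-effects analysis
#>   reference  (raw 2-back):       a0 = 0.2426 [-0.1385, 0.6236]
#>   corrected  (residualized):      a0 = 0.2506 [-0.1062, 0.6074]
#>   stage 1    (1-back response):   a0 = 2.4319 [1.6679, 3.1959]
```

A command-line wrapper is installed at `inst/cli/serialdep`
(subcommands `impulse`, `simulate`, `audit`, `recovery`, `reanalyze`,
`genfixture`), e.g.

```sh
Rscript inst/cli/serialdep impulse --model dR --a 4.8 --w 0.03 --steps 4
#> 0.66
#> 0.22
#> 0.07
#> 0.03
```

## Notes on method choices

The fitting protocol (local Gauss-Newton from `(a, w) = (1, 0.05)`,
`w` constrained to `[0, 1]`, non-convergent fits counted
non-significant, significance = amplitude CI entirely above zero) and
the mixed-model CI convention (between-subject degrees of freedom for
the group amplitude) are documented, with their rationale, in the
methods vignette `vignettes/serial-dependence-audit.Rmd`.
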