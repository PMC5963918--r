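---
title: "Simulating and analysing duration-comparison psychophysics with durpsych"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing duration-comparison psychophysics with durpsych}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(durpsych)
```

## The scientific problem

In a two-interval forced-choice (2IFC) duration-comparison task, an observer
watches two motion sequences per trial — one showing agents interacting
communicatively, one showing the same kind of agents acting independently —
and reports which appeared longer. The signed physical duration difference
`x` (communicative minus noncommunicative, in ms) is varied over a fixed set
of levels (the method of constant stimuli), and the proportion of
"communicative judged longer" responses per level traces out a psychometric
function. Its 50% point, the **point of subjective equality (PSE)**, measures
a temporal bias: a positive PSE means the communicative sequence must be
physically *longer* to be judged equal, i.e. its subjective duration is
compressed. Half the interquartile range of the fitted function, the
**difference limen (DL)**, indexes temporal discrimination sensitivity and
should be unaffected by a pure bias shift.

durpsych packages this analysis end to end: a generative model of such
observers, the psychometric fitting stage, the group-level inferential layer
(t tests with Cohen's d, mixed-design ANOVA with Cohen's f, Pearson
correlation, median splits, bivariate bootstrap), and replication templates
for a six-experiment study design in which the PSE is linked to a social-
proficiency trait score (the Autism Spectrum Quotient, AQ) and shifted by
intranasal oxytocin or its antagonist atosiban.

## The choice model

A single observer in condition `c` is characterised by a latent PSE
`x0`, a slope parameter `omega > 0` and a lapse rate. The probability of
judging the communicative sequence longer at duration difference `x` is

$$P(\text{choose communicative}) = \frac{\lambda}{2} +
  (1-\lambda)\,F(x), \qquad
  F(x) = \frac{1}{1 + e^{-(x - x_0)/\omega}}.$$

`F` is the Boltzmann sigmoid in its *increasing* parameterisation. The same
curve is often printed with `+(x - x0)/omega` in the exponent and a negative
slope; the two forms are identical under `omega -> -omega`, and we adopt the
increasing convention with `omega > 0` so that the difference limen is
simply `omega * log(3) >= 0`. `F(x0) = 0.5` exactly, and the DL equals half
the interquartile range because `F(x0 ± omega*log 3) = 0.75 / 0.25`.

The lapse rate defaults to 0: the fitted two-parameter function has no lapse
term, and the simulator's lapse exists only for robustness checks (it mixes
the curve symmetrically toward chance, which biases fitted slopes shallow if
ignored — a known property, not a defect).

Presentation order and standard-assignment flags are recorded in every trial
but do not enter the choice model; a single curve per observer and condition
is the analysis unit, so modelling an order effect would add a parameter the
analysis never reads.

## Fitting

`fit_boltzmann()` maximises the Bernoulli likelihood of the per-level counts
(the estimator of record; least squares on proportions is available as
`method = "lsq"` for sensitivity analysis). Because `(x0, omega)` is a
reparameterisation of a binomial GLM with logit link (`x0 = -b0/b1`,
`omega = 1/b1`), the optimiser starts from the GLM solution where one
exists, plus heuristic multi-starts (x0 at the level whose proportion is
nearest 0.5, omega from the empirical 25–75% span, and a broader variant),
and polishes with box-constrained L-BFGS-B using the analytic gradient:
`x0` in ±1200 ms, `omega` in (0, 2000] ms, objective tolerance 1e-8.
Convergence is declared from the gradient at the optimum, not the
optimiser's exit code. An independent brute-force check,
`boltzmann_grid_max()`, evaluates the likelihood on a dense 1 ms grid and
shares no code with the optimiser; the test suite asserts the MLE never
falls below the grid optimum.

Degenerate data — all responses identical, a flat proportion profile, or
perfect separation pushing a parameter to its bound — are flagged
`converged = FALSE` with a warning and finite fallback estimates. Group
statistics exclude non-converged fits and report the exclusion count;
nothing is silently dropped.

## The synthetic populations

`population_spec()` + `sample_population()` generate observers with:

* an integer AQ drawn from a normal distribution truncated to a stated
  recruitment range and rounded (the trait's true distribution is not known;
  a truncated rounded normal matching the printed group mean and SD is the
  natural minimal choice);
* a latent PSE per condition,
  `intercept[c] + slope * AQ + b_i + e_ic`, with an observer-level effect
  `b_i` shared across conditions (controlling the within-observer
  correlation between, say, upright and inverted blocks) and
  condition-specific noise `e_ic`;
* a slope parameter `omega` shared across conditions (group DL comparisons
  in this design are null, so a condition-invariant omega is the appropriate
  default), drawn from a truncated normal with mean 150 ms and SD 40 ms —
  a DL near 165 ms, a realistic discrimination sensitivity for ~1 s
  motion sequences;
* optionally, a drug arm: treatment adds an observer-specific
  `N(shift_mean, shift_sd)` change to the latent PSE and leaves omega
  untouched (a pure bias mechanism).

`calibrate_aq_pse()` moment-matches the trait-to-PSE regression: given a
target correlation and total PSE SD it returns the slope and residual SD
implied by the truncated-normal trait moments (including the ~1/12 variance
of integer rounding). The package verifies the algebra by simulating 10,000
observers and checking the empirical correlation.

### Calibration of the experiment templates

`experiment_template("exp1")` … `"exp6"` encode the study conditions: sample
sizes 24, 24, 24, 90, 40+40, 40+40; generating means taken from the printed
group statistics (upright mean 69.3 ms in the first experiment, zero for
inverted and for both disrupted-interaction controls, 38.5 ms overall in the
trait experiment; baselines 13.3/9.7 ms in the high-AQ drug pair and
48.6/54.5 ms in the low-AQ pair; treatment shifts +36.9 ms under oxytocin,
−19.1/−31.1 ms under atosiban, 0 under saline).

Between-observer SDs are back-solved from the printed t statistics
(`sd = mean * sqrt(n) / t`). One refinement matters: printed statistics
describe *fitted* PSEs, which carry psychometric estimation noise on top of
true between-observer spread. The templates therefore subtract the
asymptotic estimation variance of the fitting stage (`pse_fit_se()`, ≈39 ms
under the default 20-trials-per-level design at omega = 150 ms) before
setting the latent SD, flooring the result at 10 ms where the printed
statistic leaves little or no room for latent variability (the
change-score SDs of the atosiban arms hit this floor). Without this
correction the simulated fitted-PSE SDs would be systematically larger than
the printed ones and every downstream effect size too small. Likewise, the
trait experiment preserves the printed AQ–PSE *covariance* so that the
correlation on the fitted scale — the scale on which it was reported —
reproduces the −0.40 target.

These back-solved SDs are approximations (printed SEs readable only from
figures are not used), and the controls' generating means are set to 0
because they were reported only as "not different from zero".

## The inferential layer

Effect-size conventions are fixed by reverse-engineering every printed
value: `d = t/sqrt(n)` for one-sample and paired tests,
`d = t*sqrt(1/n1 + 1/n2)` for independent tests, and
`f = sqrt(eta_p^2/(1 - eta_p^2))` from partial eta squared. All printed
effect sizes are reproduced to two decimals under these formulas (one
printed pair, t = 4.22 with d = 0.66 at n = 40, rounds to 0.67 under the
formula — a printed-rounding artifact), so they are adopted as canonical.
The independent test uses the pooled-variance statistic — the printed
degrees of freedom (e.g. 88 = 46 + 44 − 2) rule out Welch. All p-values are
two-sided and no multiplicity correction is applied, matching the original
analyses.

The mixed-design ANOVA (`mixed_anova_interaction()`) fits
`aov(value ~ between * within + Error(observer/within))` and reports the
interaction from the within-observer stratum with partial eta squared
computed as `SS_interaction / (SS_interaction + SS_error_within)`.

`median_split()` uses the convention that when the sample median is an
attained integer score, the threshold is the smallest integer strictly
above it: a median AQ of 19 yields groups "< 20" and "≥ 20".

`bootstrap_bivariate_mean()` is the standard nonparametric bootstrap over
observers: whole (pre, post) pairs are resampled with replacement 1000
times and each resample contributes its bivariate mean. Percentile
summaries can be computed from the cloud; no BCa correction is applied, as
the procedure's purpose here is the visual central-tendency cloud.

## Reproducibility and numerics

All randomness flows from one integer seed through named substreams
(`substream_seed()`): population, per-condition trials, drug assignment and
bootstrap each have their own stream, so re-running a stage in isolation
reproduces its output, and an identical `(config, seed)` pair reproduces a
report byte-for-byte (report provenance records the seed, config hash and
package version; it deliberately excludes wall-clock timestamps so that
serialized reports are reproducible).

Numerical edge cases are handled explicitly: a zero-variance sample is an
error for a t test (undefined statistic) except for the exactly-null paired
case, which returns t = 0; an ANOVA with no interaction variance returns
F = 0 rather than 0/0; `omega = 0` is rejected as a degenerate slope; and
contrasts that cannot be computed in a deliberately tiny run (too few
converged fits) are reported as skipped rather than crashing the report.

## What the simulations do and do not show

The generator reproduces the *statistical structure* the analyses assume:
binomial trial noise around a logistic curve, between-observer variability
calibrated to printed group statistics, a linear trait link, additive
treatment shifts. It does not emulate sequential effects, learning or
fatigue across blocks, order effects, non-stationary lapses, or any visual
property of the point-light stimuli. Passing tests therefore validate the
pipeline — that the estimator recovers known parameters without material
bias, that test statistics have their nominal operating characteristics,
and that the published direction/significance pattern is what this
generative model produces at the published sample sizes. They do not, and
cannot, re-establish the empirical findings themselves: the human
trial-level data are not deposited, and printed human means enter only as
generating parameters.

Replication fidelity is assessed over 200 seeded end-to-end replicates of
the four headline experiments; each headline contrast (upright bias
positive and significant; inverted null; negative trait correlation;
oxytocin increase significant; atosiban decrease — in sign where the
original effect was marginal, significant where it was strong; saline
flat) must be reproduced in at least 80% of replicates, and DL contrasts
must stay non-significant in at least 85%, mirroring the claim that
treatment moves bias, not sensitivity. Heavier validation (parameter
recovery at 1,000 observers, 10,000-sample type-I calibration, 1 ms-grid
likelihood verification on 50 observers) uses problem sizes chosen to keep
the full suite comfortably runnable on a laptop while leaving Monte-Carlo
error well inside the asserted bands.

## A worked example

```{r example, eval = FALSE}
rep1 <- run_experiment("exp1", seed = 1)
rep1
#> Experiment exp1 (orientation design), seed 1
#> Fits: 48 (0 excluded as non-converged)
#>   pse_upright_vs0     stat = 5.147  df = 23  p = 3.24e-05  effect = 1.05
#>   pse_inverted_vs0    stat = 0.441  df = 23  p = 0.663     effect = 0.09
#>   ...
```

The CLI mirrors the R surface
(`Rscript inst/cli/durpsych.R replicate --experiment exp1 --seed 1
--out-dir out/`), writing the trial CSV, fit CSV, report JSON and a
bootstrap-cloud figure where applicable.
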