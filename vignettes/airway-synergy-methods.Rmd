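---
title: "Quantifying bronchodilator synergy in isolated airways: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bronchodilator synergy in isolated airways: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaysyn)
```

`airwaysyn` implements the analysis chain used to decide whether two (or
three) bronchodilators interact synergistically in human isolated airway
preparations: concentration-response fitting, Bliss Independence expected
effects, interaction classification with subject-level replicate statistics,
and 12-hour electrical field stimulation (EFS) time-course metrics. This
vignette describes the models, their assumptions, the tunable parameters, and
the numerical and design choices behind the implementation.

## The measurement scales

Two normalizations anchor everything downstream.

**Concentration-response experiments.** Airway rings (or precision-cut lung
slices, PCLS) are submaximally precontracted (e.g. acetylcholine at its
EC~70~); relaxation is then expressed as a fraction of the maximal relaxation
produced by papaverine 100 µM at the end of the experiment. `normalize_responses()`
maps the precontraction plateau to 0 and the papaverine level to 1, linearly
in between and beyond; the mapping works for tension (decreasing on
relaxation) and luminal area (increasing) alike. Fractions slightly outside
[0, 1] are legitimate measurements (PCLS maxima above papaverine occur) and
are retained for curve fitting.

**EFS experiments.** Contraction amplitudes evoked by 10 Hz EFS trains (one
pulse every 5 min, mimicking vagal firing) are expressed relative to the
pre-treatment control EFS contraction: `normalize_efs()` returns
`100 * (1 - amplitude / reference)` percent relaxation. The transformation is
invariant to rescaling amplitudes and reference together.

Internally all effects are stored as fractions; percentages appear only in
reports and in the interaction delta, which is conventionally quoted in
percentage points.

## Concentration-response model

The variable-slope sigmoid (four-parameter logistic),

$$Y = \mathrm{Bottom} + \frac{\mathrm{Top} - \mathrm{Bottom}}
      {1 + 10^{(\log EC_{50} - X)\,\cdot\,\mathrm{HillSlope}}},$$

is fitted by bounded Levenberg-Marquardt least squares (`fit_4pl()`, via
minpack.lm). Potency is reported as pEC~50~ = -log~10~EC~50~; efficacy as the
fitted Top (E~max~). `ec_n()` inverts the fit in closed form,

$$EC_n = EC_{50}\left(\frac{f}{1-f}\right)^{1/\mathrm{HillSlope}},
\qquad f = \frac{n/100 - \mathrm{Bottom}}{\mathrm{Top} - \mathrm{Bottom}},$$

and the round trip `predict(ec_n(fit, n)) = n %` holds to 1e-9, which the
test suite checks across randomized fits.

Numerical choices:

* **Starting values** are deterministic (bottom = min response, top = max
  response, log EC~50~ = the grid point nearest the half-range response,
  Hill slope = 1), so a fit is reproducible from the data alone.
* **Bounds.** On the normalized scale, the defaults bottom ∈ [-0.05, 0.2],
  top ∈ [0.5, 1.1], Hill slope ∈ (0, 5] are physiologically generous for
  full relaxant curves while preventing the flat-curve degeneracies that
  unconstrained 4PL fits exhibit on n = 8 point grids. `constrained = FALSE`
  removes them.
* **Degenerate inputs.** Fewer than 5 distinct concentrations, or a response
  range below 2 % of the normalized maximum, is a refusal (`no_fit`), not a
  warning: a sigmoid fitted to flat data reports noise as potency.
* **Replicates.** The default analysis fits each subject separately and
  summarizes parameters as mean ± SEM across subjects
  (`fit_crc_replicates()`, `summarize_crc_fits()`), matching the n = 3
  subject-level convention of organ-bath studies; a pooled fit is available
  by simply concatenating the data.

`isoeffective_grid()` builds the combination design: at every requested
effect level each drug is dosed at its own EC~n~, so the single agents enter
the combination at equal fractional effect. Levels outside a drug's
attainable range (e.g. 95 % for a drug with E~max~ 92 %) are flagged rather
than dropped, because a silently missing design point corrupts the
level-by-level interaction profile.

## Bliss Independence and interaction classification

The Bliss Independence (BI) reference assumes the agents act through
independent mechanisms; for fractional effects,

$$E(x,y) = E_x + E_y - E_x E_y, \qquad
  E(x,y,z) = 1 - (1-E_x)(1-E_y)(1-E_z),$$

with the three-agent form implemented as the expanded sum and verified
against the complement product to 1e-12 in the tests. BI is a probabilistic
model: effects entering it are clipped to [0, 1] (fitted maxima slightly
above 1 are clipped only here, never in the fits), and the number of clipped
inputs is recorded in the output.

**Uncertainty of the expectation.** The standard organ-bath design measures each
single agent in the same subjects as the combination, so the default
(`pairing = "by_subject"`) computes the BI expectation within each subject
and summarizes across subjects; this respects within-subject correlation.
When pairing is impossible, `pairing = "delta_method"` propagates first-order
variance through the BI formula from the per-drug means and SEMs,
$\mathrm{Var}(E) \approx \sum_i \left(\prod_{j\neq i}(1-\bar E_j)\right)^2
\mathrm{SEM}_i^2$. For perfectly correlated replicates the two estimates
legitimately differ (the delta method assumes independence); for independent
noise they agree within 10 %, which a Monte-Carlo test asserts.

**Classification.** `assess_interaction()` compares observed combination
replicates with the expectation by a two-sided two-sample t-test and labels
the condition *synergistic* (delta > 0, p < α), *antagonistic* (delta < 0,
p < α) or *additive* (otherwise), with delta reported in percentage points.
The pooled-variance (Student) test is the default rather than Welch: at the
n = 3 replicate scale the Satterthwaite degrees-of-freedom estimate makes
Welch noticeably conservative (measured null significant-call rate ≈ 0.037
at α = 0.05, versus ≈ 0.05 for the pooled test under equal variances), and a
conservative test silently shortens the estimated duration of synergism.
`test = "welch"` restores the unequal-variance variant. Note that with a
two-sided test at level α, the *synergistic* false-call rate under the null
is α/2, with the other α/2 going to antagonistic calls; the calibration
tests assert exactly this split. No multiple-testing correction is applied
across effect levels or time points by default, matching field practice for
these designs; `stats::p.adjust` composes trivially with the returned
p-values if a correction is wanted.

## EFS time-course analysis

`fit_trend()` fits polynomials of degree 1-4 and selects the degree by the
small-sample-corrected Akaike criterion (AICc), choosing the smallest degree
whenever several fit exactly; the cap at degree 4 avoids Runge-type
oscillation on 145-point traces. `compute_metrics()` then derives:

* **E~max~ relaxation** - the maximum of the trend over the trace;
* **onset t~1/2~** - the earliest time the trend crosses half of E~max~,
  located by root-finding on the fitted trend. A degree ≤ 4 polynomial over
  12 h cannot represent a ~20-min rise followed by an 11-h plateau, so for
  onset estimation the package fits a *local* trend on the treatment window
  (the first 60 min, `fit_trend(..., window = c(0, 60))`) and passes it as
  `onset_trend`; the full-trace trend still supplies E~max~ and the plateau.
  With the generator's defaults this recovers the true half-maximum crossing
  within one 5-min sampling step;
* **E~max~ at plateau** - the mean of the trend over the final 3 h (a
  window parameter), after trimming any terminal segment that falls more
  than 5 % of E~max~ below the running within-window maximum, so a late
  decline does not drag the plateau estimate down.

`synergism_curve()` computes, at every time point, the per-subject BI
expectation from the single-agent traces and the observed-minus-expected
delta with its SEM and per-time t-test; a treatment-by-time two-way ANOVA
over the whole pair of curves is attached for the global comparison.
Interval areas (`auc_intervals()`) are trapezoidal integrals of the *delta*
curve in %·h. The choice of the delta curve rather than the raw relaxation
curve is deliberate: interval AUCs of ~20 %·h over the first hour arise from
a ~20-percentage-point synergism delta, and the head-to-head comparison this
feature serves is titled a comparison of the synergism, not of raw
relaxation. `auc_curve = "observed"` analyses can be had by passing the
observed column as the delta.

**Duration of synergism** (`duration_of_synergism()`) is the length of the
longest contiguous run of significantly synergistic time points (delta > 0,
p < α). When that run starts within a short onset grace (30 min by default -
the synergy needs a few sampling steps to reach significance), the duration
is reported as elapsed time from treatment to the run's last point, i.e.
"synergism for X h after treatment"; otherwise the run's own span is
reported. A single non-significant point flanked by significant neighbours
does not break a run (`gap_tolerance = 1`): with 5-min sampling and n = 3,
single-point dropouts at p ≈ 0.05-0.1 are expected even under sustained
synergy. Both conventions are switchable.

`compare_combinations()` performs the head-to-head comparison of two
combinations: per-metric t-tests on subject replicates and a
combination-by-interval two-way ANOVA across the AUC metrics;
`compare_synergism_summary()` performs the same arithmetic on printed
summary values for worked examples.

## The synthetic-data generator

The generator exists so that every downstream stage has a testable ground
truth; it is phenomenological, not biophysical (no receptor kinetics, no
cAMP dynamics). Its defaults are fixed once to the study conditions the
analysis assumes:

| Parameter | Default | Meaning |
|---|---|---|
| `n_subjects` | 3 | subject replicates (organ-bath convention) |
| `noise_sd` | 0.05 | Gaussian SD on the fraction-of-maximum scale; with n = 3 this yields SEM values of ~3 percentage points, the scale reported for such data |
| truths | pEC50 8.44 / 7.39, E~max~ 0.9968 / 0.9228, Hill 1 | published potency/efficacy estimates for glycopyrronium and indacaterol in human bronchi |
| `synergy_delta` | 0.30 | injected deviation from the BI surface |
| `synergy_window` | [0, 540] min | a 9-h synergistic period after treatment |
| `efs_grid` | 0-720 by 5 min | 12-h trace at the EFS cadence |
| `wash_time` | 60 min | treatment phase before washout |
| `onset_half_time` | 18.3 min | half-time of drug-effect and synergy onset (published onset estimate for the combination; the generator needs *a* functional form, and a saturating exponential gives the t~1/2~ estimator a known truth) |
| `decay_half_time` | 2 min | synergy offset after the window; deliberately fast so the window edge is the ground truth the duration estimator should find |
| `subject_sd` | 0 | optional shared per-subject offset (within-subject correlation is not reported for such data, so it is exposed as a parameter rather than asserted) |

Noise is additive Gaussian on the normalized scale, truncated to
[-0.05, 1.10] - the band real normalized data occupy; synergy is injected
additively on the effect scale and clipped to [0, 1], the same convention in
which deltas are reported. Single-agent EFS traces rise to the design effect
(EC~20~ ⇒ 0.2) and hold it, as long-acting bronchodilators do over 12 h; the
washout at 60 min is recorded as metadata but does not interrupt the
response. The time control fluctuates around zero relaxation.

What the generator does *not* emulate - slow receptor rebinding,
time-varying noise, inter-subject potency heterogeneity (unless `subject_sd`
is set), correlated drifts of the organ bath - bounds what passing tests
show: they validate the estimators under the stated statistical structure,
not the biology of any particular tissue.

## Problem sizes and calibration evidence

The test suite validates the pipeline at the following scales, chosen to
pin each property tightly while keeping a default run fast: 10^5 random
tuples for the BI algebraic equivalence (1e-12), 10^3 random fits for the
EC~n~ round trip (1e-9), 200 simulated experiments per drug for pEC~50~
recovery (bias < 0.05 log units at noise 0.05, n = 3), 1000 null simulations
for classifier calibration (false-interaction rate within the binomial 95 %
CI of α), 200 simulations for recovery of an injected 0.30 delta, and 30
seeds for the duration estimator (9 h ± one 5-min grid step in ≥ 90 % of
seeds). `scripts/acceptance.R` recomputes the headline quantities from
scratch at the same scales.

## Known limitations

* The 4PL fit reports asymptotic standard errors from the least-squares
  Hessian; at boundary-constrained optima these can be unreliable (returned
  as NA when the curvature matrix is singular).
* The polynomial trend is a smoother, not a mechanistic model; E~max~ from
  the full-trace trend can overshoot the data near a sharp onset, which is
  why the onset t~1/2~ uses the local trend.
* BI is the only reference model implemented (no Loewe additivity, HSA or
  ZIP); the isoeffective design makes BI the natural reference, and the
  classification logic is deliberately model-agnostic should another
  expectation be supplied to `assess_interaction()`.
* Duration is resolved at grid resolution; sub-grid duration estimates
  (e.g. "9:00 ± 0:11 h") require interpolation assumptions the package does
  not make.
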