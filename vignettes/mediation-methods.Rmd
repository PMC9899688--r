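---
title: "Natural effect decomposition for longitudinal trial mediators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Natural effect decomposition for longitudinal trial mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longmediate)
```

## The scientific question

In a randomized trial of an antihypertensive, renoprotective drug, the
urinary albumin-to-creatinine ratio (UACR) falls substantially under active
treatment. How much of that fall travels *through* the drug's effect on
blood pressure or kidney filtration, and how much is a direct effect of the
drug on albuminuria? `longmediate` answers this with regression-based causal
mediation analysis: it decomposes the intention-to-treat (total) effect on
log UACR into a natural direct effect (NDE) and a natural indirect effect
(NIE) transmitted by longitudinally measured mediators — systolic or
diastolic blood pressure, mean arterial pressure, or estimated glomerular
filtration rate (eGFR).

All analysis happens on the natural-log scale, where effects add; results
are back-transformed to geometric mean ratios to baseline (versus control),
where effects multiply: `te_ratio = nde_ratio * nie_ratio`. The proportion
mediated is defined on the additive scale,

$$\mathrm{PM} = 100 \cdot \frac{\mathrm{NIE}_{\log}}{\mathrm{TE}_{\log}}
             = 100 \cdot \frac{\ln(\text{NIE ratio})}{\ln(\text{TE ratio})},$$

which is the only reading under which published PM values are recoverable
from published ratio-scale effects.

## Mediator summaries

Mediators are measured repeatedly (every 2 weeks to week 8, every 4 weeks
after), so each patient's trajectory must be reduced to a scalar before it
can enter a regression. Two conventions are supported, encoding two
pharmacological hypotheses:

* **cumulative mean** — the average change from baseline over all observed
  post-baseline visits up to the endpoint: a cumulative-exposure
  hypothesis. The mean is unweighted over observed visits (the simplest
  reading of "average value up to the end of treatment"); a time-weighted
  trapezoid variant is available via `time_weighted = TRUE` for schedules
  whose early visits are closely spaced.
* **achieved** — the change from baseline at the latest non-missing visit
  *strictly before* the endpoint: an acute-effect hypothesis. We read
  "just before the end of treatment" as excluding the endpoint visit
  itself, because mediator and outcome share visit days and a same-day
  value invites reverse-causation ambiguity; when no earlier visit exists
  the endpoint value is used and flagged, and `at_endpoint = TRUE` switches
  to the same-visit reading throughout.

Whether the original 2-weekly early visits should enter the cumulative
average is not decidable from the outside; we average over every scheduled
visit present in the data. Both summaries are translation-equivariant and
order-invariant, and they coincide for a constant trajectory — properties
the test suite checks directly. MAP, when requested, is computed per visit
as DBP + (SBP − DBP)/3 before differencing.

## The estimator

For treatment \(A\), mediator summaries \(M_k\) and baseline covariates
\(C\) (log baseline UACR plus the baseline of every analyzed mediator —
mediator baselines are always forced into the covariate set), two model
layers are fit by ordinary least squares on the same complete-case analysis
frame:

$$Y = \theta_0 + \theta_A A + \sum_k (\theta_{Mk} M_k + \theta_{AMk} A M_k)
      + \theta_C' C + \varepsilon,\qquad
  M_k = \beta_{0k} + \beta_{Ak} A + \beta_{Ck}' C + \epsilon_k.$$

With \(\bar c\) the covariate sample mean and
\(\bar m_k(a^*) = \beta_{0k} + \beta_{Ak} a^* + \beta_{Ck}'\bar c\), the
natural effects for the contrast \(a = 1\) versus \(a^* = 0\) are the
standard counterfactual regression formulas with exposure–mediator
interaction:

$$\mathrm{NDE} = \Big[\theta_A + \sum_k \theta_{AMk}\,\bar m_k(a^*)\Big](a - a^*),
\qquad
\mathrm{NIE} = \Big[\sum_k (\theta_{Mk} + \theta_{AMk}\,a)\,\beta_{Ak}\Big](a - a^*),$$

and TE is their sum by construction. Evaluating at \(\bar c\) is not a
restriction: with linear models it equals the average of patient-level
conditional effects, so conditional and marginal reports coincide, and
centering covariates changes nothing (tested). With several mediators the
NIE is the *joint* indirect effect through all of them, which sidesteps
having to order the mediators causally (blood pressure and eGFR plausibly
affect each other); no per-mediator split is attempted for that reason.
With `interaction = FALSE` the NIE collapses to the classic product of
coefficients.

The package separately reports the marginal intention-to-treat regression
(outcome on treatment and covariates only) as a consistency check. A point
worth recording: the decomposition TE and the marginal coefficient agree to
numerical precision exactly when the outcome model has no
treatment-by-mediator interaction (any covariates), or has interactions but
no covariates; with both present they differ at the order of the arms'
finite-sample covariate imbalance (about 1e-4 on a 400-patient cohort).
The acceptance tests assert the exact identity on the fixtures where it is
an identity and the loose agreement elsewhere.

Correctness of the closed forms is checked against an independent
counterfactual simulation oracle: mediators are drawn from the fitted
mediator models under the control condition, pushed through the fitted
outcome model at both treatment levels, and averaged over one million
draws; closed-form NDE and NIE must land within three Monte-Carlo standard
errors.

## Inference

Confidence intervals use the percentile bootstrap with whole-patient
resampling, 1000 replicates by default. Arms are pooled (the plainest
bootstrap for a randomized trial); `stratify = TRUE` gives the
arm-stratified variant. Percentile intervals were chosen over BCa because
they keep the replicate bookkeeping transparent; percentiles interpolate
linearly between order statistics (`stats::quantile` type 7) so intervals
are bit-reproducible under a fixed seed. Degenerate resamples — a missing
arm or a collinear design — are redrawn, counted, and capped at ten times
the replicate count. The PM interval is taken from the replicate PM draws
themselves, not transformed from the effect intervals, so PM and effect
intervals are mutually consistent replicate by replicate.

## Scans

`longitudinal_scan()` moves the endpoint week across the UACR schedule,
rebuilding the complete-case analysis set per week (only patients with a
UACR value at that week enter, so per-week sample sizes differ) and
recomputing summaries up to / just before each week. `subgroup_scan()`
applies the identical specification within each level of a patient
attribute, with no subgroup-specific covariate selection. Per-cell
bootstrap seeds are the master seed plus the cell index, so any cell can be
reproduced in isolation. `autoplot()` draws the PM-versus-week trajectory
or the per-subgroup interval plot.

## The synthetic cohort and its calibration

No patient-level data ship with the package, so validation rests on
`generate_cohort()`: a two-arm cohort whose mediator change-from-baseline
trajectories follow a piecewise-linear ramp, `change(t) = target * min(1,
t/plateau)`, reaching a patient-specific target (treatment effect +
covariate effects + noise) at a mediator-specific plateau — week 30 for
blood pressure, week 24 for eGFR and the UACR ramp. The ramp is the
simplest one-parameter shape matching the observed "decline then stable"
pattern, and it keeps the two summary conventions genuinely different
during the ramp (cumulative mean ≠ achieved value). The structural
log-outcome change at the endpoint is
`delta*A + sum_k (gamma_k + tau_k*A)*M_k + c'C + noise`, where `M_k` is the
configured summary computed on the patient's *realized* visit schedule
(after independent per-visit dropping at `missing_rate`), so the structural
mediator is exactly the quantity the estimator reconstructs and
`true_effects()` is exact rather than approximate. Interim UACR values are
the endpoint log-change scaled along the UACR ramp — a construction that
makes the true PM constant across endpoint weeks, which the scan tests
exploit.

Defaults are calibration choices, not measurements: 449 patients, 1:1
allocation, baseline UACR log-normal around 120 mg/g, SBP 141 ± 12 mmHg,
eGFR 68 ± 14 mL/min/1.73 m²; treatment lowers SBP by 5 mmHg and eGFR by 4
mL/min/1.73 m² at plateau; `gamma_sbp = 0.028`, `gamma_egfr = 0.080` per
unit, `delta = −0.630`, outcome noise SD 0.7 on the log scale, 2% per-visit
missingness. These place the default total effect near a geometric ratio of
0.385 with single-mediator mediated fractions near 10% (SBP) and 24%
(eGFR) — the neighbourhood reported for trials of this kind — so that
recovery tests operate at a realistic signal-to-noise ratio. They were
fixed once, before validation, and are documented here as the package's own
study conditions.

What the generator does *not* emulate: informative or monotone dropout
(missingness is independent per visit), skewed or truncated baseline
distributions, nonlinear mediator–outcome relations, correlated mediator
noise (mediator targets are conditionally independent given covariates, so
the joint NIE equals the sum of single NIEs — in real data correlated
mediators make it smaller), and any mediator–outcome confounding. Passing
the recovery and coverage tests therefore certifies the estimator under
its own assumptions; it cannot certify those assumptions in real data,
where the usual no-unmeasured-confounding conditions remain untestable.

## Numerical choices and degenerate inputs

Least squares goes through pivoted QR with an explicit rank contract:
collinear designs name the offending columns instead of silently aliasing.
Nonpositive UACR (log undefined), duplicated visits, arms varying within
patient and non-finite measurements are rejected at read time; missing
cells are never coerced to zero. A zero total effect makes PM undefined and
is returned as a flagged missing value. Complete-case filtering per
endpoint (no imputation) mirrors per-timepoint inclusion; units are
documented, never converted.

## Validation problem sizes

The shipped checks use: the counterfactual oracle at n = 400 with 10^6
draws; parameter recovery over 200 generator replicates at n = 449 (mean
bias of NDE, NIE and PM within two Monte-Carlo standard errors of zero);
bootstrap coverage over 200 replicates at B = 400 (empirical 95% coverage
for the NIE required within 90–99%); and null-path limits (no mediator path
gives PM ≈ 0 to fit precision; no direct path drives PM to 100 at n =
5000). These sizes give stable Monte-Carlo error while keeping a full run
of the suite to a few minutes.

## Known limitations

Single continuous log-scale outcome only; at most four mediators; no
path-specific effects under mediator–mediator causation; no sensitivity
analysis for identification-assumption violations; no analytic standard
errors (bootstrap only); no multiplicity adjustment across scan cells.
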