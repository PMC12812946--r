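---
title: "Methods: a partitioned survival cost-utility model for first-line PIK3CA-mutated advanced breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a partitioned survival cost-utility model for first-line PIK3CA-mutated advanced breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

`psmcea` implements a three-state partitioned survival model (PSM) for the
cost-utility comparison of inavolisib + palbociclib + fulvestrant versus
palbociclib + fulvestrant in PIK3CA-mutated HR+/HER2− advanced breast
cancer, from the Chinese healthcare perspective. This vignette is the
package's account of the science: the model, its assumptions, the tunable
parameters, the synthetic-trial generator that stands in for digitized
trial curves, the numerical choices, and the limits of what the tests can
show.

## The model

Patients occupy one of three mutually exclusive states — progression-free
(PFS), progressed disease (PD), dead — with a unidirectional pathway
PFS → PD → death. A PSM derives state occupancy directly from two
marginal survival curves rather than from transition rates. At each cycle
boundary $t$:

$$
\pi_{\text{PFS}}(t) = \min\{S_{\text{PFS}}(t),\,S_{\text{OS}}(t)\},\qquad
\pi_{\text{dead}}(t) = 1 - S_{\text{OS}}(t),\qquad
\pi_{\text{PD}}(t) = S_{\text{OS}}(t) - \pi_{\text{PFS}}(t).
$$

The clamp in $\pi_{\text{PFS}}$ handles fitted-curve crossings without
renormalisation, so the death fraction always equals $1 - S_{\text{OS}}$
exactly. Cycles are 28 days (the treatment schedule); the simulation runs
until 99% of the cohort has died, capped at 40 years (the cap is flagged
on the trace if hit; with the default inputs the 99% rule fires first,
after roughly 110 cycles). Occupancy used for accrual is the half-cycle
average of boundary values; costs and QALYs are discounted at 5%/year,
evaluated continuously at cycle midpoints with a 365.25-day year. The
midpoint-versus-cycle-start choice is not stated in most published models;
midpoint is the consistent partner of the half-cycle correction, and the
difference is below 0.1% of totals.

Discounted accrual for an arm with per-cycle state costs $C_s$ and
utilities $u_s$:

$$
\text{Cost} = \sum_c \delta_c\left(\bar\pi_{\text{PFS},c} C_{\text{PFS}} +
  \bar\pi_{\text{PD},c} C_{\text{PD}}\right) + \text{AE}_\$,\qquad
\text{QALY} = \sum_c \delta_c\left(\bar\pi_{\text{PFS},c} u_{\text{PFS}} +
  \bar\pi_{\text{PD},c} u_{\text{PD}}\right)\Delta t_c - \text{AE}_u,
$$

with $\delta_c = (1+r)^{-t_c^{\text{mid}}}$. Incremental results are
$\Delta C$, $\Delta E$, ICER $= \Delta C / \Delta E$ and net monetary
benefit $\text{NMB} = \lambda\,\Delta E - \Delta C$ at willingness-to-pay
$\lambda$ = \$40,271/QALY (three times per-capita GDP).

## Survival inputs: reconstruction and extrapolation

When only published Kaplan–Meier figures are available, the package
consumes digitized curve coordinates plus numbers-at-risk tables and
reconstructs pseudo individual patient data with the Guyot interval
algorithm (`reconstruct_ipd()`): within each inter-risk-time interval the
censoring count is solved iteratively so the implied number at risk
matches the table, censoring times are spread uniformly, and event counts
are recovered from the KM drops. The procedure uses no random numbers and
is exact when there is no within-interval censoring. Two documented
degradations: without a risk table, censoring is assumed administrative at
the curve end; in the final interval (beyond the last risk-table anchor)
the censoring rate of earlier intervals is carried forward, capped so that
the remaining KM drops stay feasible.

Reconstructed data are fitted with Royston–Parmar (RP) flexible parametric
models on the proportional-hazards scale:
$\ln H(t) = \gamma^\top b(\ln t)$, where $b$ is a restricted cubic spline
basis with 0–3 interior knots at equally spaced centiles of the uncensored
log event times and boundary knots at the extreme event times. The scale
choice is the RP default; it also makes the zero-knot model *exactly* a
Weibull, which gives the test suite an independent maximum-likelihood
oracle (`survival::survreg`). Candidates are compared by AIC and BIC and
the winner extrapolates the trace; BIC uses the number of events as its
sample size (the survival-model convention — documented here because it
changes the penalty). Knot counts are selected from the data at run time;
no published per-endpoint knot choice is assumed.

Numerical choices in the fitter: multi-start BFGS from five perturbed
Weibull-based initialisations, convergence tolerance 1e-12 on the
objective; monotonicity of $\ln H$ in $\ln t$ is encouraged by a soft
quadratic penalty on a 1000-point grid out to the 40-year horizon and
verified after fitting (a non-monotone winner is an error, not a silent
repair). Ties in model selection break toward fewer parameters, then lower
BIC.

## The synthetic trial generator

The digitized coordinates of the source trial are not redistributable, so
the package ships a calibrated generator (`default_design()`,
`generate_ipd()`, `km_curve()`) that emulates its published summaries: PFS
medians 15.0 vs 7.3 months with hazard ratio 0.43, OS medians 34 vs 27
months with hazard ratio 0.67. A common-shape Weibull pair is the unique
two-parameter family satisfying both medians and a constant hazard ratio
simultaneously: $k = \ln(\text{HR}) / \ln(m_{\text{ctl}}/m_{\text{trt}})$
and $\lambda = m / (\ln 2)^{1/k}$ per arm, giving $k \approx 1.172$ for
PFS and $k \approx 1.737$ for OS.

Fixed conditions, chosen once:

* **Arm size** defaults to 162/arm (a plausible phase-III scale under the
  trial's 1:1 randomization; per-arm counts are not part of the published
  summaries). Precision-hungry checks use 2000–5000/arm.
* **Administrative censoring** at 21.4 months for PFS (midpoint of the
  arms' reported median follow-ups) and 34.2 months for OS (the extended
  follow-up at which OS was reported — a 34-month median is unobservable
  under 21.4-month censoring). No dropout process: the source reports
  none.
* **Independence of endpoints**: PFS and OS are generated as separate
  endpoint-level datasets because a PSM consumes only marginal curves;
  patient-level PFS ≤ OS coupling is not enforced, and the engine's clamp
  handles any fitted-curve crossing.

What the generator does *not* emulate: covariates and subgroups,
non-proportional hazards, dropout, digitization error beyond click
discreteness. Tests passing on synthetic data therefore demonstrate the
pipeline's internal correctness (calibration recovered, reconstruction
faithful, estimators consistent), not agreement with the unpublished
patient-level trial data.

One estimator convention worth knowing: with OS censored at 34.2 months
and a true median of 34, the KM curve ends within sampling noise of 0.5,
so in a minority of realisations the median is formally "not reached".
`km_median(..., not_reached = "limit")` then reports the follow-up limit,
the usual trial-report lower bound — and, because the curve sits at ≈0.5
there, a reasonable point estimate as well.

## Economic inputs

All costs are USD per 28-day cycle (converted at 7.1329 CNY/USD; the rate
is metadata). Progression-free patients accrue their regimen's drug costs
(combination: inavolisib \$4,065.70 + palbociclib \$419.60 + fulvestrant
\$646.59; control: the latter two) plus non-drug items (laboratory
\$59.89, radiological \$152.95, hospitalization/daily care \$90.71,
supportive care \$140.20, follow-up \$11.64). Progressed patients in both
arms receive everolimus (\$459.28) plus the same non-drug items — the
non-drug mapping to both alive states is a symmetric default, since the
published input table gives no state assignment. Utilities: PFS 0.837, PD
0.443. Drugs are costed for the entire PFS occupancy (treat-to-
progression); time-on-treatment is not modelled separately.

Grade ≥3 adverse events with ≥5% incidence carry one-off costs and
disutilities at model entry, incidence-weighted, with a one-cycle default
duration for the QALY loss; a per-cycle mode exists because "cost per
cycle" labelling of AE inputs is ambiguous. **The AE incidences shipped in
`economic_inputs()` are synthetic placeholders** — the source prints AE
costs and disutilities but not incidences — and are documented as such;
their influence is a few tens of dollars against six-figure drug totals,
which the tornado analysis makes visible. Diarrhea appears among the AE
cost/disutility rows with zero default incidence in both arms.

## Uncertainty and scenarios

One-way DSA varies each parameter over its published range (±20% for most;
discount rate 0–8%) and orders tornado bars by ICER spread; bars whose
incremental QALY changes sign within the range are flagged and excluded
from the ordering. PSA samples costs from gamma and
utilities/disutilities/discount from beta distributions, moment-matched
with $\sigma = (\text{high}-\text{low})/(2\times 1.96)$ — ranges read as
95% intervals, the common convention when no dispersion is published. The
discount rate's beta is rescaled onto [0, 0.08]; the PFS utility's upper
range (1.004) is sampled on [0,1] with clamping. Survival-curve
uncertainty is deliberately *not* resampled: the published sensitivity
table lists only cost/utility/probability parameters, so traces stay at
their point fits. The CEAC reports, per willingness-to-pay value, the
fraction of draws with positive NMB.

Scenarios: (1) an inavolisib price sweep in 5% steps — the per-tablet
price is the cycle cost over 28 tablets (\$145.204 at baseline) and the
ICER is affine and strictly increasing in it, so the break-even price at
the threshold is found by bisection (tolerance 1e-6, unique root); (2) a
time-horizon sweep over 5/10/15/20 years and lifetime by trace
truncation; (3) substitution of US-population utilities (PFS 0.736, PD
0.630), which by construction leaves costs untouched; (4) comparison
against regional thresholds supplied as plain numbers (e.g. three times
provincial per-capita GDP).

## Problem sizes and determinism

The test suite exercises calibration and estimator-consistency checks at
2,000–10,000 patients/arm, reconstruction round trips at 300–1,000/arm,
selection-consistency sweeps at 150/arm over 50 seeds, and PSA behaviour
at 100–400 iterations; the full-scale analysis defaults (10,000 PSA
iterations, 5,000/arm calibration checks) run in seconds to minutes. All
randomness flows through explicit seeds; a single pipeline seed expands to
fixed per-stage child seeds so that enabling or disabling the PSA never
perturbs the synthetic-trial stream, and the pipeline writes every stage
seed and model-selection verdict to its log.

## Known limitations

* The headline totals depend on extrapolating a Weibull/RP fit far beyond
  follow-up; with calibrated-Weibull inputs the model reproduces the
  *direction* of published results (an ICER several-fold above the
  threshold, break-even near \$16/tablet) but not their exact magnitudes,
  which rest on spline fits to digitized curves that are not
  redistributable.
* Treat-to-progression drug costing overstates drug cost if patients stop
  before progression.
* No subgroups, no treatment switching after progression beyond a single
  everolimus regimen, no societal costs.
* AE incidences are placeholders (see above) and should be replaced with
  trial safety data for any substantive use.
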