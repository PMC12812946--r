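# psmcea

A partitioned survival cost-utility model for first-line treatment of
PIK3CA-mutated HR+/HER2− advanced breast cancer: inavolisib combined with
palbociclib and fulvestrant versus palbociclib–fulvestrant alone, from the
Chinese healthcare perspective. The package is aimed at health-economics
analysts who need a reproducible, tested pipeline from published
Kaplan–Meier figures (or a calibrated synthetic stand-in) to incremental
cost-effectiveness results with full sensitivity and scenario analysis.

## What it does

* **Synthetic trial generation** — a common-shape Weibull pair calibrated
  so both arms' medians and the constant hazard ratio match published
  trial summaries exactly (PFS 15.0 vs 7.3 months, HR 0.43; OS 34 vs 27
  months, HR 0.67), with administrative censoring and seeded, reproducible
  patient draws.
* **Pseudo-IPD reconstruction** — the Guyot interval algorithm inverts
  digitized KM coordinates plus numbers-at-risk into per-patient
  (time, event) records, deterministically.
* **Survival extrapolation** — Royston–Parmar restricted cubic splines on
  the log cumulative hazard scale (`ln H(t) = γᵀ b(ln t)`, 0–3 interior
  knots; zero knots ≡ Weibull), selected by AIC/BIC, plus standard
  parametric comparators.
* **Partitioned survival engine** — three states (PFS, PD, dead) with
  occupancy `π_PFS = min(S_PFS, S_OS)`, `π_dead = 1 − S_OS`,
  `π_PD = S_OS − π_PFS`; 28-day cycles, half-cycle correction, 5% annual
  midpoint discounting, lifetime horizon to 99% cohort death.
* **Economics** — per-cycle costs and utilities accrued over the trace,
  one-off adverse-event burden, ΔC, ΔE, ICER = ΔC/ΔE and
  NMB = λ·ΔE − ΔC at λ = $40,271/QALY.
* **Uncertainty & scenarios** — tornado-style one-way DSA over published
  ranges, probabilistic sensitivity analysis (gamma costs, beta
  utilities; 10,000 iterations by default) with CEAC, price sweep with
  break-even bisection, time-horizon sweep, alternative utilities,
  regional willingness-to-pay verdicts.

## Worked example

```r
library(psmcea)

# survival calibrated to the published medians and hazard ratios
cal_pfs <- calibrate_weibull_pair(15.0, 7.3, 0.43)  # shape 1.172
cal_os  <- calibrate_weibull_pair(34, 27, 0.67)     # shape 1.737

traces <- list(
  combination = build_trace(weibull_fit(cal_pfs$shape, cal_pfs$scale_trt),
                            weibull_fit(cal_os$shape,  cal_os$scale_trt)),
  control     = build_trace(weibull_fit(cal_pfs$shape, cal_pfs$scale_ctl),
                            weibull_fit(cal_os$shape,  cal_os$scale_ctl)))

model <- ce_model(traces, economic_inputs())
model(list())
#> Partitioned survival cost-effectiveness result
#>   combination  cost $   125835.57   QALYs   1.833
#>   control      cost $    33275.39   QALYs   1.302
#>   delta cost $92560.18, delta QALY 0.531
#>   ICER $174415.22/QALY (WTP $40271.00; NMB $-71188.82; none)

break_even_price(model, 40271)
#> [1] 16.37
```

Reading: with survival calibrated to the printed trial summaries and the
published cost/utility inputs, adding inavolisib buys 0.531 discounted
QALYs for an extra $92,560 — an ICER of ~$174,000/QALY, several times the
$40,271/QALY willingness-to-pay threshold, so the combination is not
cost-effective at the current price. Bisection puts the break-even
inavolisib price near $16.4 per tablet, an ~89% reduction from the $145.20
baseline. The absolute cost and QALY totals depend on the survival inputs
(here calibrated Weibulls rather than spline fits to digitized trial
curves), but the directional conclusions and the break-even region are
stable.

The whole pipeline can also be driven from one config:

```r
cfg <- load_config(list(seed = 1,
                        survival = list(synthetic = list(n_per_arm = 162)),
                        psa = list(enabled = TRUE, n_iter = 10000),
                        scenarios = list(price = list(enabled = TRUE))))
run_pipeline(cfg, "out/")   # curves, fits, traces, base case, tornado, PSA, scenarios
```

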