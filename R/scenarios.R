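# Scenario analyses: inavolisib price sweep with break-even search,
# time-horizon sweep, alternative utilities, and regional
# willingness-to-pay thresholds.

#' Inavolisib price-reduction sweep
#'
#' Re-computes the ICER with only the inavolisib per-cycle cost scaled by
#' `1 - reduction`. The per-tablet price is the per-cycle cost divided by
#' 28 (9 mg once daily, days 1-28 of each 28-day cycle).
#'
#' @param model A closure from [ce_model()].
#' @param reductions Fractional price reductions in `[0, 1]` (default 0
#'   to 95% in 5% steps).
#' @param base_cycle_cost Baseline inavolisib cost per cycle (USD).
#' @param tablets_per_cycle Tablets per cycle (default 28).
#' @return Data frame: `reduction`, `per_tablet_price`, `delta_cost`,
#'   `delta_qaly`, `icer`.
#' @export
price_sweep <- function(model, reductions = seq(0, 0.95, by = 0.05),
                        base_cycle_cost = 4065.70, tablets_per_cycle = 28) {
  if (any(reductions < 0 | reductions > 1))
    stop_psm("reductions must lie in [0, 1]")
  rows <- lapply(reductions, function(r) {
    res <- model(list(cost_drug_inavolisib = base_cycle_cost * (1 - r)))
    data.frame(reduction = r,
               per_tablet_price = base_cycle_cost * (1 - r) / tablets_per_cycle,
               delta_cost = res$delta_cost, delta_qaly = res$delta_qaly,
               icer = res$icer)
  })
  do.call(rbind, rows)
}

#' Break-even inavolisib price at a willingness-to-pay threshold
#'
#' Bisection on the per-tablet price for `ICER(price) = wtp`; the ICER is
#' strictly increasing in price (incremental QALYs fixed, incremental
#' cost affine in price), so the root is unique.
#'
#' @param model A closure from [ce_model()].
#' @param wtp Threshold (USD/QALY).
#' @param base_cycle_cost Baseline inavolisib cost per cycle (USD).
#' @param tablets_per_cycle Tablets per cycle (default 28).
#' @param tol Relative tolerance on `|ICER - wtp|` (default 1e-6).
#' @param max_iter Bisection iteration cap (default 200).
#' @return Break-even price per tablet (USD).
#' @export
break_even_price <- function(model, wtp, base_cycle_cost = 4065.70,
                             tablets_per_cycle = 28, tol = 1e-6,
                             max_iter = 200) {
  icer_at <- function(pt) {
    model(list(cost_drug_inavolisib = pt * tablets_per_cycle))$icer
  }
  base_pt <- base_cycle_cost / tablets_per_cycle
  icer_lo <- icer_at(0); icer_hi <- icer_at(base_pt)
  if (is.na(icer_lo) || is.na(icer_hi))
    stop_psm("ICER undefined on the bracket (delta QALY = 0?)")
  if (icer_lo >= wtp)
    stop_psm("never cost-effective: ICER at price 0 (%.2f) already exceeds wtp", icer_lo)
  if (icer_hi <= wtp)
    stop_psm("already cost-effective at the base price (ICER %.2f <= wtp)", icer_hi)
  lo <- 0; hi <- base_pt
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    ic <- icer_at(mid)
    if (abs(ic - wtp) <= tol * wtp) return(mid)
    if (ic < wtp) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Time-horizon sweep
#'
#' Re-runs the accrual with the traces truncated to each horizon; the
#' lifetime entry uses the untruncated traces.
#'
#' @param traces List with `combination` and `control` `psm_trace`s
#'   (lifetime traces).
#' @param inputs An [economic_inputs()].
#' @param horizons Numeric horizons in years; `Inf` denotes lifetime.
#' @return Data frame: `horizon_years`, per-arm cost and QALYs,
#'   incremental cost/QALY and `icer`.
#' @export
horizon_sweep <- function(traces, inputs, horizons = c(5, 10, 15, 20, Inf)) {
  if (any(horizons <= 0)) stop_psm("horizons must be positive")
  rows <- lapply(horizons, function(h) {
    trc <- if (is.finite(h)) lapply(traces, truncate_trace, horizon_years = h)
    else traces
    ce <- incremental(accrue(trc$combination, "combination", inputs),
                      accrue(trc$control, "control", inputs), inputs$wtp)
    data.frame(horizon_years = h,
               cost_combination = ce$trt$total_cost,
               qaly_combination = ce$trt$total_qaly,
               cost_control = ce$ctl$total_cost,
               qaly_control = ce$ctl$total_qaly,
               delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
               icer = ce$icer)
  })
  do.call(rbind, rows)
}

#' Alternative health-state utilities scenario
#'
#' Re-runs the model with substituted PFS/PD utilities; costs are
#' untouched by construction (utilities enter only the QALY accrual).
#'
#' @param model A closure from [ce_model()].
#' @param u_pfs,u_pd Utilities in `[0, 1]` (e.g. 0.736 / 0.630 reported
#'   for US HR+/HER2- advanced breast cancer populations).
#' @return A `ce_result`.
#' @export
utility_scenario <- function(model, u_pfs, u_pd) {
  if (any(c(u_pfs, u_pd) < 0 | c(u_pfs, u_pd) > 1))
    stop_psm("utilities must lie in [0, 1]")
  model(list(utility_pfs = u_pfs, utility_pd = u_pd))
}

#' Regional willingness-to-pay verdicts
#'
#' Compares an incremental result against region-specific thresholds
#' (e.g. three times provincial per-capita GDP, supplied as plain
#' numbers).
#'
#' @param ce A `ce_result`.
#' @param thresholds Named numeric vector: region -> USD/QALY.
#' @return Data frame: `region`, `threshold`, `nmb`, `cost_effective`.
#' @export
regional_wtp <- function(ce, thresholds) {
  if (any(thresholds <= 0)) stop_psm("thresholds must be positive")
  data.frame(region = names(thresholds),
             threshold = unname(thresholds),
             nmb = unname(thresholds * ce$delta_qaly - ce$delta_cost),
             cost_effective = unname(thresholds * ce$delta_qaly - ce$delta_cost > 0),
             row.names = NULL)
}
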