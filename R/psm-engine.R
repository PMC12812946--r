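# Partitioned survival engine: two survival curves per arm partition the
# cohort into progression-free (PFS), progressed (PD) and dead states at
# each cycle boundary. PFS occupancy comes directly from the PFS curve
# (clamped to OS where the fitted curves cross), death is 1 - OS, and PD
# is the difference. No transition rates are involved.

#' Model settings for the partitioned survival engine
#'
#' @param cycle_length_days Cycle length in days (default 28, the 4-week
#'   treatment schedule).
#' @param discount_annual Annual discount rate for costs and outcomes
#'   (default 0.05).
#' @param horizon_rule `"lifetime"` (run until 99% of the cohort has died)
#'   or `"fixed"` (run to `fixed_horizon_years`).
#' @param max_horizon_years Cap on the lifetime rule (default 40 years).
#' @param fixed_horizon_years Horizon when `horizon_rule = "fixed"`.
#' @param half_cycle Apply half-cycle correction (average of
#'   cycle-boundary occupancies for accrual; default `TRUE`).
#' @param dead_threshold Cohort death fraction that terminates the
#'   lifetime rule (default 0.99).
#' @return A `model_settings` list.
#' @export
model_settings <- function(cycle_length_days = 28, discount_annual = 0.05,
                           horizon_rule = c("lifetime", "fixed"),
                           max_horizon_years = 40, fixed_horizon_years = NULL,
                           half_cycle = TRUE, dead_threshold = 0.99) {
  horizon_rule <- match.arg(horizon_rule)
  if (cycle_length_days <= 0) stop_psm("cycle_length_days must be positive")
  if (discount_annual < 0 || discount_annual > 0.08)
    stop_psm("discount_annual must be in [0, 0.08]")
  if (max_horizon_years < 1) stop_psm("max_horizon_years must be >= 1")
  if (horizon_rule == "fixed" && is.null(fixed_horizon_years))
    stop_psm("fixed horizon_rule requires fixed_horizon_years")
  structure(list(cycle_length_days = cycle_length_days,
                 discount_annual = discount_annual,
                 horizon_rule = horizon_rule,
                 max_horizon_years = max_horizon_years,
                 fixed_horizon_years = fixed_horizon_years,
                 half_cycle = half_cycle,
                 dead_threshold = dead_threshold),
            class = "model_settings")
}

#' Discount factor at a point in time
#'
#' `(1 + rate)^(-t)` with `t` in years (365.25-day year); applied at cycle
#' midpoints in [build_trace()].
#'
#' @param t_years Time in years, non-negative.
#' @param annual_rate Annual discount rate, non-negative.
#' @return Dimensionless discount factor(s).
#' @export
discount_factor <- function(t_years, annual_rate) {
  if (any(t_years < 0)) stop_psm("t_years must be >= 0")
  if (annual_rate < 0) stop_psm("annual_rate must be >= 0")
  (1 + annual_rate)^(-t_years)
}

#' Build a discounted state-occupancy trace from two survival fits
#'
#' At each cycle boundary `t`: `pfs = min(S_PFS(t), S_OS(t))` (clamp where
#' the fitted curves cross), `dead = 1 - S_OS(t)`, `pd = S_OS(t) - pfs`.
#' Under the lifetime rule the trace ends at the first boundary where the
#' dead fraction reaches the threshold (cap: `max_horizon_years`, flagged
#' if hit). Per-cycle accrual rows carry half-cycle-averaged occupancy
#' (or start-of-cycle occupancy when `half_cycle = FALSE`) and the
#' discount factor at the cycle midpoint.
#'
#' @param pfs_fit,os_fit Survival fits (see [surv_prob()]).
#' @param settings A [model_settings()].
#' @return A `psm_trace`: `boundaries` (cycle, t_months, pfs, pd, dead),
#'   `accrual` (cycle, t_mid_years, dt_years, pfs_bar, pd_bar, df),
#'   `settings`, `horizon_capped`.
#' @export
build_trace <- function(pfs_fit, os_fit, settings = model_settings()) {
  cyc_days <- settings$cycle_length_days
  cyc_months <- days_to_months(cyc_days)
  horizon_years <- if (settings$horizon_rule == "fixed")
    settings$fixed_horizon_years else settings$max_horizon_years
  max_c <- ceiling(horizon_years * DAYS_PER_YEAR / cyc_days)
  bt_months <- (0:max_c) * cyc_months

  S_pfs <- surv_prob(pfs_fit, bt_months)
  S_os <- surv_prob(os_fit, bt_months)
  if (any(S_os < -1e-9) || any(S_os > 1 + 1e-9) ||
      any(S_pfs < -1e-9) || any(S_pfs > 1 + 1e-9))
    stop_psm("survival fit returned probabilities outside [0, 1]")
  pfs <- pmin(S_pfs, S_os)
  dead <- 1 - S_os
  pd <- S_os - pfs

  horizon_capped <- FALSE
  if (settings$horizon_rule == "lifetime") {
    hit <- which(dead >= settings$dead_threshold)
    if (length(hit) == 0) {
      n_cycles <- max_c
      horizon_capped <- TRUE
    } else n_cycles <- hit[1] - 1  # boundary index (0-based) where rule fires
    n_cycles <- max(n_cycles, 1)
  } else n_cycles <- max_c

  idx <- seq_len(n_cycles)           # cycles 1..C; boundaries 0..C
  start <- idx; end <- idx + 1       # boundary row indices into bt vectors
  pfs_bar <- if (settings$half_cycle) (pfs[start] + pfs[end]) / 2 else pfs[start]
  pd_bar <- if (settings$half_cycle) (pd[start] + pd[end]) / 2 else pd[start]
  t_mid_years <- (idx - 0.5) * cyc_days / DAYS_PER_YEAR
  dt_years <- rep(cyc_days / DAYS_PER_YEAR, n_cycles)
  df <- discount_factor(t_mid_years, settings$discount_annual)

  structure(list(
    boundaries = data.frame(cycle = 0:n_cycles,
                            t_months = bt_months[1:(n_cycles + 1)],
                            pfs = pfs[1:(n_cycles + 1)],
                            pd = pd[1:(n_cycles + 1)],
                            dead = dead[1:(n_cycles + 1)]),
    accrual = data.frame(cycle = idx, t_mid_years = t_mid_years,
                         dt_years = dt_years, pfs_bar = pfs_bar,
                         pd_bar = pd_bar, df = df),
    settings = settings, horizon_capped = horizon_capped
  ), class = "psm_trace")
}

#' Recompute a trace's discount factors under a different rate
#'
#' State occupancy is unchanged; only the midpoint discount factors are
#' refreshed. Used by sensitivity analyses that vary the discount rate.
#'
#' @param trace A `psm_trace`.
#' @param annual_rate New annual discount rate.
#' @return The trace with updated `accrual$df` and settings.
#' @export
rediscount_trace <- function(trace, annual_rate) {
  trace$accrual$df <- discount_factor(trace$accrual$t_mid_years, annual_rate)
  trace$settings$discount_annual <- annual_rate
  trace
}

#' Truncate a trace to a fixed horizon
#'
#' @param trace A `psm_trace`.
#' @param horizon_years Horizon in years; cycles whose midpoint lies
#'   beyond it are dropped.
#' @return The truncated trace.
#' @export
truncate_trace <- function(trace, horizon_years) {
  keep <- trace$accrual$cycle * trace$settings$cycle_length_days / DAYS_PER_YEAR <=
    horizon_years + 1e-12
  n <- sum(keep)
  trace$accrual <- trace$accrual[seq_len(n), , drop = FALSE]
  trace$boundaries <- trace$boundaries[seq_len(n + 1), , drop = FALSE]
  trace
}

#' Export a trace as CSV for audit
#'
#' Columns: cycle, t_months, pfs, pd, dead at boundaries merged with the
#' per-cycle discount factor.
#'
#' @param trace A `psm_trace`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  b <- trace$boundaries
  b$df <- c(NA, trace$accrual$df)
  utils::write.csv(b, path, row.names = FALSE)
  invisible(path)
}
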