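# Synthetic two-arm trial generator calibrated to published trial summaries.
#
# A common-shape Weibull pair is the generating family: it is the unique
# two-parameter family in which both arms' medians and a constant hazard
# ratio can be matched simultaneously, so a design calibrated to printed
# medians and HRs reproduces all three quantities exactly in expectation.

#' Calibrate a common-shape Weibull pair to two medians and a hazard ratio
#'
#' Under Weibull survival `S(t) = exp(-(t/scale)^shape)` with a shared shape
#' `k`, the hazard ratio of treatment vs control is constant and equals
#' `(median_ctl / median_trt)^k`. Solving for `k` gives
#' `k = log(hr) / log(median_ctl / median_trt)`, and each arm's scale follows
#' from its median: `scale = median / log(2)^(1/k)`.
#'
#' @param median_trt,median_ctl Median survival (months) per arm; positive.
#' @param hr Target constant hazard ratio (treatment vs control), in (0, 1].
#' @return A list with `shape`, `scale_trt`, `scale_ctl`.
#' @examples
#' calibrate_weibull_pair(15.0, 7.3, 0.43)
#' @export
calibrate_weibull_pair <- function(median_trt, median_ctl, hr) {
  if (median_trt <= 0 || median_ctl <= 0) stop_psm("medians must be positive")
  if (hr <= 0 || hr > 1) stop_psm("hr must be in (0, 1]")
  if (hr < 1 && median_trt < median_ctl)
    stop_psm("hr < 1 requires median_trt >= median_ctl")
  if (hr == 1) {
    if (abs(median_trt - median_ctl) > 1e-12)
      stop_psm("hr = 1 is inconsistent with distinct medians: no common shape exists")
    shape <- 1 # convention: exponential when the arms are identical
  } else {
    shape <- log(hr) / log(median_ctl / median_trt)
  }
  list(
    shape = shape,
    scale_trt = median_trt / log(2)^(1 / shape),
    scale_ctl = median_ctl / log(2)^(1 / shape)
  )
}

#' Specify one arm of a synthetic trial
#'
#' @param name Arm label.
#' @param n Number of patients (integer, at least 2).
#' @param median Median survival in months; used to derive `scale` when
#'   `scale` is not given.
#' @param shape Weibull shape.
#' @param scale Weibull scale (months); defaults to `median / log(2)^(1/shape)`
#'   so that survival at `median` is exactly 0.5.
#' @return An `arm_spec` list.
#' @export
arm_spec <- function(name, n, median, shape, scale = NULL) {
  if (n < 2) stop_psm("arm '%s': n must be >= 2", name)
  if (median <= 0 || shape <= 0) stop_psm("arm '%s': median and shape must be positive", name)
  if (is.null(scale)) scale <- median / log(2)^(1 / shape)
  structure(list(name = name, n = as.integer(n), median = median,
                 shape = shape, scale = scale),
            class = "arm_spec")
}

#' Design a two-arm synthetic trial for one endpoint
#'
#' Calibrates a common-shape Weibull pair to the target medians and hazard
#' ratio, then attaches arm sizes, administrative censoring and a seed.
#'
#' @param endpoint Endpoint label, e.g. `"PFS"` or `"OS"`.
#' @param median_trt,median_ctl Target medians (months).
#' @param hr Target hazard ratio (treatment vs control).
#' @param n_per_arm Patients per arm (default 162, a plausible phase-III
#'   scale under 1:1 randomization; the source trial's per-arm counts are
#'   not published alongside its summaries).
#' @param censor_time Administrative censoring time (months).
#' @param seed Integer RNG seed used by [generate_ipd()].
#' @param arm_names Labels for the treatment and control arms.
#' @return A `trial_design` list with calibrated `arm_spec`s.
#' @export
trial_design <- function(endpoint, median_trt, median_ctl, hr,
                         n_per_arm = 162, censor_time = 21.4, seed = 1L,
                         arm_names = c("combination", "control")) {
  if (censor_time <= 0) stop_psm("censor_time must be positive")
  cal <- calibrate_weibull_pair(median_trt, median_ctl, hr)
  structure(list(
    endpoint = endpoint,
    arms = list(
      trt = arm_spec(arm_names[1], n_per_arm, median_trt, cal$shape, cal$scale_trt),
      ctl = arm_spec(arm_names[2], n_per_arm, median_ctl, cal$shape, cal$scale_ctl)
    ),
    target_hr = hr, censor_time = censor_time, seed = as.integer(seed)
  ), class = "trial_design")
}

#' Default designs emulating the published first-line trial summaries
#'
#' PFS: medians 15.0 vs 7.3 months, HR 0.43, administrative censoring at
#' 21.4 months (midpoint of the arms' reported median follow-ups).
#' OS: medians 34 vs 27 months, HR 0.67, censoring at 34.2 months (the
#' extended median follow-up at which OS was reported).
#'
#' @param endpoint `"PFS"` or `"OS"`.
#' @param n_per_arm Patients per arm.
#' @param seed Integer RNG seed.
#' @return A `trial_design`.
#' @export
default_design <- function(endpoint = c("PFS", "OS"), n_per_arm = 162, seed = 1L) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "PFS")
    trial_design("PFS", 15.0, 7.3, 0.43, n_per_arm, censor_time = 21.4, seed = seed)
  else
    trial_design("OS", 34, 27, 0.67, n_per_arm, censor_time = 34.2, seed = seed)
}

new_psm_ipd <- function(time, event, arm, endpoint) {
  structure(data.frame(time = time, event = as.integer(event),
                       arm = arm, endpoint = endpoint,
                       stringsAsFactors = FALSE),
            class = c("psm_ipd", "data.frame"))
}

#' Generate individual patient data from a trial design
#'
#' Event times are drawn from each arm's Weibull; observed time is the
#' minimum of the event time and the design's administrative censoring
#' time, with the event indicator set accordingly. Reproducible for a
#' fixed design seed (the caller's RNG stream is left untouched).
#'
#' @param design A [trial_design()].
#' @return A `psm_ipd` data frame: `time` (months), `event` (0/1), `arm`,
#'   `endpoint`, both arms stacked.
#' @export
generate_ipd <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  with_seed(design$seed, {
    pieces <- lapply(design$arms, function(a) {
      ev <- stats::rweibull(a$n, shape = a$shape, scale = a$scale)
      obs <- pmin(ev, design$censor_time)
      new_psm_ipd(obs, as.integer(ev <= design$censor_time), a$name, design$endpoint)
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    class(out) <- c("psm_ipd", "data.frame")
    out
  })
}

#' Kaplan-Meier curve coordinates and numbers at risk from patient data
#'
#' Emulates the product a graph digitizer would extract from a published
#' figure: product-limit step coordinates plus a numbers-at-risk table.
#'
#' @param ipd A `psm_ipd` (single arm/endpoint) or data frame with `time`
#'   and `event` columns.
#' @param risk_times Time grid (months) for the numbers-at-risk table;
#'   defaults to quarterly from 0 to the last observation.
#' @return A `digitized_curve` (see [digitized_curve()]).
#' @export
km_curve <- function(ipd, risk_times = NULL) {
  ipd <- as.data.frame(ipd)
  if (nrow(ipd) == 0) stop_psm("km_curve: empty input")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  if (is.null(risk_times))
    risk_times <- seq(0, max(ipd$time), by = 3)
  risk_times <- risk_times[risk_times <= max(ipd$time)]
  n_at_risk <- vapply(risk_times, function(tt) sum(ipd$time >= tt), numeric(1))
  coords <- data.frame(time = c(0, sf$time), survival = c(1, sf$surv))
  digitized_curve(coords,
                  risk_table = data.frame(time = risk_times, n_at_risk = n_at_risk),
                  n_total = nrow(ipd))
}

#' Write / read individual patient data as CSV
#'
#' Columns: `time` (months), `event` (0/1), `arm`, `endpoint`.
#' @param ipd A `psm_ipd`.
#' @param path File path.
#' @return `write_ipd_csv` returns `path` invisibly; `read_ipd_csv` a `psm_ipd`.
#' @export
write_ipd_csv <- function(ipd, path) {
  utils::write.csv(as.data.frame(ipd), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ipd_csv
#' @export
read_ipd_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "event")
  if (!all(need %in% names(df))) stop_psm("IPD CSV must have columns time, event")
  if (is.null(df$arm)) df$arm <- "arm"
  if (is.null(df$endpoint)) df$endpoint <- "endpoint"
  new_psm_ipd(df$time, df$event, df$arm, df$endpoint)
}

#' Write / read digitized Kaplan-Meier coordinates as CSV
#'
#' The curve CSV has columns `time`, `survival`; the companion risk-table
#' CSV has `time`, `n_at_risk`. This is the dialect [reconstruct_ipd()]
#' consumes.
#'
#' @param curve A `digitized_curve`.
#' @param path Curve CSV path.
#' @param risk_path Risk-table CSV path (default: `path` with
#'   `_risk.csv` suffix).
#' @return `write_curve_csv` returns `path` invisibly; `read_curve_csv` a
#'   `digitized_curve`.
#' @export
write_curve_csv <- function(curve, path, risk_path = sub("\\.csv$", "_risk.csv", path)) {
  utils::write.csv(curve$coords, path, row.names = FALSE)
  utils::write.csv(curve$risk_table, risk_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param n_total Total patients at time zero; defaults to the first
#'   risk-table entry.
#' @export
read_curve_csv <- function(path, risk_path = sub("\\.csv$", "_risk.csv", path),
                           n_total = NULL) {
  coords <- utils::read.csv(path)
  risk <- if (file.exists(risk_path)) utils::read.csv(risk_path) else NULL
  if (is.null(n_total)) {
    if (is.null(risk)) stop_psm("n_total required when no risk table is present")
    n_total <- risk$n_at_risk[1]
  }
  digitized_curve(coords, risk_table = risk, n_total = n_total)
}
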