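# Shared time-unit constants and small internal helpers.

# 365.25-day year throughout; months are "average" months.
DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 365.25 / 12
MONTHS_PER_YEAR <- 12

months_to_years <- function(m) m / MONTHS_PER_YEAR
days_to_months <- function(d) d / DAYS_PER_MONTH

#' Evaluate a Kaplan-Meier curve from individual patient data
#'
#' Product-limit survival probabilities at arbitrary times, as a
#' right-continuous step function extended beyond the last observation.
#'
#' @param ipd A `psm_ipd` object or data frame with `time` and `event`.
#' @param times Numeric vector of times (months).
#' @return Numeric vector of survival probabilities at `times`.
#' @keywords internal
km_eval <- function(ipd, times) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = as.data.frame(ipd))
  summary(sf, times = times, extend = TRUE)$surv
}

#' Kaplan-Meier median survival time
#'
#' @inheritParams km_eval
#' @param not_reached What to report when the curve never drops to 0.5
#'   within follow-up: `"NA"` (default), or `"limit"` to report the last
#'   observed time as the lower-bound estimate. The latter is the usual
#'   trial-report convention for a median that is not reached, and only
#'   matters for administratively censored designs whose true median sits
#'   at the edge of follow-up (there the curve ends within sampling noise
#'   of 0.5, so the limit is itself a reasonable estimate).
#' @return Median survival in months.
#' @export
km_median <- function(ipd, not_reached = c("NA", "limit")) {
  not_reached <- match.arg(not_reached)
  ipd <- as.data.frame(ipd)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  med <- unname(stats::quantile(sf, probs = 0.5)$quantile)
  if (is.na(med) && not_reached == "limit") med <- max(ipd$time)
  med
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Tiny rolling hash of a character scalar, for audit headers (hex string).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stop_psm <- function(...) stop(sprintf(...), call. = FALSE)
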