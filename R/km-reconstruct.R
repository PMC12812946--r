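# Reconstruction of pseudo individual patient data from digitized
# Kaplan-Meier coordinates plus numbers at risk: the Guyot (2012)
# interval algorithm. Within each inter-risk-time interval, the number of
# censorings is adjusted iteratively until the implied number at risk at
# the next risk-table time matches the table; censoring times are spread
# uniformly within the interval; event counts are then read off the KM
# drops. The procedure is fully deterministic.

#' Construct a digitized Kaplan-Meier curve object
#'
#' Validates and normalises digitizer output: times are sorted,
#' duplicates keep the minimum survival per time (digitizer jitter),
#' survival is clamped to `[0, 1]` and forced non-increasing, and a
#' `(0, 1)` coordinate is inserted when absent.
#'
#' @param coords Data frame with `time` (months) and `survival`
#'   (probability) columns.
#' @param risk_table Optional data frame with `time`, `n_at_risk`; counts
#'   must be non-increasing. When absent, [reconstruct_ipd()] falls back to
#'   assuming no censoring before the last click (administrative censoring
#'   only at the curve end).
#' @param n_total Total patients at time zero.
#' @return A `digitized_curve` list: `coords`, `risk_table` (or `NULL`),
#'   `n_total`.
#' @export
digitized_curve <- function(coords, risk_table = NULL, n_total) {
  stopifnot(all(c("time", "survival") %in% names(coords)))
  if (n_total < 1) stop_psm("n_total must be >= 1")
  coords <- coords[order(coords$time, coords$survival), , drop = FALSE]
  # deduplicate: one click per time, keep the lowest survival (rows are
  # sorted ascending in survival within a time, so keep each time's first)
  coords <- coords[!duplicated(coords$time), , drop = FALSE]
  coords$survival <- pmin(pmax(coords$survival, 0), 1)
  coords$survival <- cummin(coords$survival)
  if (coords$time[1] > 0) coords <- rbind(data.frame(time = 0, survival = 1), coords)
  if (abs(coords$survival[1] - 1) > 1e-9)
    stop_psm("survival at time 0 must be 1 (got %.4f)", coords$survival[1])
  if (!is.null(risk_table)) {
    stopifnot(all(c("time", "n_at_risk") %in% names(risk_table)))
    risk_table <- risk_table[order(risk_table$time), , drop = FALSE]
    if (any(diff(risk_table$n_at_risk) > 0))
      stop_psm("risk-table counts must be non-increasing")
    if (risk_table$time[1] != 0)
      risk_table <- rbind(data.frame(time = 0, n_at_risk = n_total), risk_table)
    if (risk_table$n_at_risk[1] != n_total)
      stop_psm("n_at_risk at time 0 (%d) must equal n_total (%d)",
               risk_table$n_at_risk[1], n_total)
  }
  rownames(coords) <- NULL
  structure(list(coords = coords, risk_table = risk_table,
                 n_total = as.integer(n_total)),
            class = "digitized_curve")
}

#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' The interval algorithm: for each interval between consecutive
#' risk-table times, an initial censoring count is guessed from the KM
#' ratio across the interval, censoring times are distributed uniformly
#' within it, event counts at each click are recovered from the KM drops
#' given the implied numbers at risk, and the censoring count is adjusted
#' until the implied number at risk at the next risk time matches the
#' table. Patients still at risk after the last click are administratively
#' censored there.
#'
#' @param curve A [digitized_curve()].
#' @param arm,endpoint Labels carried into the output.
#' @return A `psm_ipd` data frame with `n_total` rows.
#' @export
reconstruct_ipd <- function(curve, arm = "arm", endpoint = "endpoint") {
  stopifnot(inherits(curve, "digitized_curve"))
  tS <- curve$coords$time
  S <- curve$coords$survival
  K <- length(tS)
  if (is.null(curve$risk_table)) {
    # fallback: no censoring before the last click
    rt <- data.frame(time = 0, n_at_risk = curve$n_total)
  } else rt <- curve$risk_table
  # drop risk times beyond the last click (no information there)
  rt <- rt[rt$time <= tS[K] + 1e-9, , drop = FALSE]
  t.risk <- rt$time
  n.risk <- rt$n_at_risk
  n.int <- length(t.risk)

  # click index ranges per risk interval i: [t.risk[i], t.risk[i+1])
  lower <- upper <- integer(n.int)
  for (i in seq_len(n.int)) {
    lo <- t.risk[i]
    hi <- if (i < n.int) t.risk[i + 1] else Inf
    idx <- which(tS >= lo - 1e-9 & tS < hi - 1e-9)
    if (i == n.int) idx <- which(tS >= lo - 1e-9)
    if (length(idx) == 0) { lower[i] <- NA; next }
    lower[i] <- min(idx); upper[i] <- max(idx)
  }
  # merge empty intervals into their predecessor by dropping the risk time
  if (anyNA(lower)) {
    keep <- !is.na(lower)
    t.risk <- t.risk[keep]; n.risk <- n.risk[keep]
    lower <- lower[keep]; upper <- upper[keep]
    n.int <- length(t.risk)
  }

  n.censor <- numeric(n.int)
  n.hat <- c(n.risk[1], numeric(K))
  cen <- d <- numeric(K)
  KM.hat <- rep(1, K)
  last.i <- rep(1, n.int + 1)
  cen.times <- vector("list", n.int)

  run_interval <- function(i, nc, last_start) {
    # distribute nc censorings uniformly over the click span of interval i
    hi_idx <- if (i < n.int) lower[i + 1] else K
    cen[lower[i]:upper[i]] <<- 0
    ct <- numeric(0)
    if (nc > 0) {
      ct <- tS[lower[i]] + seq_len(nc) * (tS[hi_idx] - tS[lower[i]]) / (nc + 1)
      if (hi_idx > lower[i]) {
        cnt <- graphics::hist(ct, breaks = tS[lower[i]:hi_idx],
                              plot = FALSE, right = FALSE)$counts
        cen[lower[i]:(hi_idx - 1)] <<- cnt
      }
    }
    n.hat[lower[i]] <<- n.risk[i]
    last <- last_start
    for (k in lower[i]:upper[i]) {
      if (k == 1) { d[k] <<- 0; KM.hat[k] <<- 1 }
      else if (n.hat[k] <= 0) { d[k] <<- 0; KM.hat[k] <<- KM.hat[last] }
      else {
        d[k] <<- round(n.hat[k] * (1 - S[k] / KM.hat[last]))
        d[k] <<- max(0, min(d[k], n.hat[k]))
        KM.hat[k] <<- KM.hat[last] * (1 - d[k] / n.hat[k])
      }
      n.hat[k + 1] <<- n.hat[k] - d[k] - cen[k]
      if (d[k] != 0) last <- k
    }
    list(ct = ct, last = last)
  }

  for (i in seq_len(n.int)) {
    if (i < n.int) {
      # initial guess from the KM ratio across the interval
      n.censor[i] <- round(n.risk[i] * S[lower[i + 1]] / S[lower[i]] - n.risk[i + 1])
      iter <- 0
      repeat {
        nc <- max(0, n.censor[i])
        res <- run_interval(i, nc, last.i[i])
        gap <- n.hat[lower[i + 1]] - n.risk[i + 1]
        if (gap == 0 || (gap < 0 && nc == 0)) break
        n.censor[i] <- nc + gap
        iter <- iter + 1
        if (iter > 1000)
          stop_psm("reconstruction infeasible in interval %d ([%.2f, %.2f) months): implied events negative or counts cannot match the risk table",
                   i, t.risk[i], if (i < n.int) t.risk[i + 1] else tS[K])
      }
      n.censor[i] <- max(0, n.censor[i])
      if (n.hat[lower[i + 1]] < n.risk[i + 1]) n.risk[i + 1] <- n.hat[lower[i + 1]]
      cen.times[[i]] <- res$ct
      last.i[i + 1] <- res$last
    } else {
      # last interval: without further risk-table anchors, assume the mean
      # censoring rate of earlier intervals (0 when there are none), but
      # never censor patients that the remaining KM drops require as events
      if (n.int > 1) {
        span_prev <- tS[upper[n.int - 1]] - tS[lower[1]]
        rate <- if (span_prev > 0) sum(n.censor[1:(n.int - 1)]) / span_prev else 0
        need_events <- if (S[lower[i]] > 0)
          ceiling(n.risk[i] * (1 - S[K] / S[lower[i]])) else 0
        n.censor[i] <- min(round(rate * (tS[K] - tS[lower[i]])),
                           max(n.risk[i] - need_events, 0))
      } else n.censor[i] <- 0
      res <- run_interval(i, max(0, n.censor[i]), last.i[i])
      cen.times[[i]] <- res$ct
    }
  }

  times <- c(rep(tS, times = d), unlist(cen.times))
  events <- c(rep(1L, sum(d)), rep(0L, length(unlist(cen.times))))
  # remaining at risk after the last click: administrative censoring there
  n_left <- curve$n_total - length(times)
  if (n_left < 0)
    stop_psm("reconstruction produced %d records for n_total = %d",
             length(times), curve$n_total)
  if (n_left > 0) {
    times <- c(times, rep(tS[K], n_left))
    events <- c(events, rep(0L, n_left))
  }
  ord <- order(times, -events)
  new_psm_ipd(times[ord], events[ord], arm, endpoint)
}

#' Check a reconstruction against its source curve
#'
#' Recomputes the Kaplan-Meier estimate from the reconstructed records and
#' reports the sup-norm deviation from the digitized coordinates, plus the
#' numbers-at-risk mismatch at each risk-table time. Read-only.
#'
#' @param curve The source [digitized_curve()].
#' @param ipd The reconstructed `psm_ipd`.
#' @param tol Deviation above which `ok` is `FALSE` (default 0.01).
#' @return A list: `max_km_deviation`, `risk_mismatch` (data frame or
#'   `NULL`), `n_records`, `ok`.
#' @export
validate_reconstruction <- function(curve, ipd, tol = 0.01) {
  s_hat <- km_eval(ipd, curve$coords$time)
  dev <- max(abs(s_hat - curve$coords$survival))
  mismatch <- NULL
  if (!is.null(curve$risk_table)) {
    nr <- vapply(curve$risk_table$time,
                 function(tt) sum(ipd$time >= tt - 1e-9), numeric(1))
    mismatch <- data.frame(time = curve$risk_table$time,
                           table = curve$risk_table$n_at_risk,
                           implied = nr,
                           diff = nr - curve$risk_table$n_at_risk)
  }
  list(max_km_deviation = dev, risk_mismatch = mismatch,
       n_records = nrow(ipd), ok = dev <= tol)
}
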