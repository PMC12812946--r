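# One-way deterministic sensitivity analysis (tornado) and probabilistic
# sensitivity analysis with cost-effectiveness acceptability curves.
#
# Survival-curve uncertainty is not resampled: the state traces are held
# at their point fits and only cost/utility/probability parameters (and
# the discount rate) vary, mirroring the published input table.

#' Build a re-evaluable cost-effectiveness model closure
#'
#' Binds fixed state traces to economic inputs and returns a function
#' `f(overrides)` that recomputes the full incremental result with named
#' parameters overridden. Override names follow the sensitivity table:
#' `cost_drug_<name>`, `cost_ae_<name>`, `cost_other_<name>`,
#' `utility_pfs`, `utility_pd`, `disutility_<name>`, `discount_rate`.
#'
#' @param traces List with `combination` and `control` `psm_trace`s.
#' @param inputs An [economic_inputs()].
#' @return A function `f(overrides = list())` returning a `ce_result`.
#' @export
ce_model <- function(traces, inputs) {
  stopifnot(all(c("combination", "control") %in% names(traces)))
  function(overrides = list()) {
    inp <- inputs
    trc <- traces
    for (nm in names(overrides)) {
      val <- overrides[[nm]]
      if (nm == "discount_rate") {
        trc <- lapply(trc, rediscount_trace, annual_rate = val)
      } else if (grepl("^cost_drug_", nm)) {
        inp$drug_cost[[sub("^cost_drug_", "", nm)]] <- val
      } else if (grepl("^cost_other_", nm)) {
        inp$other_cost[[sub("^cost_other_", "", nm)]] <- val
      } else if (grepl("^cost_ae_", nm)) {
        i <- match(sub("^cost_ae_", "", nm), inp$ae$name)
        if (is.na(i)) stop_psm("unknown AE '%s'", nm)
        inp$ae$cost[i] <- val
      } else if (grepl("^disutility_", nm)) {
        i <- match(sub("^disutility_", "", nm), inp$ae$name)
        if (is.na(i)) stop_psm("unknown AE '%s'", nm)
        inp$ae$disutility[i] <- val
      } else if (nm == "utility_pfs") {
        inp$utilities[["pfs"]] <- min(max(val, 0), 1)
      } else if (nm == "utility_pd") {
        inp$utilities[["pd"]] <- min(max(val, 0), 1)
      } else stop_psm("unknown override '%s'", nm)
    }
    incremental(accrue(trc$combination, "combination", inp),
                accrue(trc$control, "control", inp),
                inp$wtp)
  }
}

#' Deterministic sensitivity ranges for every model parameter
#'
#' One row per parameter with base/low/high (the published ranges,
#' largely +/-20% around baseline; discount rate 0-8%) and the
#' distribution family used by the PSA (gamma for costs, beta for
#' utilities, disutilities and the discount rate).
#'
#' @param inputs An [economic_inputs()].
#' @return Data frame: `param`, `base`, `low`, `high`, `dist`.
#' @export
dsa_ranges <- function(inputs) inputs$ranges

#' One-way sensitivity of the ICER to a single parameter
#'
#' @param param One row of [dsa_ranges()] (or a list with `param`, `low`,
#'   `high`).
#' @param model A closure from [ce_model()].
#' @return List: `param`, `icer_low`, `icer_high` (ICERs at the low/high
#'   parameter value), `spread`, `sign_change` (`TRUE` when the
#'   incremental QALY changes sign within the range, which invalidates
#'   the bar).
#' @export
one_way <- function(param, model) {
  lo <- model(stats::setNames(list(param$low), param$param))
  hi <- model(stats::setNames(list(param$high), param$param))
  sign_change <- sign(lo$delta_qaly) != sign(hi$delta_qaly)
  list(param = param$param, icer_low = lo$icer, icer_high = hi$icer,
       spread = abs(hi$icer - lo$icer), sign_change = sign_change)
}

#' Full tornado table
#'
#' Runs [one_way()] for every parameter and orders bars by descending
#' ICER spread; entries whose incremental QALY changes sign within the
#' range are flagged and pushed to the bottom, unordered.
#'
#' @param model A closure from [ce_model()].
#' @param ranges A [dsa_ranges()] table.
#' @return Data frame: `param`, `icer_low`, `icer_high`, `spread`,
#'   `sign_change`, sorted for tornado plotting.
#' @export
dsa_tornado <- function(model, ranges) {
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- one_way(as.list(ranges[i, ]), model)
    data.frame(param = r$param, icer_low = r$icer_low, icer_high = r$icer_high,
               spread = r$spread, sign_change = r$sign_change)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sign_change, -out$spread), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gamma hyper-parameters from a mean and a range
#'
#' Treats `[low, high]` as a 95% interval, `sd = (high - low) / (2 * 1.96)`,
#' then moment-matches: `shape = (mean/sd)^2`, `rate = mean/sd^2`.
#'
#' @param mean,low,high Mean and range of the parameter.
#' @return List: `shape`, `rate`, `sd`.
#' @export
moments_to_gamma <- function(mean, low, high) {
  if (!(low <= mean && mean <= high)) stop_psm("need low <= mean <= high")
  sd <- (high - low) / (2 * 1.96)
  if (sd == 0) return(list(shape = Inf, rate = Inf, sd = 0, degenerate = TRUE))
  list(shape = (mean / sd)^2, rate = mean / sd^2, sd = sd, degenerate = FALSE)
}

#' Beta hyper-parameters from a mean and a range
#'
#' Same sd convention as [moments_to_gamma()]; the mean is clamped into
#' (0, 1) before moment matching: `a = m (m(1-m)/sd^2 - 1)`,
#' `b = (1-m) (m(1-m)/sd^2 - 1)`.
#'
#' @inheritParams moments_to_gamma
#' @return List: `a`, `b`, `sd`.
#' @export
moments_to_beta <- function(mean, low, high) {
  if (!(low <= mean && mean <= high)) stop_psm("need low <= mean <= high")
  sd <- (high - low) / (2 * 1.96)
  if (sd == 0) return(list(a = Inf, b = Inf, sd = 0, degenerate = TRUE))
  hp <- beta_from_mean_sd(mean, sd)
  list(a = hp$a, b = hp$b, sd = sd, degenerate = FALSE)
}

beta_from_mean_sd <- function(mean, sd) {
  m <- min(max(mean, 1e-6), 1 - 1e-6)
  nu <- m * (1 - m) / sd^2 - 1
  if (nu <= 0) stop_psm("sd too large for a beta with mean %.3f", mean)
  list(a = m * nu, b = (1 - m) * nu)
}

# Sample one parameter vector (named) from the ranges table.
sample_params <- function(ranges, scale_sd = 1) {
  vals <- numeric(nrow(ranges))
  for (i in seq_len(nrow(ranges))) {
    r <- ranges[i, ]
    if (r$dist == "gamma") {
      hp <- moments_to_gamma(r$base, r$low, r$high)
      vals[i] <- if (hp$degenerate || scale_sd == 0) r$base
      else stats::rgamma(1, shape = hp$shape / scale_sd^2,
                         rate = hp$rate / scale_sd^2)
    } else {
      if (r$param == "discount_rate") {
        # beta on the rescaled published 0-8% range
        span <- r$high - r$low
        hp <- beta_from_mean_sd((r$base - r$low) / span,
                                (span / (2 * 1.96)) / span)
        vals[i] <- if (scale_sd == 0) r$base
        else r$low + span * stats::rbeta(1, hp$a, hp$b)
      } else {
        hp <- moments_to_beta(r$base, r$low, r$high)
        vals[i] <- if (hp$degenerate || scale_sd == 0) r$base
        else min(max(stats::rbeta(1, hp$a, hp$b), 0), 1)
      }
    }
  }
  stats::setNames(vals, ranges$param)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the parameter distributions: each iteration samples
#' every parameter independently (gamma for costs, beta for utilities,
#' disutilities and the rescaled discount rate), re-runs the economics
#' over the fixed traces, and records incremental cost and QALYs.
#' Reproducible by seed.
#'
#' @param model A closure from [ce_model()].
#' @param ranges A [dsa_ranges()] table.
#' @param n_iter Number of iterations (default 10000).
#' @param seed Integer seed.
#' @param scale_sd Multiplier on every parameter's sd (0 collapses the
#'   PSA onto the deterministic base case; used for convergence checks).
#' @return A `psa_result`: `draws` (data frame `delta_cost`,
#'   `delta_qaly`), `params` (matrix of sampled values), `n_iter`, `seed`.
#' @export
run_psa <- function(model, ranges, n_iter = 10000, seed = 1L, scale_sd = 1) {
  with_seed(seed, {
    pm <- matrix(NA_real_, n_iter, nrow(ranges),
                 dimnames = list(NULL, ranges$param))
    dc <- de <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      p <- sample_params(ranges, scale_sd = scale_sd)
      pm[it, ] <- p
      res <- model(as.list(p))
      dc[it] <- res$delta_cost
      de[it] <- res$delta_qaly
    }
    structure(list(draws = data.frame(delta_cost = dc, delta_qaly = de),
                   params = pm, n_iter = n_iter, seed = seed),
              class = "psa_result")
  })
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the strategy is cost-effective (positive net monetary
#' benefit) at each willingness-to-pay value.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Vector of WTP values (USD/QALY).
#' @return Data frame: `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  if (length(wtp_grid) == 0) stop_psm("empty WTP grid")
  if (nrow(psa$draws) == 0) stop_psm("PSA has no draws")
  p <- vapply(wtp_grid, function(w)
    mean(w * psa$draws$delta_qaly - psa$draws$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = p)
}
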