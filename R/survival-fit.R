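# Royston-Parmar flexible parametric survival models on the
# proportional-hazards scale: ln H(t) = gamma' b(ln t), where b is a
# restricted (natural) cubic spline basis in log time. With zero interior
# knots the model reduces exactly to a Weibull, which provides an
# independent maximum-likelihood oracle for testing. Standard parametric
# comparators (Weibull, log-normal, log-logistic) are fitted through
# survival::survreg behind the same interface.

#' Restricted cubic spline basis for Royston-Parmar models
#'
#' Basis columns are `1, x, v_1(x), ..., v_m(x)` for `m` interior knots,
#' with `v_j(x) = (x - k_j)_+^3 - l_j (x - k_min)_+^3 -
#' (1 - l_j)(x - k_max)_+^3` and `l_j = (k_max - k_j) / (k_max - k_min)`.
#' The basis is linear beyond the boundary knots (natural spline).
#'
#' @param x Numeric vector (log time).
#' @param knots Strictly increasing knot vector on the log-time scale,
#'   boundary knots first and last; length >= 2.
#' @return Matrix with `length(knots)` columns.
#' @export
rp_basis <- function(x, knots) {
  check_knots(knots)
  kmin <- knots[1]; kmax <- knots[length(knots)]
  interior <- knots[-c(1, length(knots))]
  B <- cbind(1, x)
  for (kj in interior) {
    lj <- (kmax - kj) / (kmax - kmin)
    B <- cbind(B, pmax(x - kj, 0)^3 - lj * pmax(x - kmin, 0)^3 -
                 (1 - lj) * pmax(x - kmax, 0)^3)
  }
  unname(B)
}

#' @rdname rp_basis
#' @details `rp_basis_deriv` returns the derivative of each basis column
#'   with respect to `x`.
#' @export
rp_basis_deriv <- function(x, knots) {
  check_knots(knots)
  kmin <- knots[1]; kmax <- knots[length(knots)]
  interior <- knots[-c(1, length(knots))]
  B <- cbind(0, rep(1, length(x)))
  for (kj in interior) {
    lj <- (kmax - kj) / (kmax - kmin)
    B <- cbind(B, 3 * pmax(x - kj, 0)^2 - 3 * lj * pmax(x - kmin, 0)^2 -
                 3 * (1 - lj) * pmax(x - kmax, 0)^2)
  }
  unname(B)
}

check_knots <- function(knots) {
  if (length(knots) < 2) stop_psm("need at least 2 knots (boundaries)")
  if (any(diff(knots) <= 0)) stop_psm("knots must be strictly increasing (duplicates?)")
  invisible(knots)
}

#' Fit a Royston-Parmar spline survival model
#'
#' Maximises the right-censored log-likelihood
#' `sum_i d_i (s(x_i) + log s'(x_i) - x_i) - sum_i exp(s(x_i))` with
#' `s(x) = gamma' b(x)`, `x = ln t`, by multi-start BFGS from perturbed
#' Weibull-based initial values. Interior knots sit at equally spaced
#' centiles of the uncensored log event times; boundary knots at the
#' min/max event time. Monotonicity of the log cumulative hazard in log
#' time is encouraged by a soft quadratic penalty on a 1000-point grid to
#' the extrapolation horizon and verified after fitting.
#'
#' @param ipd `psm_ipd` or data frame with `time` (months) and `event`.
#' @param n_interior Number of interior knots, 0-3.
#' @param horizon_months Extrapolation horizon used for the monotonicity
#'   grid (default 480 months = 40 years).
#' @param restarts Number of perturbed starts (default 5).
#' @return An `rp_fit`: `scale` (`"hazard"`), `knots`, `gamma`, `loglik`,
#'   `aic`, `bic` (events-based n), `n_params`, `n_events`, `n`.
#' @export
fit_rp <- function(ipd, n_interior = 0, horizon_months = 480, restarts = 5) {
  ipd <- as.data.frame(ipd)
  tt <- ipd$time; dd <- ipd$event
  if (any(tt <= 0)) stop_psm("event/censoring times must be positive")
  n_ev <- sum(dd)
  if (n_ev < 1) stop_psm("need at least one event")
  if (n_interior < 0 || n_interior > 3) stop_psm("n_interior must be 0..3")
  et <- log(tt[dd == 1])
  bknots <- range(et)
  if (diff(bknots) <= 0) stop_psm("all events at a single time: cannot place boundary knots")
  interior <- if (n_interior > 0)
    as.numeric(stats::quantile(et, seq_len(n_interior) / (n_interior + 1), type = 7))
  else numeric(0)
  knots <- c(bknots[1], interior, bknots[2])
  if (any(diff(knots) <= 0)) stop_psm("degenerate interior knots (ties in event times)")

  x <- log(tt)
  B <- rp_basis(x, knots)
  Bd <- rp_basis_deriv(x, knots)
  ev <- dd == 1
  grid_x <- seq(bknots[1] - 1, log(horizon_months), length.out = 1000)
  Bg <- rp_basis_deriv(grid_x, knots)

  loglik_fn <- function(g) {
    s <- drop(B %*% g); sp <- drop(Bd %*% g)
    if (any(sp[ev] <= 0)) return(-Inf)
    sum(s[ev] + log(sp[ev]) - x[ev]) - sum(exp(s))
  }
  negobj <- function(g) {
    ll <- loglik_fn(g)
    if (!is.finite(ll)) return(1e10)
    pen <- 1e4 * sum(pmin(drop(Bg %*% g), 0)^2)
    -ll + pen
  }

  # Weibull-based initialisation: ln H = k ln t - k ln lambda
  sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = ipd, dist = "weibull")
  k0 <- 1 / sr$scale; lnlam <- unname(sr$coefficients[1])
  g0 <- c(-k0 * lnlam, k0, rep(0, n_interior))
  starts <- list(g0, g0 * 1.1, g0 * 0.9, g0 + 0.1, g0 - 0.1)[seq_len(min(5, max(1, restarts)))]
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, negobj, method = "BFGS",
                            control = list(maxit = 1000, reltol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10)
    stop_psm("RP fit did not converge after %d restarts (n_interior = %d)",
             restarts, n_interior)
  gamma <- best$par
  # post-fit monotonicity check on the extrapolation grid
  if (any(drop(Bg %*% gamma) < -1e-6))
    stop_psm("fitted log cumulative hazard is non-monotone on the extrapolation grid (n_interior = %d)",
             n_interior)
  ll <- loglik_fn(gamma)
  k_par <- length(gamma)
  structure(list(scale = "hazard", knots = knots, gamma = gamma,
                 loglik = ll, aic = 2 * k_par - 2 * ll,
                 bic = k_par * log(n_ev) - 2 * ll,
                 n_params = k_par, n_events = n_ev, n = length(tt),
                 family = sprintf("rp(%d knots)", length(knots) - 2)),
            class = c("rp_fit", "psm_surv_fit"))
}

#' Fit a standard parametric survival model
#'
#' Weibull, log-normal or log-logistic comparator via
#' [survival::survreg()], wrapped in the same interface as [fit_rp()].
#'
#' @inheritParams fit_rp
#' @param dist One of `"weibull"`, `"lognormal"`, `"loglogistic"`.
#' @return A `parametric_fit`.
#' @export
fit_parametric <- function(ipd, dist = c("weibull", "lognormal", "loglogistic")) {
  dist <- match.arg(dist)
  ipd <- as.data.frame(ipd)
  sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = ipd, dist = dist)
  ll <- sr$loglik[1]
  k_par <- 2
  n_ev <- sum(ipd$event)
  params <- switch(dist,
    weibull = list(shape = 1 / sr$scale,
                   scale = exp(unname(sr$coefficients[1]))),
    lognormal = list(meanlog = unname(sr$coefficients[1]), sdlog = sr$scale),
    loglogistic = list(shape = 1 / sr$scale,
                       scale = exp(unname(sr$coefficients[1]))))
  structure(list(dist = dist, params = params, loglik = ll,
                 aic = 2 * k_par - 2 * ll, bic = k_par * log(n_ev) - 2 * ll,
                 n_params = k_par, n_events = n_ev, n = nrow(ipd),
                 family = dist),
            class = c("parametric_fit", "psm_surv_fit"))
}

#' Construct a Weibull survival fit from known parameters
#'
#' Used when survival is specified directly (e.g. curves calibrated to
#' published medians and hazard ratios) rather than estimated from data.
#'
#' @param shape,scale Weibull shape and scale (months).
#' @return A `parametric_fit` with `NA` fit statistics.
#' @export
weibull_fit <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  structure(list(dist = "weibull", params = list(shape = shape, scale = scale),
                 loglik = NA_real_, aic = NA_real_, bic = NA_real_,
                 n_params = 2, n_events = NA_integer_, n = NA_integer_,
                 family = "weibull (specified)"),
            class = c("parametric_fit", "psm_surv_fit"))
}

#' Survival, hazard and cumulative hazard from a fitted model
#'
#' @param fit An `rp_fit` or `parametric_fit`.
#' @param t Times (months), non-negative.
#' @return Numeric vector.
#' @export
surv_prob <- function(fit, t) UseMethod("surv_prob")

#' @export
surv_prob.rp_fit <- function(fit, t) {
  if (any(t < 0)) stop_psm("t must be >= 0")
  out <- numeric(length(t))
  pos <- t > 0
  out[!pos] <- 1
  if (any(pos))
    out[pos] <- exp(-exp(drop(rp_basis(log(t[pos]), fit$knots) %*% fit$gamma)))
  out
}

#' @export
surv_prob.parametric_fit <- function(fit, t) {
  if (any(t < 0)) stop_psm("t must be >= 0")
  p <- fit$params
  switch(fit$dist,
    weibull = exp(-(t / p$scale)^p$shape),
    lognormal = 1 - stats::plnorm(t, p$meanlog, p$sdlog),
    loglogistic = 1 / (1 + (t / p$scale)^p$shape))
}

#' @rdname surv_prob
#' @export
cum_haz <- function(fit, t) {
  s <- surv_prob(fit, t)
  -log(pmax(s, .Machine$double.xmin))
}

#' @rdname surv_prob
#' @export
haz_rate <- function(fit, t) UseMethod("haz_rate")

#' @export
haz_rate.rp_fit <- function(fit, t) {
  if (any(t <= 0)) stop_psm("hazard requires t > 0")
  x <- log(t)
  s <- drop(rp_basis(x, fit$knots) %*% fit$gamma)
  sp <- drop(rp_basis_deriv(x, fit$knots) %*% fit$gamma)
  exp(s) * sp / t
}

#' @export
haz_rate.parametric_fit <- function(fit, t) {
  if (any(t <= 0)) stop_psm("hazard requires t > 0")
  p <- fit$params
  switch(fit$dist,
    weibull = (p$shape / p$scale) * (t / p$scale)^(p$shape - 1),
    lognormal = stats::dlnorm(t, p$meanlog, p$sdlog) /
      (1 - stats::plnorm(t, p$meanlog, p$sdlog)),
    loglogistic = {
      z <- (t / p$scale)^p$shape
      (p$shape / t) * z / (1 + z)
    })
}

#' Fit a bundle of candidate survival models
#'
#' Royston-Parmar fits with 0-3 interior knots, optionally plus standard
#' parametric comparators, for model selection by AIC/BIC.
#'
#' @inheritParams fit_rp
#' @param knot_range Integer vector of interior-knot counts (default 0:3).
#' @param comparators Character vector of [fit_parametric()] families, or
#'   `NULL` for none.
#' @return A `fit_bundle`: list of candidates plus per-candidate AIC/BIC
#'   table.
#' @export
fit_bundle <- function(ipd, knot_range = 0:3, comparators = NULL,
                       horizon_months = 480) {
  cands <- list()
  for (k in knot_range) {
    f <- try(fit_rp(ipd, n_interior = k, horizon_months = horizon_months),
             silent = TRUE)
    if (!inherits(f, "try-error")) cands[[sprintf("rp%d", k)]] <- f
  }
  for (d in comparators) {
    f <- try(fit_parametric(ipd, d), silent = TRUE)
    if (!inherits(f, "try-error")) cands[[d]] <- f
  }
  if (length(cands) == 0) stop_psm("no candidate model converged")
  tab <- data.frame(model = names(cands),
                    n_params = vapply(cands, `[[`, numeric(1), "n_params"),
                    loglik = vapply(cands, `[[`, numeric(1), "loglik"),
                    aic = vapply(cands, `[[`, numeric(1), "aic"),
                    bic = vapply(cands, `[[`, numeric(1), "bic"),
                    row.names = NULL)
  structure(list(candidates = cands, table = tab), class = "fit_bundle")
}

#' Select the best model from a bundle
#'
#' Argmin of the chosen criterion; ties broken by fewer parameters, then
#' lower BIC.
#'
#' @param bundle A [fit_bundle()].
#' @param criterion `"aic"` or `"bic"`.
#' @return The winning fit, with attribute `selection` naming it.
#' @export
select_model <- function(bundle, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (length(bundle$candidates) == 0) stop_psm("empty bundle")
  tab <- bundle$table
  ord <- order(tab[[criterion]], tab$n_params, tab$bic)
  winner <- bundle$candidates[[tab$model[ord[1]]]]
  attr(winner, "selection") <- list(model = tab$model[ord[1]], criterion = criterion)
  winner
}

#' Serialize / restore a survival fit as JSON
#'
#' Round-trippable record of the fitted model so a cohort-model run is
#' reproducible from a config plus fit files.
#'
#' @param fit A `psm_surv_fit`.
#' @param path JSON file path.
#' @return `write_fit_json` returns `path` invisibly; `read_fit_json` the fit.
#' @export
write_fit_json <- function(fit, path) {
  core <- unclass(fit)
  core$class <- class(fit)[1]
  jsonlite::write_json(core, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class
  obj$class <- NULL
  if (identical(cls, "rp_fit")) {
    obj$knots <- as.numeric(obj$knots); obj$gamma <- as.numeric(obj$gamma)
    structure(obj, class = c("rp_fit", "psm_surv_fit"))
  } else {
    obj$params <- as.list(obj$params)
    structure(obj, class = c("parametric_fit", "psm_surv_fit"))
  }
}
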