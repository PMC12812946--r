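# Royston-Parmar spline fitting on the log cumulative hazard scale,
# model selection, and the survival/hazard accessors.

test_that("the spline basis reduces, zeroes and straightens where it must", {
  # 0 interior knots: basis is [1, x]
  B <- rp_basis(c(-1, 0, 2), c(0, 1))
  expect_equal(B, cbind(1, c(-1, 0, 2)))
  knots <- c(0, 0.4, 1)
  # at the lower boundary every spline term vanishes
  expect_equal(rp_basis(0, knots)[1, 3], 0)
  # natural-spline linearity beyond the upper boundary: second finite
  # difference of each column is ~0
  x <- seq(1.5, 3, by = 0.01)
  B <- rp_basis(x, knots)
  for (j in seq_len(ncol(B))) {
    d2 <- diff(B[, j], differences = 2)
    expect_lt(max(abs(d2)), 1e-8)
  }
  expect_error(rp_basis(1, c(0.5, 0.5)), "strictly increasing")
})

test_that("a zero-knot RP fit is exactly a Weibull fit (independent MLE oracle)", {
  # 20 simulated datasets across shapes; loglik agreement within 1e-4
  for (i in 1:20) {
    des <- trial_design("PFS", 10 + i, 5 + i / 2, 0.5, n_per_arm = 120,
                        censor_time = 18, seed = 100 + i)
    ipd <- generate_ipd(des)
    a <- ipd[ipd$arm == "combination", ]
    f <- fit_rp(a, n_interior = 0)
    sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = a,
                            dist = "weibull")
    expect_equal(f$loglik, sr$loglik[1], tolerance = 1e-4)
    # gamma maps to (shape, scale): ln H = g0 + g1 ln t
    expect_equal(f$gamma[2], 1 / sr$scale, tolerance = 1e-3)
    expect_equal(exp(-f$gamma[1] / f$gamma[2]),
                 exp(unname(sr$coefficients[1])), tolerance = 1e-3)
  }
})

test_that("RP fit recovers exponential and Weibull truth", {
  # exponential data: shape 1
  des <- trial_design("OS", m <- 12, m, 1.0, n_per_arm = 2000,
                      censor_time = 60, seed = 8)
  ipd <- generate_ipd(des)
  a <- ipd[ipd$arm == "combination", ]
  f <- fit_rp(a, 0)
  expect_equal(f$gamma[2], 1, tolerance = 0.05) # ln H slope ~ shape
  tt <- seq(1, 40, length.out = 50)
  expect_lt(max(abs(surv_prob(f, tt) - exp(-tt * log(2) / 12))), 0.02)
  # calibrated PFS Weibull: shape ~ 1.17 at n = 2000
  des2 <- default_design("PFS", n_per_arm = 2000, seed = 9)
  f2 <- fit_rp(generate_ipd(des2)[generate_ipd(des2)$arm == "combination", ], 0)
  expect_equal(f2$gamma[2], 1.1717, tolerance = 0.1 / 1.1717)
})

test_that("adding knots never lowers the maximised log-likelihood (nesting)", {
  des <- default_design("PFS", n_per_arm = 400, seed = 15)
  a <- generate_ipd(des)
  a <- a[a$arm == "control", ]
  lls <- vapply(0:3, function(k) fit_rp(a, k)$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("survival accessors satisfy the probability axioms and the Weibull identity", {
  des <- default_design("PFS", n_per_arm = 300, seed = 4)
  a <- generate_ipd(des)
  f <- fit_rp(a[a$arm == "combination", ], 1)
  expect_equal(surv_prob(f, 0), 1)
  grid <- seq(0.01, 480, length.out = 400)
  s <- surv_prob(f, grid)
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
  # cumulative hazard non-decreasing out to the horizon
  expect_true(all(diff(cum_haz(f, grid)) >= -1e-9))
  expect_error(surv_prob(f, -1), "t must be")
  # 0-knot fit with gamma set from a known Weibull reproduces it exactly
  k <- 1.4; lam <- 18
  g <- structure(list(scale = "hazard", knots = log(c(1, 30)),
                      gamma = c(-k * log(lam), k)),
                 class = c("rp_fit", "psm_surv_fit"))
  tt <- seq(0.5, 60, length.out = 10)
  expect_equal(surv_prob(g, tt), exp(-(tt / lam)^k), tolerance = 1e-12)
  expect_equal(haz_rate(g, tt), (k / lam) * (tt / lam)^(k - 1), tolerance = 1e-9)
})

test_that("model selection follows the criterion with deterministic tie-breaks", {
  mk <- function(nm, aic, bic, k) structure(
    list(aic = aic, bic = bic, n_params = k, loglik = 0, family = nm),
    class = c("parametric_fit", "psm_surv_fit"))
  b <- list(candidates = list(a = mk("a", 100, 101, 2), b = mk("b", 98, 99, 3),
                              c = mk("c", 103, 104, 4)),
            table = data.frame(model = c("a", "b", "c"), n_params = c(2, 3, 4),
                               loglik = 0, aic = c(100, 98, 103),
                               bic = c(101, 99, 104)))
  class(b) <- "fit_bundle"
  expect_equal(attr(select_model(b, "aic"), "selection")$model, "b")
  # single candidate
  b1 <- b; b1$candidates <- b$candidates["a"]; b1$table <- b$table[1, ]
  expect_equal(attr(select_model(b1, "aic"), "selection")$model, "a")
  expect_error(select_model(list(candidates = list(), table = NULL)), "empty")
})

test_that("BIC prefers the parsimonious model when Weibull is the truth", {
  hits <- 0
  for (s in 1:50) {
    des <- trial_design("PFS", 14, 8, 0.5, n_per_arm = 150,
                        censor_time = 24, seed = 1000 + s)
    a <- generate_ipd(des)
    b <- fit_bundle(a[a$arm == "control", ], knot_range = 0:2)
    if (attr(select_model(b, "bic"), "selection")$model == "rp0") hits <- hits + 1
  }
  expect_gte(hits, 40) # >= 80% of seeds
})

test_that("AIC and BIC come from the same log-likelihood", {
  des <- default_design("PFS", n_per_arm = 200, seed = 6)
  a <- generate_ipd(des)
  for (k in 0:2) {
    f <- fit_rp(a[a$arm == "combination", ], k)
    expect_equal(f$aic - f$bic, 2 * f$n_params - f$n_params * log(f$n_events),
                 tolerance = 1e-9)
  }
})

test_that("fits serialize to JSON and back without losing predictions", {
  des <- default_design("PFS", n_per_arm = 200, seed = 6)
  a <- generate_ipd(des)
  f <- fit_rp(a[a$arm == "combination", ], 1)
  p <- tempfile(fileext = ".json")
  write_fit_json(f, p)
  g <- read_fit_json(p)
  tt <- c(1, 5, 20, 100)
  expect_equal(surv_prob(g, tt), surv_prob(f, tt), tolerance = 1e-12)
  w <- fit_parametric(a[a$arm == "control", ], "lognormal")
  write_fit_json(w, p)
  w2 <- read_fit_json(p)
  expect_equal(surv_prob(w2, tt), surv_prob(w, tt), tolerance = 1e-12)
})

test_that("RP fits agree with flexsurvspline on the same data", {
  skip_if_not_installed("flexsurv")
  des <- default_design("PFS", n_per_arm = 500, seed = 23)
  a <- generate_ipd(des)
  a <- a[a$arm == "combination", ]
  f <- fit_rp(a, 1)
  fs <- flexsurv::flexsurvspline(survival::Surv(time, event) ~ 1, data = a,
                                 k = 1, scale = "hazard")
  expect_equal(f$loglik, fs$loglik, tolerance = 1e-3)
  tt <- seq(1, 60, length.out = 20)
  s_fs <- summary(fs, t = tt, type = "survival", ci = FALSE)[[1]]$est
  expect_lt(max(abs(surv_prob(f, tt) - s_fs)), 1e-3)
})
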