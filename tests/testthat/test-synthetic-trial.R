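# Synthetic two-arm trial generator: Weibull-pair calibration, patient
# generation, and the Kaplan-Meier digitization emulator.

test_that("Weibull-pair calibration solves the median/HR system (root-check oracle)", {
  cases <- list(list(mt = 15.0, mc = 7.3, hr = 0.43, shape = 1.1717),
                list(mt = 34, mc = 27, hr = 0.67, shape = 1.7373))
  for (cs in cases) {
    cal <- calibrate_weibull_pair(cs$mt, cs$mc, cs$hr)
    # independent scalar root check: k must satisfy (mc/mt)^k = hr
    f <- function(k) (cs$mc / cs$mt)^k - cs$hr
    k_oracle <- uniroot(f, c(0.1, 10), tol = 1e-12)$root
    expect_equal(cal$shape, k_oracle, tolerance = 1e-9)
    expect_equal(cal$shape, cs$shape, tolerance = 1e-3)
    # both medians exact: S(median) = 0.5
    S <- function(t, lam) exp(-(t / lam)^cal$shape)
    expect_equal(S(cs$mt, cal$scale_trt), 0.5, tolerance = 1e-9)
    expect_equal(S(cs$mc, cal$scale_ctl), 0.5, tolerance = 1e-9)
    # constant hazard ratio at 10 time points
    h <- function(t, lam) (cal$shape / lam) * (t / lam)^(cal$shape - 1)
    tt <- seq(1, 30, length.out = 10)
    expect_equal(h(tt, cal$scale_trt) / h(tt, cal$scale_ctl),
                 rep(cs$hr, 10), tolerance = 1e-9)
    # median of each implied Weibull by numeric inversion
    expect_equal(uniroot(function(t) S(t, cal$scale_trt) - 0.5, c(0.01, 200),
                         tol = 1e-10)$root,
                 cs$mt, tolerance = 1e-6)
  }
})

test_that("calibration handles the identical-arms and error cases", {
  cal <- calibrate_weibull_pair(10, 10, 1.0)
  expect_equal(cal$shape, 1.0)
  expect_equal(cal$scale_trt, cal$scale_ctl)
  expect_error(calibrate_weibull_pair(15, 7.3, 1.0), "no common shape")
  expect_error(calibrate_weibull_pair(-1, 7.3, 0.5), "positive")
  expect_error(calibrate_weibull_pair(15, 7.3, 1.2), "hr")
  expect_error(calibrate_weibull_pair(5, 10, 0.5), "median_trt >= median_ctl")
})

test_that("arm_spec derives the scale so survival at the median is exactly 0.5", {
  a <- arm_spec("x", 100, median = 12, shape = 1.5)
  expect_equal(exp(-(12 / a$scale)^1.5), 0.5, tolerance = 1e-9)
  expect_error(arm_spec("x", 1, 12, 1.5), "n must be")
})

test_that("generate_ipd is reproducible, censors administratively, and leaves the RNG alone", {
  des <- default_design("PFS", n_per_arm = 50, seed = 11)
  a <- generate_ipd(des)
  b <- generate_ipd(des)
  expect_identical(a, b)
  expect_true(all(a$time <= des$censor_time + 1e-12))
  expect_true(all(a$event[a$time < des$censor_time - 1e-9] == 1))
  # degenerate censoring: everything censored at ~0
  des0 <- trial_design("PFS", 15, 7.3, 0.43, n_per_arm = 20, censor_time = 1e-9, seed = 1)
  z <- generate_ipd(des0)
  expect_true(all(z$event == 0))
  expect_true(all(z$time <= 1e-9))
  # caller's stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_ipd(des)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated arms recover the design medians and hazard ratio at large n", {
  des <- default_design("PFS", n_per_arm = 2000, seed = 5)
  ipd <- generate_ipd(des)
  expect_equal(km_median(ipd[ipd$arm == "combination", ]), 15.0, tolerance = 0.5 / 15)
  expect_equal(km_median(ipd[ipd$arm == "control", ]), 7.3, tolerance = 0.5 / 7.3)
  cx <- survival::coxph(survival::Surv(time, event) ~ I(arm == "combination"),
                        data = ipd)
  expect_lt(abs(exp(unname(coef(cx))) - 0.43), 0.05)
})

test_that("km_curve agrees with a hand-rolled product-limit oracle on small inputs", {
  # two patients, events at 1 and 2
  ipd <- data.frame(time = c(1, 2), event = c(1, 1))
  cv <- km_curve(ipd, risk_times = 0)
  expect_equal(cv$coords$time, c(0, 1, 2))
  expect_equal(cv$coords$survival, c(1, 0.5, 0))
  # all censored: flat at 1
  flat <- km_curve(data.frame(time = c(1, 2, 3), event = c(0, 0, 0)), risk_times = 0)
  expect_true(all(flat$coords$survival == 1))
  # <=10 patients with mixed censoring: exact agreement with the oracle
  ipd <- data.frame(time = c(0.5, 1, 1, 1.7, 2.2, 2.2, 3, 3.5, 4),
                    event = c(1, 1, 0, 1, 0, 1, 1, 0, 1))
  cv <- km_curve(ipd, risk_times = c(0, 2))
  oracle <- naive_km(ipd$time, ipd$event)
  got <- cv$coords[match(oracle$time, cv$coords$time), "survival"]
  expect_equal(got, oracle$survival, tolerance = 1e-12)
  expect_error(km_curve(data.frame(time = numeric(0), event = integer(0))), "empty")
})

test_that("km_curve output starts at 1, is non-increasing, and tracks the true survival", {
  des <- default_design("OS", n_per_arm = 10000, seed = 21)
  ipd <- generate_ipd(des)
  a <- ipd[ipd$arm == "combination", ]
  cv <- km_curve(a)
  expect_equal(cv$coords$survival[1], 1)
  expect_true(all(diff(cv$coords$survival) <= 1e-12))
  expect_equal(cv$risk_table$n_at_risk[1], nrow(a))
  # sup-norm against the closed-form generating Weibull
  truth <- exp(-(cv$coords$time / des$arms$trt$scale)^des$arms$trt$shape)
  expect_lt(max(abs(cv$coords$survival - truth)), 0.02)
})

test_that("IPD and curve CSV round trips preserve the data", {
  des <- default_design("PFS", n_per_arm = 30, seed = 2)
  ipd <- generate_ipd(des)
  f <- tempfile(fileext = ".csv")
  write_ipd_csv(ipd, f)
  back <- read_ipd_csv(f)
  expect_equal(back$time, ipd$time)
  expect_equal(back$event, ipd$event)
  cv <- km_curve(ipd[ipd$arm == "control", ])
  g <- tempfile(fileext = ".csv")
  write_curve_csv(cv, g)
  cb <- read_curve_csv(g)
  expect_equal(cb$coords$survival, cv$coords$survival)
  expect_equal(cb$risk_table$n_at_risk, cv$risk_table$n_at_risk)
  expect_equal(cb$n_total, cv$n_total)
})
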