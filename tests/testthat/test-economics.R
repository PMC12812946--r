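# Cost/QALY accrual and incremental statistics.

test_that("state costs assemble the published per-cycle components", {
  inp <- economic_inputs()
  other <- 59.89 + 152.95 + 90.71 + 140.20 + 11.64
  expect_equal(state_cost_per_cycle("control", "PFS", inp),
               419.60 + 646.59 + other)
  expect_equal(state_cost_per_cycle("combination", "PFS", inp),
               4065.70 + 419.60 + 646.59 + other)
  # progressed disease: everolimus for both arms
  expect_equal(state_cost_per_cycle("combination", "PD", inp),
               459.28 + other)
  expect_equal(state_cost_per_cycle("control", "PD", inp),
               state_cost_per_cycle("combination", "PD", inp))
  # all-zero inputs give zero
  z <- inp; z$drug_cost[] <- 0; z$other_cost[] <- 0
  expect_equal(state_cost_per_cycle("control", "PFS", z), 0)
})

test_that("adverse-event burden is incidence-weighted and additive", {
  inp <- economic_inputs()
  z <- inp
  z$ae$inc_combination[] <- 0
  expect_equal(ae_burden("combination", z)$cost, 0)
  expect_equal(ae_burden("combination", z)$qaly_loss, 0)
  # single AE with incidence 1 contributes its full cost
  one <- inp
  one$ae <- data.frame(name = "neutropenia", cost = 28.04, disutility = 0.13,
                       inc_combination = 1, inc_control = 0)
  expect_equal(ae_burden("combination", one)$cost, 28.04)
  # additivity across AEs
  two <- one
  two$ae <- rbind(two$ae, data.frame(name = "anemia", cost = 21.03,
                                     disutility = 0.07, inc_combination = 0.5,
                                     inc_control = 0))
  expect_equal(ae_burden("combination", two)$cost, 28.04 + 0.5 * 21.03)
  expect_error(ae_burden("combination", local({
    b <- one; b$ae$inc_combination <- 1.2; b
  })), "incidences")
})

test_that("accrual reduces to life-years under unit utilities and zero discount", {
  inp <- economic_inputs(utilities = c(pfs = 1, pd = 1))
  inp$ae$inc_combination[] <- 0; inp$ae$inc_control[] <- 0
  tr <- base_traces(model_settings(discount_annual = 0))$combination
  res <- accrue(tr, "combination", inp)
  expect_equal(res$total_qaly, res$life_years, tolerance = 1e-12)
  # zero PFS utility and a PFS-only trace gives zero QALYs
  inp0 <- economic_inputs(utilities = c(pfs = 0, pd = 0.443))
  inp0$ae$inc_combination[] <- 0
  alive <- weibull_fit(1, 1e9) # effectively immortal: trace never leaves PFS
  tr0 <- build_trace(alive, alive, model_settings(max_horizon_years = 2))
  expect_equal(accrue(tr0, "combination", inp0)$total_qaly, 0)
})

test_that("a single fully-progression-free cycle accrues one cycle cost plus AE one-off", {
  inp <- economic_inputs()
  alive <- weibull_fit(1, 1e9)
  tr <- build_trace(alive, alive, model_settings(discount_annual = 0,
                                                 horizon_rule = "fixed",
                                                 fixed_horizon_years = 28 / 365.25))
  expect_equal(nrow(tr$accrual), 1)
  res <- accrue(tr, "combination", inp)
  expect_equal(res$total_cost,
               state_cost_per_cycle("combination", "PFS", inp) +
                 ae_burden("combination", inp)$cost)
})

test_that("cost accrual is linear in each unit cost", {
  inp <- economic_inputs()
  traces <- base_traces()
  m <- ce_model(traces, inp)
  base <- m(list())
  doubled <- m(list(cost_drug_inavolisib = 2 * 4065.70))
  # only the combination arm's total moves, by the discounted
  # PFS-occupancy-weighted inavolisib term
  expect_equal(doubled$ctl$total_cost, base$ctl$total_cost)
  w <- sum(traces$combination$accrual$df * traces$combination$accrual$pfs_bar)
  expect_equal(doubled$trt$total_cost - base$trt$total_cost, 4065.70 * w,
               tolerance = 1e-9)
})

test_that("QALYs never exceed discounted life expectancy", {
  inp <- economic_inputs()
  for (arm in c("combination", "control")) {
    res <- accrue(base_traces()[[arm]], arm, inp)
    expect_lte(res$total_qaly, res$life_years)
  }
})

test_that("incremental statistics and dominance labels are definitional", {
  mk <- function(cost, q) list(arm = "x", total_cost = cost, total_qaly = q)
  ce <- incremental(mk(200, 4), mk(100, 2), wtp = 50)
  expect_equal(ce$icer, 50)
  expect_equal(ce$nmb, 50 * 2 - 100)
  # published worked example: 2.999 vs 1.744 QALYs -> increment 1.255
  ce2 <- incremental(mk(194306.06, 2.999), mk(55938.19, 1.744), wtp = 40271)
  expect_equal(ce2$delta_qaly, 1.255, tolerance = 1e-12)
  expect_equal(ce2$delta_cost, 138367.87, tolerance = 1e-6)
  # dominance labels and NMB signs
  expect_equal(incremental(mk(90, 3), mk(100, 2), 50)$dominance, "dominant")
  expect_gt(incremental(mk(90, 3), mk(100, 2), 1)$nmb, 0)
  expect_equal(incremental(mk(110, 1), mk(100, 2), 50)$dominance, "dominated")
  und <- incremental(mk(110, 2), mk(100, 2), 50)
  expect_true(is.na(und$icer))
  expect_equal(und$nmb, -10)
})

test_that("ICER above WTP if and only if NMB is negative (positive QALY gain)", {
  m <- base_model()
  res <- m(list())
  expect_gt(res$delta_qaly, 0)
  expect_identical(res$icer > res$wtp, res$nmb < 0)
  cheap <- m(list(cost_drug_inavolisib = 10))
  expect_identical(cheap$icer > cheap$wtp, cheap$nmb < 0)
})

test_that("per-cycle AE mode accrues over PFS occupancy instead of one-off", {
  inp1 <- economic_inputs()
  inp2 <- economic_inputs(ae_mode = "per_cycle")
  tr <- base_traces()$combination
  r1 <- accrue(tr, "combination", inp1)
  r2 <- accrue(tr, "combination", inp2)
  w <- sum(tr$accrual$df * tr$accrual$pfs_bar)
  ae_cycle <- sum(inp1$ae$inc_combination * inp1$ae$cost)
  expect_equal(r2$total_cost - (r1$total_cost - ae_burden("combination", inp1)$cost),
               w * ae_cycle, tolerance = 1e-9)
})
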