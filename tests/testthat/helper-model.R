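# Shared fixtures: the calibrated base-case survival pair, its traces and
# a reusable cost-effectiveness model closure. Built once per test run.

base_fits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pfs <- calibrate_weibull_pair(15.0, 7.3, 0.43)
      os <- calibrate_weibull_pair(34, 27, 0.67)
      cache <<- list(
        pfs_trt = weibull_fit(pfs$shape, pfs$scale_trt),
        pfs_ctl = weibull_fit(pfs$shape, pfs$scale_ctl),
        os_trt = weibull_fit(os$shape, os$scale_trt),
        os_ctl = weibull_fit(os$shape, os$scale_ctl))
    }
    cache
  }
})

base_traces <- local({
  cache <- NULL
  function(settings = model_settings()) {
    f <- base_fits()
    list(combination = build_trace(f$pfs_trt, f$os_trt, settings),
         control = build_trace(f$pfs_ctl, f$os_ctl, settings))
  }
})

base_model <- function(inputs = economic_inputs(),
                       settings = model_settings()) {
  ce_model(base_traces(settings), inputs)
}

# Hand-rolled product-limit estimator, independent of survival::survfit;
# returns survival immediately after each distinct observed time.
naive_km <- function(time, event) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    if (at_risk > 0) s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, survival = out)
}
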