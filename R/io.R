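# Configuration and end-to-end pipeline: one YAML/JSON config describes
# the survival source (synthetic design or digitized-curve CSVs), the
# economic inputs, model settings, sensitivity and scenario blocks; the
# pipeline runs digitize -> reconstruct -> fit -> trace -> accrue ->
# (DSA/PSA/scenarios) and writes audit-friendly CSV/JSON artifacts, all
# deterministic for a fixed seed.

#' Load and validate a pipeline configuration
#'
#' Reads YAML (or JSON) and fills defaults. The survival source must be
#' exactly one of a `synthetic` design block or a `files` block of
#' digitized-curve CSV paths (all of which must exist).
#'
#' @param path Config file path, or a named list already in config shape.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop_psm("config must be a YAML mapping")

  cfg$seed <- as.integer(cfg$seed %||% 1L)
  sv <- cfg$survival %||% list()
  has_syn <- !is.null(sv$synthetic); has_files <- !is.null(sv$files)
  if (has_syn == has_files)
    stop_psm("config key 'survival': exactly one of 'synthetic' or 'files' is required")
  if (has_syn) {
    syn <- sv$synthetic
    syn$n_per_arm <- syn$n_per_arm %||% 162
    syn$pfs <- utils::modifyList(
      list(median_trt = 15.0, median_ctl = 7.3, hr = 0.43, censor_time = 21.4),
      syn$pfs %||% list())
    syn$os <- utils::modifyList(
      list(median_trt = 34, median_ctl = 27, hr = 0.67, censor_time = 34.2),
      syn$os %||% list())
    sv$synthetic <- syn
  } else {
    need <- c("pfs_combination", "pfs_control", "os_combination", "os_control")
    missing_keys <- setdiff(need, names(sv$files))
    if (length(missing_keys) > 0)
      stop_psm("config key 'survival.files': missing %s",
               paste(missing_keys, collapse = ", "))
    for (k in need) if (!file.exists(sv$files[[k]]))
      stop_psm("config key 'survival.files.%s': file '%s' does not exist",
               k, sv$files[[k]])
  }
  sv$knot_range <- sv$knot_range %||% 0:3
  sv$criterion <- sv$criterion %||% "aic"
  cfg$survival <- sv

  st <- cfg$settings %||% list()
  cfg$settings <- model_settings(
    cycle_length_days = st$cycle_length_days %||% 28,
    discount_annual = st$discount_annual %||% 0.05,
    horizon_rule = st$horizon_rule %||% "lifetime",
    max_horizon_years = st$max_horizon_years %||% 40,
    fixed_horizon_years = st$fixed_horizon_years,
    half_cycle = st$half_cycle %||% TRUE)

  eco <- cfg$economics %||% list()
  base <- economic_inputs()
  if (!is.null(eco$utilities)) {
    if (is.null(eco$utilities$pfs) || is.null(eco$utilities$pd))
      stop_psm("config key 'economics.utilities': both 'pfs' and 'pd' are required")
    base$utilities <- c(pfs = eco$utilities$pfs, pd = eco$utilities$pd)
  }
  for (k in intersect(names(eco), c("wtp", "ae_mode", "ae_duration_cycles")))
    base[[k]] <- eco[[k]]
  if (!is.null(eco$drug_cost))
    for (nm in names(eco$drug_cost)) base$drug_cost[[nm]] <- eco$drug_cost[[nm]]
  if (!is.null(eco$other_cost))
    for (nm in names(eco$other_cost)) base$other_cost[[nm]] <- eco$other_cost[[nm]]
  validate_inputs(base)
  cfg$economics <- base

  cfg$psa <- utils::modifyList(list(enabled = FALSE, n_iter = 10000), cfg$psa %||% list())
  cfg$dsa <- utils::modifyList(list(enabled = TRUE), cfg$dsa %||% list())
  scn <- cfg$scenarios %||% list()
  scn$price <- utils::modifyList(list(enabled = FALSE,
                                      reductions = seq(0, 0.95, by = 0.05)),
                                 scn$price %||% list())
  scn$horizon <- utils::modifyList(list(enabled = FALSE,
                                        horizons = c(5, 10, 15, 20, Inf)),
                                   scn$horizon %||% list())
  scn$utilities <- utils::modifyList(list(enabled = FALSE,
                                          u_pfs = 0.736, u_pd = 0.630),
                                     scn$utilities %||% list())
  scn$regional <- scn$regional %||% list(enabled = FALSE)
  cfg$scenarios <- scn
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a configuration back to YAML
#'
#' @param config A `run_config` (or plain list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$settings <- unclass(cfg$settings)
  cfg$economics <- NULL # baseline economics are package defaults + overrides
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Child seeds: fixed offsets so enabling/disabling one stage never
# perturbs another stage's stream.
child_seed <- function(seed, stage) {
  seed + c(pfs = 101L, os = 202L, psa = 303L)[[stage]]
}

# Write a CSV with one audit header line carrying the config hash + seed.
write_artifact <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# psmcea config=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Fit one arm's curve via the reconstruct -> RP-spline path.
fit_arm <- function(curve, arm, endpoint, knot_range, criterion, horizon_months) {
  ipd <- reconstruct_ipd(curve, arm = arm, endpoint = endpoint)
  bundle <- fit_bundle(ipd, knot_range = knot_range, horizon_months = horizon_months)
  select_model(bundle, criterion)
}

#' Run the full cost-effectiveness pipeline
#'
#' Stages: obtain digitized curves (generating a synthetic trial when the
#' config says so), reconstruct pseudo individual patient data, fit
#' Royston-Parmar candidates and select by AIC/BIC, build discounted
#' traces, accrue the base case, then any enabled DSA, PSA and scenario
#' blocks. Every artifact carries a header line with the config hash and
#' seed; a log of per-stage verdicts (selected knot counts, seeds) is
#' written alongside.
#'
#' @param config A `run_config` from [load_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the base-case `ce_result`, fits,
#'   traces, and any DSA/PSA/scenario tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(yaml::as.yaml(unclass(config)[c("seed", "survival", "psa", "dsa", "scenarios")]))
  seed <- config$seed
  log_lines <- c(sprintf("psmcea pipeline  config=%s  seed=%d", hash, seed))

  sv <- config$survival
  horizon_months <- config$settings$max_horizon_years * 12
  curves <- list()
  if (!is.null(sv$synthetic)) {
    syn <- sv$synthetic
    for (ep in c("pfs", "os")) {
      blk <- syn[[ep]]
      des <- trial_design(toupper(ep), blk$median_trt, blk$median_ctl, blk$hr,
                          n_per_arm = syn$n_per_arm,
                          censor_time = blk$censor_time,
                          seed = child_seed(seed, ep))
      ipd <- generate_ipd(des)
      log_lines <- c(log_lines, sprintf("synthetic %s: seed=%d n/arm=%d",
                                        ep, des$seed, syn$n_per_arm))
      for (arm in c("combination", "control")) {
        cv <- km_curve(ipd[ipd$arm == arm, , drop = FALSE])
        curves[[paste(ep, arm, sep = "_")]] <- cv
        write_curve_csv(cv, file.path(out_dir, sprintf("curve_%s_%s.csv", ep, arm)))
      }
    }
  } else {
    for (k in names(sv$files)) curves[[k]] <- read_curve_csv(sv$files[[k]])
  }

  fits <- list()
  for (k in names(curves)) {
    parts <- strsplit(k, "_")[[1]]
    fits[[k]] <- fit_arm(curves[[k]], parts[2], toupper(parts[1]),
                         sv$knot_range, sv$criterion, horizon_months)
    sel <- attr(fits[[k]], "selection")
    log_lines <- c(log_lines, sprintf("fit %s: selected %s by %s (loglik %.3f)",
                                      k, sel$model, sel$criterion, fits[[k]]$loglik))
    write_fit_json(fits[[k]], file.path(out_dir, sprintf("fit_%s.json", k)))
  }

  traces <- list(
    combination = build_trace(fits$pfs_combination, fits$os_combination,
                              config$settings),
    control = build_trace(fits$pfs_control, fits$os_control, config$settings))
  for (arm in names(traces))
    write_trace_csv(traces[[arm]], file.path(out_dir, sprintf("trace_%s.csv", arm)))

  inputs <- config$economics
  model <- ce_model(traces, inputs)
  base_ce <- model(list())
  write_artifact(data.frame(
    treatment = c("combination", "control"),
    total_cost = c(base_ce$trt$total_cost, base_ce$ctl$total_cost),
    incremental_cost = c(base_ce$delta_cost, NA),
    qalys = c(base_ce$trt$total_qaly, base_ce$ctl$total_qaly),
    incremental_qalys = c(base_ce$delta_qaly, NA),
    icer = c(base_ce$icer, NA)),
    file.path(out_dir, "base_case.csv"), hash, seed)

  out <- list(config = config, fits = fits, traces = traces, base_case = base_ce)

  if (isTRUE(config$dsa$enabled)) {
    out$tornado <- dsa_tornado(model, dsa_ranges(inputs))
    write_artifact(out$tornado, file.path(out_dir, "tornado.csv"), hash, seed)
  }
  if (isTRUE(config$psa$enabled)) {
    psa <- run_psa(model, dsa_ranges(inputs), n_iter = config$psa$n_iter,
                   seed = child_seed(seed, "psa"))
    log_lines <- c(log_lines, sprintf("psa: seed=%d iterations=%d",
                                      child_seed(seed, "psa"), config$psa$n_iter))
    out$psa <- psa
    write_artifact(psa$draws, file.path(out_dir, "psa_scatter.csv"), hash, seed)
    grid <- seq(0, 4 * inputs$wtp, length.out = 81)
    out$ceac <- ceac(psa, grid)
    write_artifact(out$ceac, file.path(out_dir, "ceac.csv"), hash, seed)
  }
  scn <- config$scenarios
  if (isTRUE(scn$price$enabled)) {
    out$price_sweep <- price_sweep(model, scn$price$reductions,
                                   base_cycle_cost = inputs$drug_cost[["inavolisib"]])
    write_artifact(out$price_sweep, file.path(out_dir, "scenario_price.csv"),
                   hash, seed)
  }
  if (isTRUE(scn$horizon$enabled)) {
    hz <- vapply(scn$horizon$horizons,
                 function(h) if (is.character(h) && h == "lifetime") Inf else as.numeric(h),
                 numeric(1))
    out$horizon_sweep <- horizon_sweep(traces, inputs, hz)
    write_artifact(out$horizon_sweep, file.path(out_dir, "scenario_horizon.csv"),
                   hash, seed)
  }
  if (isTRUE(scn$utilities$enabled)) {
    ce_u <- utility_scenario(model, scn$utilities$u_pfs, scn$utilities$u_pd)
    out$utility_scenario <- ce_u
    write_artifact(data.frame(
      u_pfs = scn$utilities$u_pfs, u_pd = scn$utilities$u_pd,
      cost_combination = ce_u$trt$total_cost, cost_control = ce_u$ctl$total_cost,
      qaly_combination = ce_u$trt$total_qaly, qaly_control = ce_u$ctl$total_qaly,
      icer = ce_u$icer),
      file.path(out_dir, "scenario_utilities.csv"), hash, seed)
  }
  if (isTRUE(scn$regional$enabled)) {
    thr <- unlist(scn$regional$thresholds)
    out$regional <- regional_wtp(base_ce, thr)
    write_artifact(out$regional, file.path(out_dir, "scenario_regional.csv"),
                   hash, seed)
  }
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(out)
}
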