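#' Default model-parameter table
#'
#' One row per model input: base value, deterministic-sensitivity range,
#' PSA distribution family, and provenance. Provenance `"table"` marks
#' values taken from the published input table; `"calibrated"` marks the
#' CPC overall-survival shape parameter, which is recalibrated so the
#' extrapolated median matches the CameL trial's reported 27.9-month median
#' OS (the published shape is inconsistent with the trial median, with the
#' arm's reported survival advantage, and with the published base-case
#' results; see the methods vignette); `"assumed"` marks
#' placeholder defaults for inputs that live only in unavailable trial
#' supplements (treatment-duration caps, subsequent-therapy fractions,
#' background-mortality anchor).
#'
#' Distribution families: `beta` (utilities/disutilities), `gamma` (costs),
#' `normal` (weight, BSA), `lognormal` (hazard ratios; normal on the log
#' scale keeps them positive), `fixed` (not sampled in PSA). Parameters
#' with `NA` range are excluded from one-way DSA.
#'
#' @return `data.frame` with columns `name`, `base`, `low`, `high`, `dist`,
#'   `provenance`.
#' @export
default_parameters <- function() {
  p <- function(name, base, low = NA, high = NA, dist = "fixed", provenance = "table")
    data.frame(name = name, base = base, low = low, high = high,
               dist = dist, provenance = provenance)
  rbind(
    # survival models (3-week-cycle time scale, raw-theta log-logistic)
    p("os_cpc_theta", 0.003326),
    p("os_cpc_kappa", 1.542250, provenance = "calibrated"),
    p("os_pc_theta", 0.004501),
    p("os_pc_kappa", 1.618052),
    p("pfs_cpc_theta", 0.01503),
    p("pfs_cpc_kappa", 1.46627),
    p("pfs_pc_theta", 0.03905),
    p("pfs_pc_kappa", 1.36768),
    p("os2_scale", 0.07471),
    p("os2_shape", 1.15519),
    p("pfs2_scale", 0.25070),
    p("pfs2_shape", 1.14230),
    p("hr_os_ppp", 0.71, 0.57, 0.85, "lognormal"),
    p("hr_pfs_ppp", 0.92, 0.74, 1.10, "lognormal"),
    p("hr_os_niv", 0.76, 0.56, 1.04, "lognormal"),
    p("hr_pfs_niv", 0.87, 0.46, 1.19, "lognormal"),
    # per-cycle costs (USD, reimbursement-adjusted, reference profile)
    p("cost_camrelizumab", 424.51, 212.25, 636.76, "gamma"),
    p("cost_pembrolizumab", 2597.79, 1298.89, 3896.69, "gamma"),
    p("cost_pemetrexed", 79.31, 39.65, 118.96, "gamma"),
    p("cost_nivolumab", 60.35, 30.17, 90.52, "gamma"),
    p("cost_docetaxel", 5.61, 2.81, 8.41, "gamma"),
    p("cost_followup", 55.60, 27.80, 83.40, "gamma"),
    p("cost_third_line", 854.05, 427.02, 1281.08, "gamma"),
    p("cost_bsc", 337.50, 168.75, 506.25, "gamma"),
    p("cost_eol", 2627.80, 1313.90, 3941.70, "gamma"),
    p("cost_ae_cpc", 1407.53, 703.77, 2111.30, "gamma"),
    p("cost_ae_ppp", 1141.48, 570.74, 1712.22, "gamma"),
    p("cost_ae_pc", 883.90, 441.95, 1325.85, "gamma"),
    # utilities
    p("u_stable", 0.856, 0.718, 0.994, "beta"),
    p("u_prog1", 0.768, 0.595, 0.941, "beta"),
    p("u_prog2", 0.703, 0.545, 0.861, "beta"),
    p("du_cpc", 0.079, 0.061, 0.096, "beta"),
    p("du_ppp", 0.045, 0.035, 0.056, "beta"),
    p("du_pc", 0.063, 0.049, 0.077, "beta"),
    # other
    p("discount_rate", 0.05, 0, 0.08, "fixed"),
    p("weight", 65, 52, 78, "normal"),
    p("bsa", 1.72, 1.38, 2.07, "normal"),
    p("start_age", 60, 55, 65, "fixed", "assumed"),
    # supplementary-only inputs: documented placeholder defaults
    p("cap_1l_cpc", 10, 8, 12, "fixed", "assumed"),
    p("cap_1l_pc", 12, 9, 15, "fixed", "assumed"),
    p("cap_1l_ppp", 11, 8, 14, "fixed", "assumed"),
    p("cap_2l", 4, 3, 5, "fixed", "assumed"),
    p("pembro_paid_cycles", 4),
    p("frac_2l", 0.5, 0.25, 0.75, "fixed", "assumed"),
    p("frac_3l", 0.5, 0.25, 0.75, "fixed", "assumed"),
    p("lt_base_prob", 0.009, NA, NA, "fixed", "assumed"),
    p("lt_slope", log(1.09), NA, NA, "fixed", "assumed")
  )
}

#' Read or assemble a run configuration
#'
#' A run configuration bundles the analysis selector (`"primary"` = CPC vs
#' PC, `"secondary"` = PPP vs CPC), the global settings and the parameter
#' table. `read_run_config()` loads a YAML file (see the bundled
#' `inst/extdata/config_primary.yaml`); `run_config()` builds one in code,
#' with optional parameter overrides.
#'
#' @param analysis `"primary"` or `"secondary"`.
#' @param settings A [model_settings()]; the discount rate and start age in
#'   the parameter table take precedence so sensitivity analyses can vary
#'   them.
#' @param overrides Named list of parameter base-value overrides.
#' @return A list of class `run_config`: `analysis`, `settings`, `params`.
#' @export
run_config <- function(analysis = c("primary", "secondary"),
                       settings = model_settings(), overrides = NULL) {
  analysis <- match.arg(analysis)
  params <- default_parameters()
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), params$name)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    for (nm in names(overrides)) params$base[params$name == nm] <- overrides[[nm]]
  }
  validate_params(params)
  structure(list(analysis = analysis, settings = settings, params = params),
            class = "run_config")
}

validate_params <- function(params) {
  need <- default_parameters()$name
  miss <- setdiff(need, params$name)
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  rng <- !is.na(params$low)
  bad <- params$name[rng & (params$low > params$base | params$base > params$high)]
  if (length(bad))
    stop("range must satisfy low <= base <= high for: ", paste(bad, collapse = ", "))
  ok_dist <- c("beta", "gamma", "normal", "lognormal", "fixed")
  bad <- params$name[!params$dist %in% ok_dist]
  if (length(bad)) stop("unknown distribution for: ", paste(bad, collapse = ", "))
  invisible(params)
}

#' @rdname run_config
#' @param path Path to a YAML configuration file with top-level keys
#'   `analysis`, `settings`, `parameters`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (k in c("analysis", "settings", "parameters"))
    if (is.null(raw[[k]])) stop("config is missing the `", k, "` block")
  st <- raw$settings
  settings <- model_settings(
    cycle_days = st$cycle_days %||% 21,
    horizon_years = st$horizon_years %||% 30,
    discount_annual = st$discount_annual %||% 0.05,
    wtp = st$wtp %||% 11146,
    start_age = st$start_age %||% 60,
    half_cycle_correction = isTRUE(st$half_cycle_correction)
  )
  params <- do.call(rbind, lapply(names(raw$parameters), function(nm) {
    e <- raw$parameters[[nm]]
    if (is.null(e$base)) stop("parameter `", nm, "` has no base value")
    data.frame(name = nm, base = e$base,
               low = e$low %||% NA_real_, high = e$high %||% NA_real_,
               dist = e$dist %||% "fixed",
               provenance = e$provenance %||% "table")
  }))
  validate_params(params)
  structure(list(analysis = match.arg(raw$analysis, c("primary", "secondary")),
                 settings = settings, params = params),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

param_value <- function(config, name) {
  i <- match(name, config$params$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  config$params$base[i]
}

#' Set a parameter's base value in a configuration
#'
#' @param config A `run_config`.
#' @param name Parameter name (see [default_parameters()]).
#' @param value New base value.
#' @return The modified configuration.
#' @export
set_param <- function(config, name, value) {
  i <- match(name, config$params$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  config$params$base[i] <- value
  config
}

#' Build strategies, settings and life table from a configuration
#'
#' Wires the parameter table into concrete [strategy_spec()]s with their
#' survival models. The primary analysis compares PC (reference) with CPC;
#' the secondary analysis compares CPC (reference) with PPP, whose curves
#' are the CPC log-logistic models adjusted by the network-meta-analysis
#' hazard ratios.
#'
#' @param config A `run_config`.
#' @return List: `strategies` (named list of [strategy_spec()]),
#'   `settings`, `life_table`, `utilities`, `profile`.
#' @export
build_cea_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- function(nm) param_value(config, nm)

  settings <- config$settings
  settings$discount_annual <- v("discount_rate")
  settings$start_age <- v("start_age")

  profile <- patient_profile(weight = v("weight"), bsa = v("bsa"),
                             start_age = v("start_age"))
  utilities <- list(stable = v("u_stable"), prog1 = v("u_prog1"),
                    prog2 = v("u_prog2"))
  life_table <- synthetic_life_table(base_prob = v("lt_base_prob"),
                                     base_age = 60, slope = v("lt_slope"))

  pem <- drug_cost("pemetrexed", v("cost_pemetrexed"), "per_bsa", dose = 500)
  doc <- drug_cost("docetaxel", v("cost_docetaxel"), "per_bsa", dose = 75)
  os2 <- weibull_model(v("os2_scale"), v("os2_shape"))
  pfs2 <- weibull_model(v("pfs2_scale"), v("pfs2_shape"))

  common <- function(ae_cost, ae_dis)
    list(frac_2l = v("frac_2l"), frac_3l = v("frac_3l"),
         ae_cost = ae_cost, ae_disutility = ae_dis,
         third_line_cost = v("cost_third_line"), bsc_cost = v("cost_bsc"),
         followup_cost = v("cost_followup"), eol_cost = v("cost_eol"))

  cpc <- do.call(strategy_spec, c(list(
    name = "CPC",
    first_line = list(drug_cost("camrelizumab", v("cost_camrelizumab")), pem),
    first_line_cap = round(v("cap_1l_cpc")),
    second_line = list(doc), second_line_cap = round(v("cap_2l")),
    models = list(os1 = loglogistic_model(v("os_cpc_theta"), v("os_cpc_kappa")),
                  pfs1 = loglogistic_model(v("pfs_cpc_theta"), v("pfs_cpc_kappa")),
                  os2 = os2, pfs2 = pfs2)),
    common(v("cost_ae_cpc"), v("du_cpc"))))

  strategies <- if (config$analysis == "primary") {
    pc <- do.call(strategy_spec, c(list(
      name = "PC",
      first_line = list(pem),
      first_line_cap = round(v("cap_1l_pc")),
      second_line = list(drug_cost("nivolumab", v("cost_nivolumab"), "per_kg", dose = 4.5)),
      second_line_cap = round(v("cap_2l")),
      models = list(os1 = loglogistic_model(v("os_pc_theta"), v("os_pc_kappa")),
                    pfs1 = loglogistic_model(v("pfs_pc_theta"), v("pfs_pc_kappa")),
                    os2 = hr_adjust(os2, v("hr_os_niv")),
                    pfs2 = hr_adjust(pfs2, v("hr_pfs_niv")))),
      common(v("cost_ae_pc"), v("du_pc"))))
    list(PC = pc, CPC = cpc)
  } else {
    ppp <- do.call(strategy_spec, c(list(
      name = "PPP",
      first_line = list(
        drug_cost("pembrolizumab", v("cost_pembrolizumab"),
                  paid_cycles_cap = round(v("pembro_paid_cycles"))),
        pem),
      first_line_cap = round(v("cap_1l_ppp")),
      second_line = list(doc), second_line_cap = round(v("cap_2l")),
      models = list(
        os1 = loglogistic_model(v("os_cpc_theta"), v("os_cpc_kappa"),
                                hr = v("hr_os_ppp")),
        pfs1 = loglogistic_model(v("pfs_cpc_theta"), v("pfs_cpc_kappa"),
                                 hr = v("hr_pfs_ppp")),
        os2 = os2, pfs2 = pfs2)),
      common(v("cost_ae_ppp"), v("du_ppp"))))
    list(CPC = cpc, PPP = ppp)
  }

  list(strategies = strategies, settings = settings, life_table = life_table,
       utilities = utilities, profile = profile)
}

#' Run the base-case cost-effectiveness analysis for a configuration
#'
#' Runs the cohort model for both strategies of the configured analysis and
#' returns the incremental comparison.
#'
#' @param config A `run_config`.
#' @return A `ce_table` (see [compare_strategies()]).
#' @examples
#' run_base_case(run_config("primary"))
#' @export
run_base_case <- function(config) {
  inp <- build_cea_inputs(config)
  res <- lapply(inp$strategies, run_cohort, settings = inp$settings,
                life_table = inp$life_table, utilities = inp$utilities,
                profile = inp$profile)
  compare_strategies(unname(res), wtp = inp$settings$wtp)
}

#' ICER of the configured comparison at current base values
#'
#' Convenience wrapper around [run_base_case()] returning the comparator's
#' ICER against the reference strategy; the unit of account for the
#' deterministic sensitivity analyses.
#'
#' @param config A `run_config`.
#' @return ICER in USD/QALY.
#' @export
base_icer <- function(config) {
  ce <- run_base_case(config)
  ce$icer[2]
}
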