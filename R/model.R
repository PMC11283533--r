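# Full two-arm decision model: bundles fitted survival models, costs,
# utilities and assay parameters, and evaluates the assay-guided arm
# against the standard-of-care comparator.

high_risk_regimens <- function()
  c("acalabrutinib_1l", "venetoclax_rituximab_2l", "idelalisib_rituximab_3l")
low_risk_regimens <- function()
  c("venetoclax_obinutuzumab_1l", "acalabrutinib_2l",
    "idelalisib_rituximab_3l")

#' Assemble the full CLL decision model
#'
#' The intervention arm stratifies patients by assay: high-risk patients
#' initiate acalabrutinib (then venetoclax + rituximab, then idelalisib +
#' rituximab); low-risk patients initiate venetoclax + obinutuzumab (then
#' acalabrutinib, then idelalisib + rituximab). The comparator treats all
#' patients along the high-risk sequence with no assay.
#'
#' @param fits Named list of survival fits: one entry per regimen in
#'   [cll_default_costs()], each a list with `pfs` and `os`
#'   `parametric_survival` models.
#' @param costs Data frame as [cll_default_costs()].
#' @param ae Adverse-event inputs as [cll_default_ae()].
#' @param assay An [assay_spec()].
#' @param utilities,utility_sds Named lists as [cll_default_utilities()] and
#'   [cll_default_utility_sds()].
#' @param cost_variability List with `drug_pct` (uniform half-width as a
#'   fraction of the list price, default 0.25) and `assay_pct` (default
#'   0.75).
#' @param config A [model_config()].
#' @param wtp Willingness-to-pay threshold (CAD/QALY), default 50000.
#' @return A `cll_model` object.
#' @export
cll_model <- function(fits, costs = cll_default_costs(),
                      ae = cll_default_ae(), assay = assay_spec(),
                      utilities = cll_default_utilities(),
                      utility_sds = cll_default_utility_sds(),
                      cost_variability = list(drug_pct = 0.25,
                                              assay_pct = 0.75),
                      config = model_config(), wtp = 50000) {
  need <- costs$regimen
  missing_fit <- setdiff(need, names(fits))
  if (length(missing_fit))
    stop("missing survival fits for: ", paste(missing_fit, collapse = ", "))
  for (r in need)
    stopifnot(inherits(fits[[r]]$pfs, "parametric_survival"),
              inherits(fits[[r]]$os, "parametric_survival"))
  structure(list(fits = fits, costs = costs, ae = ae, assay = assay,
                 utilities = utilities, utility_sds = utility_sds,
                 cost_variability = cost_variability, config = config,
                 wtp = wtp),
            class = "cll_model")
}

model_line <- function(model, regimen) {
  row <- model$costs[model$costs$regimen == regimen, ]
  treatment_line(
    drug_label = regimen,
    cost_per_cycle = row$cost_per_cycle,
    fixed_duration_cycles = if (!is.na(row$fixed_duration_cycles))
      row$fixed_duration_cycles,
    pfs_model = model$fits[[regimen]]$pfs,
    os_model = model$fits[[regimen]]$os,
    p_minor_ae_per_cycle = model$ae$p_minor,
    p_major_ae_per_cycle = model$ae$p_major,
    ae_cost_minor = model$ae$cost_minor,
    ae_cost_major = model$ae$cost_major)
}

#' Construct the three strategy arms of the model
#'
#' @param model A [cll_model()].
#' @return Named list of [strategy_arm()] objects: `high` (high-risk
#'   pathway), `low` (low-risk pathway) and `comparator` (standard of care;
#'   identical to the high-risk pathway but carrying no assay).
#' @export
cll_strategy_arms <- function(model) {
  stopifnot(inherits(model, "cll_model"))
  mk <- function(label, regimens, assay)
    strategy_arm(label, lapply(regimens, model_line, model = model),
                 assay = assay, utilities = model$utilities)
  list(high = mk("high_risk_pathway", high_risk_regimens(), model$assay),
       low = mk("low_risk_pathway", low_risk_regimens(), model$assay),
       comparator = mk("standard_of_care", high_risk_regimens(), NULL))
}

#' Deterministic evaluation of the two-arm model
#'
#' Runs the high- and low-risk pathways at the mean parameter values, forms
#' the intervention arm by assay mixing and the comparator as the high-risk
#' pathway without assay, and returns the incremental statistics.
#'
#' @param model A [cll_model()].
#' @return List with pathway outcomes (`high`, `low`), arm outcomes
#'   (`intervention`, `comparator`), `delta_cost`, `delta_qalys`, `icer`
#'   (number or dominance label) and `nmb` at the model's WTP threshold.
#' @export
evaluate_deterministic <- function(model) {
  arms <- cll_strategy_arms(model)
  high <- run_arm(arms$high, model$config)
  low <- run_arm(arms$low, model$config)
  intervention <- mix_by_assay(model$assay, high, low)
  comparator <- high  # standard of care: high-risk sequence, no assay
  dc <- intervention$cost - comparator$cost
  de <- intervention$qalys - comparator$qalys
  list(high = high, low = low,
       intervention = intervention, comparator = comparator,
       delta_cost = dc, delta_qalys = de,
       icer = icer(dc, de), nmb = nmb(dc, de, model$wtp))
}

#' Load a decision model from a fixture/configuration bundle
#'
#' Reads the bundle's `config.yaml`, fits Weibull models to every referenced
#' KM point file, and assembles the [cll_model()].
#'
#' @param dir Bundle directory (as written by [make_fixture_bundle()]).
#' @param family Survival family passed to [fit_parametric()].
#' @return A `cll_model` object.
#' @export
load_model_from_bundle <- function(dir, family = "weibull") {
  config_path <- file.path(dir, "config.yaml")
  if (!file.exists(config_path)) stop("no config.yaml in '", dir, "'")
  cfg <- yaml::read_yaml(config_path)
  regs <- names(cfg$regimens)
  fits <- lapply(regs, function(r) {
    rc <- cfg$regimens[[r]]
    list(pfs = fit_parametric(read_km_points(file.path(dir, rc$pfs_km)),
                              family),
         os = fit_parametric(read_km_points(file.path(dir, rc$os_km)),
                             family))
  })
  names(fits) <- regs
  costs <- data.frame(
    regimen = regs,
    cost_per_cycle = vapply(cfg$regimens, `[[`, 0, "cost_per_cycle"),
    fixed_duration_cycles = vapply(cfg$regimens, function(rc)
      if (is.null(rc$fixed_duration_cycles)) NA_real_
      else as.numeric(rc$fixed_duration_cycles), 0))
  rc1 <- cfg$regimens[[1]]
  ae <- list(p_minor = rc1$p_minor_ae_per_cycle,
             p_major = rc1$p_major_ae_per_cycle,
             cost_minor = rc1$ae_cost_minor,
             cost_major = rc1$ae_cost_major)
  ut <- cfg$utilities
  ut$on_treatment <- as.numeric(ut$on_treatment)
  usd <- cfg$utility_sds
  usd$on_treatment <- as.numeric(usd$on_treatment)
  cll_model(
    fits = fits, costs = costs, ae = ae,
    assay = assay_spec(cfg$assay$cost, cfg$assay$prevalence_high_risk,
                       cfg$assay$sensitivity, cfg$assay$specificity),
    utilities = ut, utility_sds = usd,
    cost_variability = cfg$cost_variability,
    config = model_config(cfg$model$n_cycles, cfg$model$cycle_length,
                          cfg$model$discount_rate_annual,
                          cfg$model$half_cycle_correction),
    wtp = cfg$wtp_threshold)
}
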