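# End-to-end orchestration: fixture generation, curve fitting, model runs
# and scenario sweeps, each writing CSV outputs plus a run manifest.

pkg_version <- function() {
  as.character(utils::packageVersion("cllcea"))
}

write_manifest <- function(dir, command, seed = NULL, flags = list(),
                           inputs = character()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(command = command, seed = seed, flags = flags,
                   input_md5 = digests,
                   package_version = pkg_version(),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

prepare_out_dir <- function(out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory '", out_dir,
         "' is not empty; use force = TRUE to overwrite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

#' Generate the synthetic fixture bundle (workflow command)
#'
#' @param seed Master seed.
#' @param out_dir Output directory; refused when non-empty unless `force`.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the bundle description from [make_fixture_bundle()].
#' @export
cmd_make_fixtures <- function(seed, out_dir, force = FALSE) {
  prepare_out_dir(out_dir, force)
  bundle <- make_fixture_bundle(seed, out_dir)
  write_manifest(out_dir, "make-fixtures", seed = seed,
                 inputs = bundle$km_files)
  invisible(bundle)
}

#' Fit parametric survival models to a directory of KM files (command)
#'
#' Fits every `*.csv` under `points_dir` (or its `km/` subdirectory) and
#' writes one YAML model document per input plus a `fit_diagnostics.csv`
#' with the linearized-fit R-squared.
#'
#' @param points_dir Directory of KM CSV files.
#' @param out_dir Output directory for model documents.
#' @param family Survival family for [fit_parametric()].
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, the diagnostics data frame.
#' @export
cmd_fit <- function(points_dir, out_dir, family = "weibull", force = FALSE) {
  src <- if (dir.exists(file.path(points_dir, "km")))
    file.path(points_dir, "km") else points_dir
  files <- list.files(src, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no KM CSV files found under '", points_dir, "'")
  prepare_out_dir(out_dir, force)
  diag <- lapply(files, function(f) {
    pts <- read_km_points(f)
    fit <- fit_parametric(pts, family)
    out <- file.path(out_dir, sub("\\.csv$", ".yaml", basename(f)))
    write_survival_model(fit, out)
    data.frame(input = basename(f), family = fit$family,
               shape = fit$shape, scale = fit$scale,
               r_squared = fit$r_squared, n_points = fit$n_points)
  })
  diag <- do.call(rbind, diag)
  utils::write.csv(diag, file.path(out_dir, "fit_diagnostics.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "fit", flags = list(family = family),
                 inputs = files)
  invisible(diag)
}

summary_row <- function(label, cost, qalys) {
  data.frame(arm = label, cost = cost, qalys = qalys)
}

#' Run the two-arm model (workflow command)
#'
#' Deterministic mode writes the arm summary table (costs, QALYs, ICER,
#' NMB); PSA mode additionally writes the per-draw samples, the CE-plane
#' coordinates and the acceptability curve, with means and 95% intervals
#' (mean +/- 1.96 x SD) in the summary.
#'
#' @param bundle_dir Configuration/fixture bundle directory (see
#'   [make_fixture_bundle()]).
#' @param mode `"deterministic"` or `"psa"`.
#' @param out_dir Output directory.
#' @param n_iterations PSA draws (PSA mode).
#' @param seed PSA seed.
#' @param wtp Willingness-to-pay override; `NULL` uses the bundle's value.
#' @param common_draws Common parameter draws across arms (default TRUE).
#' @param half_cycle Half-cycle-correction override; `NULL` uses the
#'   bundle's setting.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, the summary object (list for deterministic mode,
#'   `psa_summary` for PSA mode).
#' @export
cmd_run <- function(bundle_dir, mode = c("deterministic", "psa"), out_dir,
                    n_iterations = 1000, seed = 1, wtp = NULL,
                    common_draws = TRUE, half_cycle = NULL, force = FALSE) {
  mode <- match.arg(mode)
  model <- load_model_from_bundle(bundle_dir)
  if (!is.null(wtp)) model$wtp <- wtp
  if (!is.null(half_cycle))
    model$config$half_cycle_correction <- isTRUE(half_cycle)
  prepare_out_dir(out_dir, force)
  flags <- list(mode = mode, wtp = model$wtp,
                half_cycle_correction = model$config$half_cycle_correction,
                common_draws = common_draws)

  if (mode == "deterministic") {
    res <- evaluate_deterministic(model)
    tab <- rbind(
      summary_row("intervention", res$intervention$cost,
                  res$intervention$qalys),
      summary_row("comparator", res$comparator$cost, res$comparator$qalys))
    tab$delta_cost <- c(res$delta_cost, NA)
    tab$delta_qalys <- c(res$delta_qalys, NA)
    tab$icer <- c(format_icer(res$icer), NA)
    tab$nmb <- c(res$nmb, NA)
    utils::write.csv(tab, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    write_manifest(out_dir, "run", seed = NULL, flags = flags,
                   inputs = file.path(bundle_dir, "config.yaml"))
    return(invisible(res))
  }

  samples <- run_psa(model, n_iterations = n_iterations, seed = seed,
                     common_draws = common_draws)
  summ <- summarize_psa(samples, model$wtp)
  write_psa_samples(samples, file.path(out_dir, "psa_samples.csv"))
  st <- summ$stats
  tab <- data.frame(quantity = rownames(st), st, row.names = NULL)
  tab$icer <- c(format_icer(summ$icer), rep(NA, nrow(tab) - 1))
  tab$nmb_of_means <- c(summ$nmb, rep(NA, nrow(tab) - 1))
  utils::write.csv(tab, file.path(out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  d <- psa_deltas(samples)
  utils::write.csv(
    data.frame(draw = samples$draw, delta_cost = d$dc, delta_qalys = d$de),
    file.path(out_dir, "ce_plane.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(ceac(samples), file.path(out_dir, "ceac.csv"),
                   row.names = FALSE, quote = FALSE)
  flags$seed <- seed
  flags$n_iterations <- n_iterations
  write_manifest(out_dir, "run", seed = seed, flags = flags,
                 inputs = file.path(bundle_dir, "config.yaml"))
  invisible(summ)
}

#' Scenario sweep (workflow command)
#'
#' Writes one row per scenario value with the incremental cost, incremental
#' QALYs and ICER, sweeping either the assay cost or the high-risk
#' prevalence.
#'
#' @param bundle_dir Configuration/fixture bundle directory.
#' @param axis `"assay_cost"` or `"prevalence"`.
#' @param values Scenario values.
#' @param out_dir Output directory.
#' @param mode,n_iterations,seed,common_draws See [scenario_sweep()].
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, the scenario table.
#' @export
cmd_scenarios <- function(bundle_dir, axis, values, out_dir,
                          mode = "deterministic", n_iterations = 1000,
                          seed = 1, common_draws = TRUE, force = FALSE) {
  model <- load_model_from_bundle(bundle_dir)
  prepare_out_dir(out_dir, force)
  tab <- scenario_sweep(model, axis = axis, values = values, mode = mode,
                        n_iterations = n_iterations, seed = seed,
                        common_draws = common_draws)
  utils::write.csv(tab, file.path(out_dir, "scenarios.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "scenarios", seed = seed,
                 flags = list(axis = axis, mode = mode,
                              n_iterations = n_iterations,
                              common_draws = common_draws),
                 inputs = file.path(bundle_dir, "config.yaml"))
  invisible(tab)
}
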