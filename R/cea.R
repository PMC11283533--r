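# Cost-effectiveness statistics: ICER, net monetary benefit, CE-plane
# quadrants, acceptability curve, and scenario sweeps.

#' Incremental cost-effectiveness ratio
#'
#' Incremental cost divided by incremental effectiveness. Dominance replaces
#' the ratio: `"dominant"` when the intervention is cheaper and more
#' effective, `"dominated"` when costlier and less effective; an incremental
#' effect within `tol` of zero returns `"undefined (dE ~ 0)"`.
#'
#' @param delta_cost Incremental cost (CAD).
#' @param delta_qalys Incremental effectiveness (QALYs).
#' @param tol Tolerance below which `delta_qalys` counts as zero.
#' @return A number (CAD/QALY) or a dominance label.
#' @export
icer <- function(delta_cost, delta_qalys, tol = 1e-9) {
  if (abs(delta_qalys) < tol) return("undefined (dE ~ 0)")
  if (delta_cost < 0 && delta_qalys > 0) return("dominant")
  if (delta_cost > 0 && delta_qalys < 0) return("dominated")
  delta_cost / delta_qalys
}

#' Net monetary benefit
#'
#' @param delta_cost Incremental cost (CAD).
#' @param delta_qalys Incremental effectiveness (QALYs).
#' @param wtp Willingness-to-pay threshold (CAD/QALY), default 50000.
#' @return `delta_qalys * wtp - delta_cost` (CAD).
#' @export
nmb <- function(delta_cost, delta_qalys, wtp = 50000) {
  delta_qalys * wtp - delta_cost
}

psa_deltas <- function(samples) {
  list(dc = samples$cost_intervention - samples$cost_comparator,
       de = samples$qaly_intervention - samples$qaly_comparator)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the fraction of PSA draws with
#' positive net monetary benefit (`wtp * dE - dC > 0`).
#'
#' @param samples A `psa_samples` object (or data frame with the four
#'   arm-level cost/QALY columns).
#' @param grid Ordered non-negative thresholds; default 0 to 150,000 by
#'   1,000.
#' @return Data frame with `threshold` and `probability`.
#' @export
ceac <- function(samples, grid = seq(0, 150000, by = 1000)) {
  stopifnot(all(grid >= 0), !is.unsorted(grid))
  d <- psa_deltas(samples)
  prob <- vapply(grid, function(l) mean(l * d$de - d$dc > 0), 0)
  data.frame(threshold = grid, probability = prob)
}

#' Cost-effectiveness plane quadrant proportions
#'
#' Fractions of draws by sign of (dE, dC): NE (dE > 0, dC > 0), SE (dE > 0,
#' dC <= 0; intervention dominant), SW (dE <= 0, dC <= 0), NW (dE <= 0,
#' dC > 0; intervention dominated). Draws on an axis are assigned to the
#' non-positive side.
#'
#' @param samples A `psa_samples` object.
#' @return Named numeric vector `(ne, se, sw, nw)` summing to 1.
#' @export
ce_plane_quadrants <- function(samples) {
  d <- psa_deltas(samples)
  e_pos <- d$de > 0
  c_pos <- d$dc > 0
  c(ne = mean(e_pos & c_pos), se = mean(e_pos & !c_pos),
    sw = mean(!e_pos & !c_pos), nw = mean(!e_pos & c_pos))
}

#' Scenario sweeps over assay cost or high-risk prevalence
#'
#' Re-evaluates the incremental results across a grid of assay costs or
#' high-risk prevalences. In deterministic mode the pathways are run once at
#' mean parameters and re-mixed per scenario value (assay cost and
#' prevalence enter only through the mixing step). In PSA mode the per-draw
#' pathway outcomes of a single PSA run are re-mixed per value, keeping the
#' parameter draws common across scenarios.
#'
#' @param model A [cll_model()].
#' @param axis `"assay_cost"` or `"prevalence"`.
#' @param values Scenario values (costs >= 0 or prevalences in `[0, 1]`).
#' @param mode `"deterministic"` or `"psa"`.
#' @param n_iterations,seed,common_draws PSA settings (PSA mode only).
#' @return Data frame with one row per value: `value`, `delta_cost`,
#'   `delta_qalys`, `icer` (character: number or dominance label).
#' @export
scenario_sweep <- function(model, axis = c("assay_cost", "prevalence"),
                           values, mode = c("deterministic", "psa"),
                           n_iterations = 1000, seed = 1,
                           common_draws = TRUE) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  if (!length(values))
    return(data.frame(value = numeric(0), delta_cost = numeric(0),
                      delta_qalys = numeric(0), icer = character(0)))
  if (axis == "assay_cost") stopifnot(all(values >= 0))
  if (axis == "prevalence") stopifnot(all(values >= 0 & values <= 1))

  if (mode == "deterministic") {
    pw <- run_pathways(model)
    rows <- lapply(values, function(v) {
      a <- model$assay
      if (axis == "assay_cost") a$cost <- v else a$prevalence_high_risk <- v
      mixed <- mix_by_assay(a, pw$high, pw$low)
      dc <- mixed$cost - pw$high$cost
      de <- mixed$qalys - pw$high$qalys
      data.frame(value = v, delta_cost = dc, delta_qalys = de,
                 icer = format_icer(icer(dc, de)))
    })
    return(do.call(rbind, rows))
  }
  samples <- run_psa(model, n_iterations = n_iterations, seed = seed,
                     common_draws = common_draws)
  rows <- lapply(values, function(v) {
    pi_hr <- if (axis == "prevalence") v else
      attr(samples, "prevalence_high_risk")
    assay_cost <- if (axis == "assay_cost") {
      base <- model$assay$cost
      if (base > 0) samples$assay_cost_draw * (v / base) else v
    } else samples$assay_cost_draw
    ci <- pi_hr * samples$cost_high + (1 - pi_hr) * samples$cost_low +
      assay_cost
    qi <- pi_hr * samples$qaly_high + (1 - pi_hr) * samples$qaly_low
    dc <- mean(ci - samples$cost_comparator)
    de <- mean(qi - samples$qaly_comparator)
    data.frame(value = v, delta_cost = dc, delta_qalys = de,
               icer = format_icer(icer(dc, de)))
  })
  do.call(rbind, rows)
}

format_icer <- function(x) {
  if (is.character(x)) x else format(x, digits = 17)
}
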