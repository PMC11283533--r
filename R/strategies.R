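# Assembly of the two decision arms (assay-guided vs. standard of care) as
# expanded state spaces and time-dependent transition schedules.
#
# State construction per treatment line l: on_treatment_l, ae_minor_l,
# ae_major_l, and treatment_free_l when the line has a fixed duration;
# shared across lines: progression_post_3l (relapse after third line) and
# death. All per-cycle hazards are indexed by model time (clock-forward):
# each line's PFS/OS curve and fixed-duration completion are evaluated at
# the model cycle index, not time-in-state.

#' Specify a treatment line
#'
#' @param drug_label Regimen name.
#' @param cost_per_cycle Average drug cost per monthly cycle (CAD).
#' @param fixed_duration_cycles Number of cycles the regimen is given, or
#'   `NULL` for treat-to-progression regimens.
#' @param pfs_model,os_model `parametric_survival` models for the line's
#'   progression-free and overall survival.
#' @param p_minor_ae_per_cycle,p_major_ae_per_cycle Per-cycle probabilities
#'   of a minor (treatment continues) or major (treatment discontinued)
#'   adverse event.
#' @param ae_cost_minor,ae_cost_major One-cycle adverse-event management
#'   costs (CAD).
#' @return A `treatment_line` object.
#' @export
treatment_line <- function(drug_label, cost_per_cycle,
                           fixed_duration_cycles = NULL,
                           pfs_model, os_model,
                           p_minor_ae_per_cycle = 0,
                           p_major_ae_per_cycle = 0,
                           ae_cost_minor = 0, ae_cost_major = 0) {
  stopifnot(cost_per_cycle >= 0,
            inherits(pfs_model, "parametric_survival"),
            inherits(os_model, "parametric_survival"),
            p_minor_ae_per_cycle >= 0, p_minor_ae_per_cycle <= 1,
            p_major_ae_per_cycle >= 0, p_major_ae_per_cycle <= 1,
            ae_cost_minor >= 0, ae_cost_major >= 0)
  if (!is.null(fixed_duration_cycles))
    stopifnot(fixed_duration_cycles > 0)
  structure(list(drug_label = drug_label, cost_per_cycle = cost_per_cycle,
                 fixed_duration_cycles = fixed_duration_cycles,
                 pfs_model = pfs_model, os_model = os_model,
                 p_minor_ae_per_cycle = p_minor_ae_per_cycle,
                 p_major_ae_per_cycle = p_major_ae_per_cycle,
                 ae_cost_minor = ae_cost_minor,
                 ae_cost_major = ae_cost_major),
            class = "treatment_line")
}

#' Specify the risk-stratification assay
#'
#' Reference case: $1000 CAD, 50% of patients detected as high-risk, and a
#' perfectly accurate test (no false positives or negatives).
#'
#' @param cost Assay cost per patient (CAD).
#' @param prevalence_high_risk Fraction of patients stratified high-risk.
#' @param sensitivity,specificity Test accuracy; the base case fixes both at
#'   1 and misclassification pathways are rejected at run time otherwise.
#' @return An `assay_spec` object.
#' @export
assay_spec <- function(cost = 1000, prevalence_high_risk = 0.5,
                       sensitivity = 1, specificity = 1) {
  stopifnot(cost >= 0,
            prevalence_high_risk >= 0, prevalence_high_risk <= 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  structure(list(cost = cost, prevalence_high_risk = prevalence_high_risk,
                 sensitivity = sensitivity, specificity = specificity),
            class = "assay_spec")
}

#' Default health-state utilities
#'
#' Annual-equivalent utility weights by state: on-treatment by line, minor
#' and major adverse events, treatment-free interval, and relapse after
#' third-line progression.
#'
#' @return A named list of utilities.
#' @export
cll_default_utilities <- function() {
  list(on_treatment = c(0.78, 0.71, 0.65),
       ae_minor = 0.73, ae_major = 0.69,
       treatment_free = 0.91, relapse = 0.68)
}

#' Default utility standard deviations (for PSA beta sampling)
#'
#' @return A named list matching [cll_default_utilities()].
#' @export
cll_default_utility_sds <- function() {
  list(on_treatment = c(0.14, 0.17, 0.22),
       ae_minor = 0.17, ae_major = 0.18,
       treatment_free = 0.11, relapse = 0.2)
}

#' A three-line treatment-sequencing strategy arm
#'
#' @param label Arm name.
#' @param lines List of exactly three [treatment_line()] objects; third-line
#'   therapy is the same regimen in all pathways.
#' @param assay An [assay_spec()] or `NULL` (comparator).
#' @param utilities Named list as from [cll_default_utilities()].
#' @return A `strategy_arm` object.
#' @export
strategy_arm <- function(label, lines, assay = NULL,
                         utilities = cll_default_utilities()) {
  stopifnot(is.list(lines), length(lines) == 3,
            all(vapply(lines, inherits, TRUE, "treatment_line")))
  if (!is.null(assay)) stopifnot(inherits(assay, "assay_spec"))
  stopifnot(length(utilities$on_treatment) == 3)
  structure(list(label = label, lines = lines, assay = assay,
                 utilities = utilities),
            class = "strategy_arm")
}

#' Expand a strategy arm into its health-state list
#'
#' Per line: on-treatment, minor-AE and major-AE states, plus a
#' treatment-free state for fixed-duration regimens; shared: a post-third-
#' line progression (relapse) state and an absorbing death state. Utilities
#' are attached by state kind and line.
#'
#' @param arm A [strategy_arm()].
#' @return A list of [health_state()] objects (ordered).
#' @export
expand_states <- function(arm) {
  stopifnot(inherits(arm, "strategy_arm"))
  u <- arm$utilities
  states <- list()
  for (l in 1:3) {
    ln <- arm$lines[[l]]
    states <- c(states, list(
      health_state(paste0("on_treatment_", l), u$on_treatment[l],
                   ln$cost_per_cycle, line_tag = l),
      health_state(paste0("ae_minor_", l), u$ae_minor, ln$ae_cost_minor,
                   line_tag = l),
      health_state(paste0("ae_major_", l), u$ae_major, ln$ae_cost_major,
                   line_tag = l)))
    if (!is.null(ln$fixed_duration_cycles))
      states <- c(states, list(
        health_state(paste0("treatment_free_", l), u$treatment_free, 0,
                     line_tag = l)))
  }
  c(states, list(
    health_state("progression_post_3l", u$relapse, 0),
    health_state("death", 0, 0, absorbing = TRUE)))
}

#' Build the per-cycle transition schedule for a strategy arm
#'
#' From each on-treatment state, per cycle: death per the line's OS model,
#' progression (PFS net of death) to the next line's on-treatment state (or
#' to post-third-line progression from line 3), minor AE (one-cycle
#' excursion, returning), major AE (one-cycle state, then next line), and
#' residual stay. For fixed-duration lines, once model time reaches the
#' duration the residual flows to the treatment-free state, where the line's
#' PFS clock continues (progression moves to the next line) and drug cost
#' stops. After third-line progression the cohort occupies the relapse state
#' until death per the third-line OS model.
#'
#' @param arm A [strategy_arm()].
#' @param config A [model_config()].
#' @return A [transition_schedule()] with `config$n_cycles` matrices.
#' @export
build_arm_schedule <- function(arm, config) {
  stopifnot(inherits(arm, "strategy_arm"), inherits(config, "model_config"))
  states <- expand_states(arm)
  nm <- vapply(states, `[[`, "", "name")
  idx <- stats::setNames(seq_along(nm), nm)
  n <- length(nm)
  nc <- config$n_cycles
  dl <- config$cycle_length

  # per-line hazard schedules over model time
  haz <- lapply(arm$lines, function(ln)
    pfs_os_decompose(ln$pfs_model, ln$os_model, 0:(nc - 1), dl))

  next_on <- function(l) if (l < 3) idx[[paste0("on_treatment_", l + 1)]]
                         else idx[["progression_post_3l"]]

  matrices <- vector("list", nc)
  for (t in 0:(nc - 1)) {
    M <- matrix(0, n, n, dimnames = list(nm, nm))
    for (l in 1:3) {
      ln <- arm$lines[[l]]
      pd <- haz[[l]]$p_death[t + 1]
      pp <- haz[[l]]$p_progression[t + 1]
      pmi <- ln$p_minor_ae_per_cycle
      pma <- ln$p_major_ae_per_cycle
      tot <- pd + pp + pmi + pma
      if (tot > 1 + 1e-12)
        stop("competing per-cycle probabilities sum to ", format(tot),
             " (> 1) on line ", l, " at cycle ", t)
      tot <- min(tot, 1)
      i_on <- idx[[paste0("on_treatment_", l)]]
      tf_name <- paste0("treatment_free_", l)
      has_tf <- !is.null(ln$fixed_duration_cycles)
      # residual destination: stay on treatment, unless the fixed duration
      # completes at or before the end of this cycle (model-time clock)
      resid_dest <- if (has_tf && (t + 1) >= ln$fixed_duration_cycles)
        idx[[tf_name]] else i_on
      M[i_on, idx[["death"]]] <- pd
      M[i_on, next_on(l)] <- M[i_on, next_on(l)] + pp
      M[i_on, idx[[paste0("ae_minor_", l)]]] <- pmi
      M[i_on, idx[[paste0("ae_major_", l)]]] <- pma
      M[i_on, resid_dest] <- M[i_on, resid_dest] + (1 - tot)
      # minor AE: one-cycle excursion, return to the line (or its
      # treatment-free state if the fixed duration has completed)
      i_mi <- idx[[paste0("ae_minor_", l)]]
      M[i_mi, idx[["death"]]] <- pd
      M[i_mi, resid_dest] <- M[i_mi, resid_dest] + (1 - pd)
      # major AE: one-cycle state, then discontinue to the next line
      i_ma <- idx[[paste0("ae_major_", l)]]
      M[i_ma, idx[["death"]]] <- pd
      M[i_ma, next_on(l)] <- M[i_ma, next_on(l)] + (1 - pd)
      if (has_tf) {
        i_tf <- idx[[tf_name]]
        M[i_tf, idx[["death"]]] <- pd
        M[i_tf, next_on(l)] <- M[i_tf, next_on(l)] + pp
        M[i_tf, i_tf] <- M[i_tf, i_tf] + (1 - pd - pp)
      }
    }
    i_rel <- idx[["progression_post_3l"]]
    pd3 <- haz[[3]]$p_death[t + 1]
    M[i_rel, idx[["death"]]] <- pd3
    M[i_rel, i_rel] <- 1 - pd3
    M[idx[["death"]], idx[["death"]]] <- 1
    matrices[[t + 1]] <- M
  }
  transition_schedule(states, matrices)
}

#' Run one strategy arm deterministically
#'
#' Starts the whole cohort on first-line treatment, runs the cohort through
#' the arm's schedule and accumulates discounted cost and QALYs. The assay
#' cost is not applied here (see [mix_by_assay()]).
#'
#' @param arm A [strategy_arm()].
#' @param config A [model_config()].
#' @param keep_trace Return the cohort trace as well.
#' @return List with `cost`, `qalys` and optionally `trace`/`schedule`.
#' @export
run_arm <- function(arm, config, keep_trace = FALSE) {
  schedule <- build_arm_schedule(arm, config)
  init <- numeric(length(schedule$states))
  init[match("on_treatment_1", schedule$state_names)] <- 1
  trace <- run_cohort(init, schedule, config)
  out <- accumulate_outcomes(trace, schedule, config)
  res <- list(cost = out$total_cost, qalys = out$total_qalys)
  if (keep_trace) {
    res$trace <- trace
    res$schedule <- schedule
  }
  res
}

#' Mix pathway outcomes by assay stratification
#'
#' Population-weighted mean of high- and low-risk pathway outcomes, weighted
#' by the high-risk prevalence, with the assay cost added once per patient
#' (applied at cycle 0, undiscounted).
#'
#' @param assay An [assay_spec()]; base case requires sensitivity and
#'   specificity of 1 (misclassification outcomes are out of scope).
#' @param high_outcomes,low_outcomes Lists with `cost` and `qalys` computed
#'   under an identical [model_config()].
#' @return List with mixed `cost` and `qalys`.
#' @export
mix_by_assay <- function(assay, high_outcomes, low_outcomes) {
  stopifnot(inherits(assay, "assay_spec"))
  if (assay$sensitivity != 1 || assay$specificity != 1)
    stop("misclassification pathways not supplied: base case requires ",
         "sensitivity = specificity = 1")
  pi_hr <- assay$prevalence_high_risk
  list(cost = pi_hr * high_outcomes$cost +
         (1 - pi_hr) * low_outcomes$cost + assay$cost,
       qalys = pi_hr * high_outcomes$qalys +
         (1 - pi_hr) * low_outcomes$qalys)
}
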