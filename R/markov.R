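# Generic discrete-time cohort Markov engine: time-dependent transitions,
# per-cycle and one-time costs, utilities, discounting.

#' Define a health state
#'
#' @param name State identifier.
#' @param utility Annual-equivalent utility weight in `[0, 1]`.
#' @param cost_per_cycle Cost accrued per cycle of occupancy (CAD, >= 0).
#' @param absorbing Logical; absorbing states (death) must carry utility 0
#'   and cost 0.
#' @param line_tag Treatment line (1-3) the state belongs to, or `NA`.
#' @return A `health_state` object.
#' @export
health_state <- function(name, utility, cost_per_cycle = 0,
                         absorbing = FALSE, line_tag = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1,
            utility >= 0, utility <= 1, cost_per_cycle >= 0)
  if (absorbing && (utility != 0 || cost_per_cycle != 0))
    stop("absorbing state must have utility 0 and cost 0")
  structure(list(name = name, utility = utility,
                 cost_per_cycle = cost_per_cycle, absorbing = absorbing,
                 line_tag = as.integer(line_tag)),
            class = "health_state")
}

#' Time-dependent transition schedule
#'
#' Bundles an ordered state list with one row-stochastic transition matrix
#' per cycle. Validates that every row sums to 1 within 1e-12, all entries
#' lie in `[0, 1]`, and absorbing states have identity rows.
#'
#' @param states List of [health_state()] objects.
#' @param matrices List of n_states x n_states matrices, one per cycle.
#' @return A `transition_schedule` object.
#' @export
transition_schedule <- function(states, matrices) {
  stopifnot(is.list(states), length(states) >= 1,
            all(vapply(states, inherits, TRUE, "health_state")),
            is.list(matrices), length(matrices) >= 1)
  n <- length(states)
  nm <- vapply(states, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate state names")
  absorbing <- vapply(states, `[[`, TRUE, "absorbing")
  for (cyc in seq_along(matrices)) {
    M <- matrices[[cyc]]
    if (!is.matrix(M) || any(dim(M) != n))
      stop("cycle ", cyc - 1, ": matrix dimension mismatch")
    if (any(M < -1e-15 | M > 1 + 1e-15))
      stop("cycle ", cyc - 1, ": entries outside [0, 1]")
    rs <- rowSums(M)
    bad <- which(abs(rs - 1) > 1e-12)
    if (length(bad))
      stop("cycle ", cyc - 1, ": non-stochastic row for state '",
           nm[bad[1]], "' (sum = ", format(rs[bad[1]], digits = 15), ")")
    for (i in which(absorbing)) {
      if (M[i, i] != 1 || any(M[i, -i] != 0))
        stop("cycle ", cyc - 1, ": absorbing state '", nm[i],
             "' row is not identity")
    }
  }
  structure(list(states = states, matrices = matrices, state_names = nm),
            class = "transition_schedule")
}

#' Model run configuration
#'
#' Reference case: 120 monthly cycles (10-year horizon), annual discount
#' rate 1.5%, no half-cycle correction.
#'
#' @param n_cycles Number of cycles (default 120).
#' @param cycle_length Cycle length in months (default 1).
#' @param discount_rate_annual Annual discount rate (default 0.015).
#' @param half_cycle_correction Average start/end-of-cycle occupancy when
#'   accruing outcomes (default `FALSE`).
#' @return A `model_config` object.
#' @export
model_config <- function(n_cycles = 120L, cycle_length = 1,
                         discount_rate_annual = 0.015,
                         half_cycle_correction = FALSE) {
  stopifnot(n_cycles >= 1, cycle_length > 0, discount_rate_annual >= 0)
  structure(list(n_cycles = as.integer(n_cycles),
                 cycle_length = cycle_length,
                 discount_rate_annual = discount_rate_annual,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "model_config")
}

#' Per-cycle discount factor
#'
#' Annual discrete rate applied with fractional monthly exponents:
#' \eqn{(1 + r)^{-t/12}} with t the elapsed months at cycle start.
#'
#' @param cycle_index Zero-based cycle index (vectorized).
#' @param config A [model_config()].
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, config) {
  stopifnot(all(cycle_index >= 0))
  t_months <- cycle_index * config$cycle_length
  (1 + config$discount_rate_annual)^(-t_months / 12)
}

#' Run the cohort through a transition schedule
#'
#' @param initial_distribution Occupancy fractions per state, summing to 1.
#' @param schedule A [transition_schedule()].
#' @param config A [model_config()]; `schedule` must provide at least
#'   `n_cycles` matrices.
#' @return A `cohort_trace`: an `(n_cycles + 1) x n_states` matrix of
#'   occupancy fractions, rows indexed by cycle 0..n_cycles.
#' @export
run_cohort <- function(initial_distribution, schedule, config) {
  stopifnot(inherits(schedule, "transition_schedule"),
            inherits(config, "model_config"))
  n <- length(schedule$states)
  stopifnot(length(initial_distribution) == n)
  if (abs(sum(initial_distribution) - 1) > 1e-12)
    stop("initial distribution must sum to 1")
  if (length(schedule$matrices) < config$n_cycles)
    stop("schedule shorter than n_cycles")
  trace <- matrix(0, config$n_cycles + 1, n,
                  dimnames = list(NULL, schedule$state_names))
  occ <- as.numeric(initial_distribution)
  trace[1, ] <- occ
  for (cyc in seq_len(config$n_cycles)) {
    occ <- as.numeric(occ %*% schedule$matrices[[cyc]])
    trace[cyc + 1, ] <- occ
  }
  class(trace) <- c("cohort_trace", class(trace))
  trace
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Per cycle, cost adds occupancy x state cost x discount factor; QALYs add
#' occupancy x utility x (cycle length / 12) x discount factor, treating
#' utilities as annual-equivalent weights. Start-of-cycle occupancy is used
#' unless `half_cycle_correction` averages start and end of cycle. One-time
#' costs are discounted at their cycle's factor (cycle 0 is undiscounted).
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param schedule The [transition_schedule()] that produced it.
#' @param config A [model_config()].
#' @param one_time_costs Optional data frame or list of `(cycle, amount)`
#'   pairs; cycles must not exceed the horizon.
#' @return A list with `total_cost` (CAD) and `total_qalys`.
#' @export
accumulate_outcomes <- function(trace, schedule, config,
                                one_time_costs = NULL) {
  n_states <- length(schedule$states)
  stopifnot(ncol(trace) == n_states,
            nrow(trace) >= config$n_cycles + 1)
  nc <- config$n_cycles
  occ <- trace[seq_len(nc), , drop = FALSE]
  if (config$half_cycle_correction)
    occ <- (occ + trace[seq_len(nc) + 1, , drop = FALSE]) / 2
  costs <- vapply(schedule$states, `[[`, 0, "cost_per_cycle")
  utils_ <- vapply(schedule$states, `[[`, 0, "utility")
  df <- discount_factor(0:(nc - 1), config)
  total_cost <- sum((occ %*% costs) * df)
  total_qalys <- sum((occ %*% utils_) * df) * config$cycle_length / 12
  if (!is.null(one_time_costs)) {
    otc <- as.data.frame(one_time_costs)
    names(otc) <- c("cycle", "amount")[seq_along(otc)]
    if (any(otc$cycle > nc))
      stop("one-time cost scheduled beyond the model horizon")
    total_cost <- total_cost +
      sum(otc$amount * discount_factor(otc$cycle, config))
  }
  list(total_cost = total_cost, total_qalys = total_qalys)
}

#' Export a cohort trace as a long data frame
#'
#' One row per (cycle, state) with occupancy plus that cycle's discounted
#' cost and QALY contribution, suitable for CSV export.
#'
#' @param trace A `cohort_trace`.
#' @param schedule Matching [transition_schedule()].
#' @param config A [model_config()].
#' @return A data frame with columns `cycle`, `state`, `occupancy`,
#'   `discounted_cost`, `discounted_qaly`.
#' @export
trace_ledger <- function(trace, schedule, config) {
  nc <- config$n_cycles
  costs <- vapply(schedule$states, `[[`, 0, "cost_per_cycle")
  utils_ <- vapply(schedule$states, `[[`, 0, "utility")
  df <- discount_factor(0:(nc - 1), config)
  occ <- trace[seq_len(nc), , drop = FALSE]
  if (config$half_cycle_correction)
    occ <- (occ + trace[seq_len(nc) + 1, , drop = FALSE]) / 2
  data.frame(
    cycle = rep(0:(nc - 1), times = ncol(trace)),
    state = rep(schedule$state_names, each = nc),
    occupancy = as.vector(occ),
    discounted_cost = as.vector(sweep(occ * df, 2, costs, `*`)),
    discounted_qaly = as.vector(sweep(occ * df, 2, utils_, `*`) *
                                  config$cycle_length / 12)
  )
}
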