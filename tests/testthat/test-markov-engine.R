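# Cohort engine: conservation, absorbing monotonicity, discounting and
# outcome accrual.

two_state_schedule <- function(p, n_cycles) {
  states <- list(health_state("alive", 0.9, 100),
                 health_state("dead", 0, 0, absorbing = TRUE))
  M <- matrix(c(1 - p, p, 0, 1), 2, 2, byrow = TRUE)
  transition_schedule(states, rep(list(M), n_cycles))
}

test_that("identity matrices leave the occupancy unchanged", {
  states <- list(health_state("a", 0.5), health_state("b", 0.7),
                 health_state("dead", 0, 0, absorbing = TRUE))
  sched <- transition_schedule(states, rep(list(diag(3)), 24))
  tr <- run_cohort(c(0.3, 0.5, 0.2), sched, model_config(n_cycles = 24))
  expect_true(all(apply(tr, 1, function(r)
    isTRUE(all.equal(unname(r), c(0.3, 0.5, 0.2), tolerance = 1e-15)))))
})

test_that("constant death probability gives geometric survival", {
  cfg <- model_config(n_cycles = 60)
  tr <- run_cohort(c(1, 0), two_state_schedule(0.1, 60), cfg)
  expect_equal(tr[, "alive"], 0.9^(0:60), tolerance = 1e-12)
})

test_that("mass is conserved and absorbing occupancy is monotone", {
  m <- test_model()
  arms <- cll_strategy_arms(m)
  for (arm in arms) {
    sched <- build_arm_schedule(arm, m$config)
    init <- as.numeric(sched$state_names == "on_treatment_1")
    tr <- run_cohort(init, sched, m$config)
    expect_true(all(abs(rowSums(tr) - 1) <= 1e-12))
    expect_true(all(diff(tr[, "death"]) >= -1e-15))
  }
})

test_that("with death hazard bounded below, death occupancy approaches 1", {
  cfg <- model_config(n_cycles = 300)
  tr <- run_cohort(c(1, 0), two_state_schedule(0.05, 300), cfg)
  expect_gt(tr[301, "dead"], 1 - 0.95^300 - 1e-12)
  expect_lt(1 - tr[301, "dead"], 1e-6)
})

test_that("invalid schedules and initial distributions are rejected", {
  states <- list(health_state("a", 0.5),
                 health_state("dead", 0, 0, absorbing = TRUE))
  bad <- matrix(c(0.8, 0.1, 0, 1), 2, 2, byrow = TRUE)
  expect_error(transition_schedule(states, list(bad)),
               "non-stochastic row for state 'a'")
  bad_abs <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  expect_error(transition_schedule(states, list(bad_abs)),
               "not identity")
  ok <- transition_schedule(states,
                            list(matrix(c(0.9, 0.1, 0, 1), 2, 2,
                                        byrow = TRUE)))
  expect_error(run_cohort(c(0.5, 0.4), ok, model_config(n_cycles = 1)),
               "sum to 1")
})

test_that("discount factors follow the annual rate with monthly exponents", {
  cfg <- model_config()
  expect_equal(discount_factor(0, cfg), 1)
  expect_equal(discount_factor(12, cfg), 1 / 1.015)
  expect_equal(discount_factor(120, cfg), 1.015^(-10))
  # monotone non-increasing in the rate
  r_grid <- c(0, 0.005, 0.015, 0.03, 0.05)
  f <- vapply(r_grid, function(r)
    discount_factor(60, model_config(discount_rate_annual = r)), 0)
  expect_true(all(diff(f) < 0))
})

test_that("outcome accrual matches closed forms", {
  states <- list(health_state("tfi", 0.91, 0),
                 health_state("dead", 0, 0, absorbing = TRUE))
  sched <- transition_schedule(states, rep(list(diag(2)), 120))
  init <- c(1, 0)
  # zero utilities and costs -> (0, 0)
  states0 <- list(health_state("a", 0, 0),
                  health_state("dead", 0, 0, absorbing = TRUE))
  sched0 <- transition_schedule(states0, rep(list(diag(2)), 120))
  cfg0 <- model_config(discount_rate_annual = 0)
  tr <- run_cohort(init, sched0, cfg0)
  out0 <- accumulate_outcomes(tr, sched0, cfg0)
  expect_equal(out0$total_cost, 0)
  expect_equal(out0$total_qalys, 0)
  # fixed state, utility 0.91, 120 undiscounted monthly cycles -> 9.1 QALYs
  tr <- run_cohort(init, sched, cfg0)
  expect_equal(accumulate_outcomes(tr, sched, cfg0)$total_qalys, 9.1,
               tolerance = 1e-12)
  # discounted at 1.5%: geometric series closed form
  cfg <- model_config()
  q <- accumulate_outcomes(run_cohort(init, sched, cfg), sched, cfg)$total_qalys
  ratio <- 1.015^(-1 / 12)
  closed <- 0.91 / 12 * (1 - ratio^120) / (1 - ratio)
  expect_equal(q, closed, tolerance = 1e-12)
  expect_equal(q, 8.46, tolerance = 0.005)
})

test_that("discounted totals are monotone non-increasing in the rate", {
  m <- test_model()
  arm <- cll_strategy_arms(m)$high
  res <- lapply(c(0, 0.015, 0.05), function(r) {
    cfg <- model_config(discount_rate_annual = r)
    run_arm(arm, cfg)
  })
  expect_true(all(diff(vapply(res, `[[`, 0, "cost")) < 0))
  expect_true(all(diff(vapply(res, `[[`, 0, "qalys")) < 0))
})

test_that("one-time costs are discounted at their cycle; beyond horizon rejected", {
  sched <- two_state_schedule(0, 12)
  cfg <- model_config(n_cycles = 12)
  tr <- run_cohort(c(1, 0), sched, cfg)
  base <- accumulate_outcomes(tr, sched, cfg)
  with_otc <- accumulate_outcomes(tr, sched, cfg,
                                  one_time_costs = data.frame(
                                    cycle = c(0, 12), amount = c(1000, 1200)))
  expect_equal(with_otc$total_cost - base$total_cost,
               1000 + 1200 * 1.015^(-1), tolerance = 1e-12)
  expect_error(
    accumulate_outcomes(tr, sched, cfg,
                        one_time_costs = data.frame(cycle = 13, amount = 1)),
    "beyond the model horizon")
})

test_that("cohort trace matches a seeded microsimulation of the same chain", {
  m <- test_model()
  arm <- cll_strategy_arms(m)$high
  sched <- build_arm_schedule(arm, m$config)
  init <- as.numeric(sched$state_names == "on_treatment_1")
  trace <- run_cohort(init, sched, m$config)
  N <- 50000
  micro <- microsim_trace(sched, init * N, m$config$n_cycles, seed = 11)
  expect_microsim_agrees(trace, micro, N)
})

test_that("half-cycle correction averages adjacent occupancies", {
  sched <- two_state_schedule(0.1, 24)
  cfg_off <- model_config(n_cycles = 24, discount_rate_annual = 0)
  cfg_on <- model_config(n_cycles = 24, discount_rate_annual = 0,
                         half_cycle_correction = TRUE)
  tr <- run_cohort(c(1, 0), sched, cfg_off)
  q_off <- accumulate_outcomes(tr, sched, cfg_off)$total_qalys
  q_on <- accumulate_outcomes(tr, sched, cfg_on)$total_qalys
  expected <- 0.9 / 12 * sum((0.9^(0:23) + 0.9^(1:24)) / 2)
  expect_equal(q_on, expected, tolerance = 1e-12)
  expect_lt(q_on, q_off) # declining cohort: HCC trims the overcount
})
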