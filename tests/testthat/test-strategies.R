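# Strategy-arm construction: state expansion, schedule building, assay
# mixing.

flat_line <- function(label, cost = 1000, duration = NULL,
                      pfs = weibull_survival(1, 1 / 0.08),
                      os = weibull_survival(1, 1 / 0.02),
                      p_minor = 0, p_major = 0) {
  treatment_line(label, cost, duration, pfs, os,
                 p_minor_ae_per_cycle = p_minor,
                 p_major_ae_per_cycle = p_major,
                 ae_cost_minor = 500, ae_cost_major = 5000)
}

test_that("state expansion follows the construction rule", {
  # high-risk pathway: only the 24-cycle second line has a fixed duration
  arm <- strategy_arm("high", list(
    flat_line("acalabrutinib"),
    flat_line("venetoclax_rituximab", duration = 24),
    flat_line("idelalisib_rituximab")), assay = assay_spec())
  states <- expand_states(arm)
  nm <- vapply(states, `[[`, "", "name")
  expect_length(states, 12) # 3 on-treatment + 6 AE + 1 TFI + relapse + death
  expect_setequal(nm, c(paste0("on_treatment_", 1:3),
                        paste0("ae_minor_", 1:3), paste0("ae_major_", 1:3),
                        "treatment_free_2", "progression_post_3l", "death"))
  # utilities attached by state kind and line
  u <- setNames(vapply(states, `[[`, 0, "utility"), nm)
  expect_equal(unname(u[paste0("on_treatment_", 1:3)]), c(0.78, 0.71, 0.65))
  expect_equal(unname(u["ae_minor_1"]), 0.73)
  expect_equal(unname(u["ae_major_2"]), 0.69)
  expect_equal(unname(u["treatment_free_2"]), 0.91)
  expect_equal(unname(u["progression_post_3l"]), 0.68)
  # no fixed durations -> no treatment-free states
  arm2 <- strategy_arm("nofix", list(flat_line("a"), flat_line("b"),
                                     flat_line("c")))
  nm2 <- vapply(expand_states(arm2), `[[`, "", "name")
  expect_false(any(grepl("treatment_free", nm2)))
  expect_length(nm2, 11)
  # exactly one absorbing state
  expect_equal(sum(vapply(expand_states(arm), `[[`, TRUE, "absorbing")), 1)
})

test_that("AE-free, duration-free arm reduces to a progression/death chain", {
  arm <- strategy_arm("plain", list(flat_line("a"), flat_line("b"),
                                    flat_line("c")))
  cfg <- model_config(n_cycles = 60)
  sched <- build_arm_schedule(arm, cfg)
  for (M in sched$matrices) {
    expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 0)
    # AE columns never receive mass
    expect_true(all(M[, grepl("ae_", colnames(M))] == 0))
  }
})

test_that("fixed duration with zero hazard parks the cohort treatment-free", {
  no_event <- weibull_survival(1, 1e15)
  arm <- strategy_arm("tfi", list(
    treatment_line("ven_obi", 10400, 12, no_event, no_event),
    flat_line("b"), flat_line("c")))
  cfg <- model_config(n_cycles = 36)
  sched <- build_arm_schedule(arm, cfg)
  init <- as.numeric(sched$state_names == "on_treatment_1")
  tr <- run_cohort(init, sched, cfg)
  i_tf <- which(sched$state_names == "treatment_free_1")
  expect_true(all(tr[1:12, i_tf] == 0))
  expect_true(all(abs(tr[13:37, i_tf] - 1) < 1e-12))
})

test_that("all generated schedules are valid over the full horizon", {
  m <- test_model()
  arms <- cll_strategy_arms(m)
  for (arm in arms) {
    sched <- build_arm_schedule(arm, m$config)
    expect_length(sched$matrices, 120)
    for (M in sched$matrices) {
      expect_true(all(M >= 0 & M <= 1))
      expect_true(all(abs(rowSums(M) - 1) <= 1e-12))
    }
  }
})

test_that("competing probabilities above one are rejected with the cycle", {
  fast <- weibull_survival(3, 8) # hazard explodes within the horizon
  arm <- strategy_arm("bad", list(
    flat_line("a", pfs = fast, os = fast, p_minor = 0.5, p_major = 0.4),
    flat_line("b"), flat_line("c")))
  expect_error(build_arm_schedule(arm, model_config(n_cycles = 60)),
               "sum to .* at cycle")
})

test_that("schedule occupancies match the microsimulation oracle", {
  # exponential hazards on all lines
  arm <- strategy_arm("exp", list(
    flat_line("a", pfs = weibull_survival(1, 1 / 0.06),
              os = weibull_survival(1, 1 / 0.015),
              p_minor = 0.02, p_major = 0.005),
    flat_line("b", duration = 24, pfs = weibull_survival(1, 1 / 0.08),
              os = weibull_survival(1, 1 / 0.02)),
    flat_line("c", pfs = weibull_survival(1, 1 / 0.1),
              os = weibull_survival(1, 1 / 0.03))))
  cfg <- model_config(n_cycles = 120)
  sched <- build_arm_schedule(arm, cfg)
  init <- as.numeric(sched$state_names == "on_treatment_1")
  tr <- run_cohort(init, sched, cfg)
  N <- 50000
  micro <- microsim_trace(sched, init * N, cfg$n_cycles, seed = 5)
  expect_microsim_agrees(tr, micro, N)
})

test_that("assay mixing is the population-weighted mean plus assay cost", {
  high <- list(cost = 150000, qalys = 1.8)
  low <- list(cost = 160000, qalys = 2.3)
  mixed <- mix_by_assay(assay_spec(cost = 1000, prevalence_high_risk = 0.5),
                        high, low)
  expect_equal(mixed$cost, 156000)
  expect_equal(mixed$qalys, 2.05)
  all_high <- mix_by_assay(assay_spec(1000, 1), high, low)
  expect_equal(all_high$cost, high$cost + 1000)
  expect_equal(all_high$qalys, high$qalys)
  all_low <- mix_by_assay(assay_spec(1000, 0), high, low)
  expect_equal(all_low$cost, low$cost + 1000)
  expect_equal(all_low$qalys, low$qalys)
  expect_error(mix_by_assay(assay_spec(1000, 0.5, sensitivity = 0.9),
                            high, low), "misclassification")
})

test_that("comparator arm equals the high-risk pathway without the assay", {
  m <- test_model()
  arms <- cll_strategy_arms(m)
  expect_null(arms$comparator$assay)
  h <- run_arm(arms$high, m$config)
  c_ <- run_arm(arms$comparator, m$config)
  expect_identical(h$cost, c_$cost)
  expect_identical(h$qalys, c_$qalys)
  # with prevalence 1, the arms differ by exactly the assay cost
  m1 <- m
  m1$assay$prevalence_high_risk <- 1
  res <- evaluate_deterministic(m1)
  expect_identical(res$delta_qalys, 0)
  expect_equal(res$delta_cost, m1$assay$cost, tolerance = 1e-9)
})
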