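# Independent oracles and shared fixtures for the test suite.

# One fixture bundle per session, generated in code (seed fixed a priori).
test_bundle_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "cllcea-test-bundle")
      suppressWarnings(suppressMessages(
        cmd_make_fixtures(seed = 2021, out_dir = dir, force = TRUE)))
    }
    dir
  }
})

test_model <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- suppressWarnings(load_model_from_bundle(test_bundle_dir()))
    m
  }
})

# First-order microsimulation of a transition schedule: every subject
# follows the chain independently, so per-state counts evolve as chained
# multinomials (the sufficient statistic of an individual-level simulation).
microsim_trace <- function(schedule, initial_counts, n_cycles, seed) {
  set.seed(seed)
  n <- length(schedule$states)
  counts <- initial_counts
  N <- sum(counts)
  tr <- matrix(0, n_cycles + 1, n)
  tr[1, ] <- counts / N
  for (t in seq_len(n_cycles)) {
    M <- schedule$matrices[[t]]
    new <- numeric(n)
    for (s in which(counts > 0))
      new <- new + as.numeric(stats::rmultinom(1, counts[s], M[s, ]))
    counts <- new
    tr[t + 1, ] <- counts / N
  }
  tr
}

# Equivalence check between an exact cohort trace and the microsimulation.
# Marginally each cell is Binomial(N, p)/N, so the per-cell Monte-Carlo SE
# is sqrt(p(1-p)/N). With ~1400 simultaneous cells a few |Z| > 3 are
# expected from an exact trace, so the check is multiplicity-aware: at
# least 99.5% of well-populated cells within 3 SE, every cell within 5 SE,
# and sparse cells (expected count < 5) within a 30-count bound.
expect_microsim_agrees <- function(trace, micro, n_subjects) {
  p <- unclass(trace)
  se <- sqrt(p * (1 - p) / n_subjects)
  normal <- n_subjects * pmin(p, 1 - p) >= 5
  z <- abs(micro - p) / ifelse(se > 0, se, 1)
  expect_gte(mean(z[normal] <= 3), 0.995)
  expect_lt(max(z[normal]), 5)
  expect_true(all(abs(micro - p)[!normal] * n_subjects <= 30))
}

# Brute-force grid-search Weibull fit minimizing sum-of-squared survival
# error, independent of the cloglog-OLS path.
grid_fit_weibull <- function(points, shapes = seq(0.5, 3, by = 0.005),
                             scales = seq(5, 80, by = 0.05)) {
  best <- c(NA, NA)
  best_sse <- Inf
  for (k in shapes) {
    S <- outer(points$time_months, scales, function(t, l) exp(-(t / l)^k))
    sse <- colSums((S - points$survival)^2)
    j <- which.min(sse)
    if (sse[j] < best_sse) {
      best_sse <- sse[j]
      best <- c(k, scales[j])
    }
  }
  list(shape = best[1], scale = best[2], sse = best_sse)
}

# simulate -> KM -> digitize -> fit round trip for one seed
round_trip_fit <- function(shape, scale, n, seed, noise_sd = 0.01,
                           censor_rate = 0.005, admin = 48) {
  spec <- trial_sim_spec("PFS", shape, scale, n, censor_rate = censor_rate,
                         admin_censor_time = admin, seed = seed)
  km <- km_estimate(simulate_subjects(spec))
  grid <- seq(1, min(admin, floor(max(km$time_months))))
  dig <- digitize(km, grid, noise_sd = noise_sd, seed = seed + 10000L)
  suppressWarnings(fit_parametric(dig, "weibull"))
}

# tiny helper for psa_samples construction in unit tests
fake_psa_samples <- function(dc, de, base_cost = 100000, base_qaly = 2) {
  n <- length(dc)
  s <- data.frame(draw = seq_len(n),
                  cost_intervention = base_cost + dc,
                  qaly_intervention = base_qaly + de,
                  cost_comparator = rep(base_cost, n),
                  qaly_comparator = rep(base_qaly, n))
  class(s) <- c("psa_samples", "data.frame")
  s
}
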