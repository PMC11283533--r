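# Fitting digitized KM points and converting fits to per-cycle
# transition probabilities.

test_that("noise-free Weibull points are recovered to numerical precision", {
  tt <- 1:60
  pts <- km_points(tt, exp(-(tt / 24)^1.5))
  fit <- fit_parametric(pts, "weibull")
  expect_equal(fit$shape, 1.5, tolerance = 1e-6)
  expect_equal(fit$scale, 24, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # covariance is essentially zero for an exact fit
  expect_lt(max(abs(fit$coef_covariance)), 1e-12)
})

test_that("noise-free exponential points give the generating rate", {
  tt <- 1:60
  pts <- km_points(tt, exp(-0.05 * tt))
  fit <- fit_parametric(pts, "exponential")
  expect_equal(fit$shape, 1)
  expect_equal(fit$scale, 20, tolerance = 1e-9)
  expect_identical(fit$family, "exponential")
})

test_that("fit on synthetic digitized data agrees with a grid-search oracle", {
  spec <- trial_sim_spec("PFS", 1.3, 30, 200, censor_rate = 0.005,
                         admin_censor_time = 48, seed = 42)
  km <- km_estimate(simulate_subjects(spec))
  grid <- seq(1, min(48, floor(max(km$time_months))))
  dig <- digitize(km, grid, noise_sd = 0.01, seed = 43)
  fit <- fit_parametric(dig, "weibull")
  oracle <- grid_fit_weibull(dig)
  # two estimators of the same truth from the same noisy points: the OLS
  # fit must land inside a band around the SSE optimum
  expect_lt(abs(fit$shape - oracle$shape) / oracle$shape, 0.20)
  expect_lt(abs(fit$scale - oracle$scale) / oracle$scale, 0.10)
})

test_that("degenerate or invalid inputs are rejected or dropped", {
  expect_error(km_points(c(1, 2), c(0.5, 0.7)), "non-increasing")
  expect_error(km_points(c(2, 1), c(0.7, 0.5)), "strictly increasing")
  expect_error(km_points(1:3, c(1.1, 0.5, 0.4)), "\\[0, 1\\]")
  # survival values at exactly 0/1 are dropped with a warning
  pts <- km_points(c(1, 2, 3, 4, 5), c(1, 0.8, 0.6, 0.4, 0))
  expect_warning(fit <- fit_parametric(pts, "weibull"), "dropped")
  expect_equal(fit$n_points, 3L)
  # fewer than 3 usable points
  few <- km_points(c(1, 2, 3), c(1, 0.5, 0))
  expect_error(suppressWarnings(fit_parametric(few)), "insufficient data")
})

test_that("survival_at satisfies S(0)=1, monotonicity and closed forms", {
  m1 <- weibull_survival(1, 20)
  m2 <- weibull_survival(2, 10)
  expect_equal(survival_at(m1, 0), 1)
  expect_equal(survival_at(m2, 0), 1)
  expect_equal(survival_at(m1, 20), exp(-1))
  expect_equal(survival_at(m2, 10), exp(-1))
  tt <- seq(0, 100, by = 0.5)
  expect_true(all(diff(survival_at(weibull_survival(1.3, 30), tt)) <= 0))
  expect_error(survival_at(m1, -1), "non-negative")
})

test_that("per-cycle probabilities: memoryless exponential and rising Weibull hazard", {
  exp_m <- weibull_survival(1, 1 / 0.05)
  p <- per_cycle_event_prob(exp_m, 0:119)
  expect_equal(p, rep(1 - exp(-0.05), 120), tolerance = 1e-12)
  wb <- weibull_survival(1.5, 24)
  pw <- per_cycle_event_prob(wb, 0:119)
  expect_true(all(diff(pw) > 0)) # increasing hazard for k > 1
})

test_that("per-cycle schedule reproduces the survival curve exactly", {
  wb <- weibull_survival(1.3, 30)
  p <- per_cycle_event_prob(wb, 0:119, cycle_length = 1)
  # direct-evaluation oracle: cumulative survival from the schedule
  implied <- cumprod(1 - p)
  direct <- survival_at(wb, 1:120)
  expect_equal(implied, direct, tolerance = 1e-9)
  # and against an oracle on a non-unit cycle length
  p2 <- per_cycle_event_prob(wb, 0:59, cycle_length = 2)
  expect_equal(cumprod(1 - p2), survival_at(wb, seq(2, 120, 2)),
               tolerance = 1e-9)
})

test_that("discrete exponential sojourn converges to 1/rate as cycles shrink", {
  rate <- 0.05
  m <- weibull_survival(1, 1 / rate)
  sojourn <- function(dl) {
    p <- per_cycle_event_prob(m, 0, dl) # constant by memorylessness
    dl / p # mean of geometric sojourn in time units
  }
  expect_gt(sojourn(1), 1 / rate)
  expect_equal(sojourn(0.01), 1 / rate, tolerance = 1e-3)
  expect_lt(abs(sojourn(0.001) - 1 / rate), abs(sojourn(0.01) - 1 / rate))
})

test_that("PFS/OS decomposition splits competing events correctly", {
  pfs <- weibull_survival(1, 1 / 0.08)
  os <- weibull_survival(1, 1 / 0.02)
  d <- pfs_os_decompose(pfs, os, 0:119)
  expect_equal(d$p_death, rep(1 - exp(-0.02), 120), tolerance = 1e-12)
  expect_equal(d$p_progression,
               rep((1 - exp(-0.08)) - (1 - exp(-0.02)), 120),
               tolerance = 1e-12)
  expect_equal(d$p_death[1], 0.01980, tolerance = 1e-4)
  expect_equal(d$p_progression[1], 0.05708, tolerance = 1e-4)
  # identical PFS and OS: every event is a death
  d2 <- pfs_os_decompose(pfs, pfs, 0:59)
  expect_equal(d2$p_progression, rep(0, 60))
  # negligible death hazard: progression equals the PFS event probability
  no_death <- weibull_survival(1, 1e12)
  d3 <- pfs_os_decompose(pfs, no_death, 0:59)
  expect_equal(d3$p_progression, per_cycle_event_prob(pfs, 0:59),
               tolerance = 1e-9)
  expect_true(all(d$p_progression + d$p_death <= 1))
})

test_that("survival model round-trips through YAML serialization", {
  pts <- km_points(1:40, exp(-((1:40) / 24)^1.5) * 0.999)
  fit <- fit_parametric(pts, "weibull")
  path <- tempfile(fileext = ".yaml")
  write_survival_model(fit, path)
  back <- read_survival_model(path)
  expect_equal(back$shape, fit$shape, tolerance = 1e-10)
  expect_equal(back$scale, fit$scale, tolerance = 1e-10)
  expect_equal(back$coef_covariance, fit$coef_covariance, tolerance = 1e-6)
})

test_that("cross-check: cloglog OLS agrees with flexsurv on individual data", {
  skip_if_not_installed("flexsurv")
  spec <- trial_sim_spec("OS", 1.4, 36, 2000, censor_rate = 0.002,
                         admin_censor_time = 60, seed = 9)
  rec <- simulate_subjects(spec)
  fs <- flexsurv::flexsurvreg(
    survival::Surv(observed_time, event_flag) ~ 1, data = rec,
    dist = "weibull")
  km <- km_estimate(rec)
  grid <- seq(1, floor(max(km$time_months)))
  fit <- fit_parametric(digitize(km, grid, noise_sd = 0, seed = 1),
                        "weibull")
  expect_equal(fit$shape, unname(fs$res["shape", "est"]), tolerance = 0.05)
  expect_equal(fit$scale, unname(fs$res["scale", "est"]), tolerance = 0.05)
})
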