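# Probabilistic sensitivity analysis: moment-matched beta utilities,
# bounded uniform costs, multivariate-normal survival coefficients on the
# log scale; one full two-arm model evaluation per draw.

#' Moment-matched beta parameters
#'
#' Solves `alpha / (alpha + beta) = mean` and the beta variance equation for
#' `sd^2`, the standard parameterization of utility uncertainty in PSA.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @param label Parameter name used in error messages.
#' @return List with `alpha` and `beta`.
#' @export
beta_moment_match <- function(mean, sd, label = "utility") {
  stopifnot(mean > 0, mean < 1, sd >= 0)
  if (sd^2 >= mean * (1 - mean))
    stop("infeasible beta moments for ", label, ": sd^2 = ", sd^2,
         " >= mean(1-mean) = ", mean * (1 - mean))
  nu <- mean * (1 - mean) / sd^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

draw_seed <- function(seed, draw_index, attempt = 0, stream = 0) {
  h <- as.numeric(seed) %% 2147483629
  for (x in c(draw_index, attempt, stream))
    h <- (h * 31 + as.numeric(x) + 17) %% 2147483629
  as.integer(h)
}

sample_utility <- function(mean, sd) {
  if (sd == 0) return(mean)
  p <- beta_moment_match(mean, sd)
  stats::rbeta(1, p$alpha, p$beta)
}

sample_cost <- function(cost, pct) {
  if (pct == 0 || cost == 0) return(cost)
  stats::runif(1, max(0, cost * (1 - pct)), cost * (1 + pct))
}

sample_survival_model <- function(fit) {
  cv <- fit$coef_covariance
  if (is.null(cv) || all(cv == 0)) return(fit)
  lp <- MASS::mvrnorm(1, mu = c(log(fit$shape), log(fit$scale)), Sigma = cv)
  if (fit$family == "exponential") lp[1] <- 0
  weibull_survival(shape = exp(lp[1]), scale = exp(lp[2]),
                   family = fit$family)
}

#' Draw one sampled parameter set
#'
#' Utilities are drawn from moment-matched beta distributions; drug costs
#' uniformly within +/- `drug_pct` of the list price and the assay cost
#' within +/- `assay_pct`; survival log-parameters from a multivariate
#' normal around the fitted values using the fit covariance. The draw is
#' fully reproducible given `(seed, draw_index, attempt, stream)`.
#'
#' @param model A [cll_model()] holding the mean parameters.
#' @param seed Master seed.
#' @param draw_index Draw number (1-based).
#' @param attempt Resample attempt counter (0 for the first try).
#' @param stream Sampling stream; independent-arm sampling uses a distinct
#'   stream for the comparator.
#' @param vary Character subset of `c("utilities", "costs", "survival")`
#'   selecting which parameter blocks are sampled.
#' @return A `cll_model` with sampled parameters substituted.
#' @export
sample_parameters <- function(model, seed, draw_index, attempt = 0,
                              stream = 0,
                              vary = c("utilities", "costs", "survival")) {
  stopifnot(inherits(model, "cll_model"))
  set.seed(draw_seed(seed, draw_index, attempt, stream))
  m <- model
  if ("utilities" %in% vary) {
    u <- m$utilities; s <- m$utility_sds
    u$on_treatment <- vapply(1:3, function(i)
      sample_utility(m$utilities$on_treatment[i], s$on_treatment[i]), 0)
    for (k in c("ae_minor", "ae_major", "treatment_free", "relapse"))
      u[[k]] <- sample_utility(m$utilities[[k]], s[[k]])
    m$utilities <- u
  }
  if ("costs" %in% vary) {
    m$costs$cost_per_cycle <- vapply(m$costs$cost_per_cycle, sample_cost,
                                     0, pct = m$cost_variability$drug_pct)
    m$assay$cost <- sample_cost(m$assay$cost, m$cost_variability$assay_pct)
  }
  if ("survival" %in% vary)
    m$fits <- lapply(m$fits, function(f)
      list(pfs = sample_survival_model(f$pfs),
           os = sample_survival_model(f$os)))
  m
}

#' Strip all parameter variability from a model
#'
#' Sets every utility SD to zero, both cost variability percentages to zero
#' and all survival coefficient covariances to zero, so PSA draws are
#' degenerate at the mean parameter set.
#'
#' @param model A [cll_model()].
#' @return The model with all variability removed.
#' @export
zero_variability <- function(model) {
  stopifnot(inherits(model, "cll_model"))
  model$utility_sds <- list(on_treatment = c(0, 0, 0), ae_minor = 0,
                            ae_major = 0, treatment_free = 0, relapse = 0)
  model$cost_variability <- list(drug_pct = 0, assay_pct = 0)
  model$fits <- lapply(model$fits, function(f) {
    f$pfs$coef_covariance <- matrix(0, 2, 2)
    f$os$coef_covariance <- matrix(0, 2, 2)
    f
  })
  model
}

run_pathways <- function(model) {
  arms <- cll_strategy_arms(model)
  list(high = run_arm(arms$high, model$config),
       low = run_arm(arms$low, model$config))
}

#' Run the probabilistic sensitivity analysis
#'
#' One full two-arm model evaluation per draw. With common draws (the
#' default) both arms see the identical sampled parameter set, so the
#' comparator equals the sampled high-risk pathway; in independent mode the
#' comparator arm is evaluated under its own sampled parameters. Draws whose
#' sampled parameters produce an invalid (non-stochastic) schedule are
#' rejected, logged and resampled, capped at ten times `n_iterations`.
#'
#' @param model A [cll_model()].
#' @param n_iterations Number of PSA draws (reference 1000).
#' @param seed Master seed; identical `(seed, config)` reproduce the sample
#'   set bitwise.
#' @param common_draws Logical; sample one parameter set per draw shared by
#'   both arms (default) or independent sets per arm.
#' @param vary Parameter blocks to sample, see [sample_parameters()].
#' @return A `psa_samples` data frame with per-draw intervention and
#'   comparator costs and QALYs plus the underlying pathway outcomes and the
#'   sampled assay cost. Attributes: `seed`, `common_draws`, `n_rejected`,
#'   `wtp`, `prevalence_high_risk`.
#' @export
run_psa <- function(model, n_iterations = 1000, seed = 1,
                    common_draws = TRUE,
                    vary = c("utilities", "costs", "survival")) {
  stopifnot(inherits(model, "cll_model"), n_iterations >= 1)
  out <- vector("list", n_iterations)
  n_rejected <- 0L
  for (i in seq_len(n_iterations)) {
    row <- NULL
    for (attempt in 0:9) {
      res <- tryCatch({
        mi <- sample_parameters(model, seed, i, attempt, stream = 0,
                                vary = vary)
        pw <- run_pathways(mi)
        intervention <- mix_by_assay(mi$assay, pw$high, pw$low)
        comp <- if (common_draws) pw$high else {
          mc <- sample_parameters(model, seed, i, attempt, stream = 1,
                                  vary = vary)
          run_pathways(mc)$high
        }
        data.frame(draw = i,
                   cost_intervention = intervention$cost,
                   qaly_intervention = intervention$qalys,
                   cost_comparator = comp$cost,
                   qaly_comparator = comp$qalys,
                   cost_high = pw$high$cost, qaly_high = pw$high$qalys,
                   cost_low = pw$low$cost, qaly_low = pw$low$qalys,
                   assay_cost_draw = mi$assay$cost)
      }, error = function(e) e)
      if (!inherits(res, "error")) { row <- res; break }
      n_rejected <- n_rejected + 1L
      if (n_rejected > 10 * n_iterations)
        stop("PSA aborted: rejected draws exceeded 10x n_iterations; ",
             "last error: ", conditionMessage(res))
      message("draw ", i, " attempt ", attempt, " rejected: ",
              conditionMessage(res))
    }
    if (is.null(row))
      stop("draw ", i, " rejected on 10 consecutive attempts")
    out[[i]] <- row
  }
  samples <- do.call(rbind, out)
  attr(samples, "seed") <- seed
  attr(samples, "common_draws") <- common_draws
  attr(samples, "n_rejected") <- n_rejected
  attr(samples, "wtp") <- model$wtp
  attr(samples, "prevalence_high_risk") <- model$assay$prevalence_high_risk
  class(samples) <- c("psa_samples", "data.frame")
  samples
}

mean_ci <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  c(mean = m, sd = s, lower = m - 1.96 * s, upper = m + 1.96 * s)
}

#' Summarize a PSA sample set
#'
#' Means with 95% intervals computed as mean +/- 1.96 x sample standard
#' deviation (n - 1 denominator) for each arm's cost and QALYs and for the
#' increments, plus the ratio-of-means ICER, the net monetary benefit of the
#' mean increments, cost-effectiveness-plane quadrant proportions and the
#' probability of cost-effectiveness at the WTP threshold. Note the
#' intervals describe the sampled distribution (the stated formula), not the
#' standard error of the mean.
#'
#' @param samples A `psa_samples` object from [run_psa()].
#' @param wtp Willingness-to-pay threshold; defaults to the value carried by
#'   `samples`.
#' @return A list of class `psa_summary`.
#' @export
summarize_psa <- function(samples, wtp = attr(samples, "wtp") %||% 50000) {
  stopifnot(nrow(samples) >= 2)
  dc <- samples$cost_intervention - samples$cost_comparator
  de <- samples$qaly_intervention - samples$qaly_comparator
  stats_tab <- rbind(
    cost_intervention = mean_ci(samples$cost_intervention),
    qaly_intervention = mean_ci(samples$qaly_intervention),
    cost_comparator = mean_ci(samples$cost_comparator),
    qaly_comparator = mean_ci(samples$qaly_comparator),
    delta_cost = mean_ci(dc),
    delta_qalys = mean_ci(de),
    nmb = mean_ci(wtp * de - dc))
  structure(list(
    n = nrow(samples),
    stats = as.data.frame(stats_tab),
    icer = icer(mean(dc), mean(de)),
    nmb = nmb(mean(dc), mean(de), wtp),
    quadrants = ce_plane_quadrants(samples),
    prob_cost_effective = ceac(samples, wtp)$probability,
    wtp = wtp,
    n_rejected = attr(samples, "n_rejected") %||% 0L,
    common_draws = attr(samples, "common_draws") %||% NA),
    class = "psa_summary")
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("PSA summary (%d draws, common draws: %s)\n", x$n,
              x$common_draws))
  print(round(x$stats, 4))
  cat(sprintf("ICER (ratio of means): %s\n",
              if (is.numeric(x$icer)) sprintf("%.2f CAD/QALY", x$icer)
              else x$icer))
  cat(sprintf("NMB at %d CAD/QALY: %.2f\n", x$wtp, x$nmb))
  cat(sprintf("P(cost-effective at %d): %.3f\n", x$wtp,
              x$prob_cost_effective))
  cat("CE-plane quadrants (NE SE SW NW):",
      paste(round(x$quadrants, 3), collapse = " "), "\n")
  invisible(x)
}

#' Write PSA samples to CSV
#'
#' Long format (draw, arm, cost, qaly) with the seed and sampling mode
#' echoed in comment header lines.
#'
#' @param samples A `psa_samples` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_psa_samples <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# seed: ", attr(samples, "seed")),
    paste0("# common_draws: ", attr(samples, "common_draws")),
    paste0("# n_rejected: ", attr(samples, "n_rejected"))), con)
  long <- rbind(
    data.frame(draw = samples$draw, arm = "intervention",
               cost = samples$cost_intervention,
               qaly = samples$qaly_intervention),
    data.frame(draw = samples$draw, arm = "comparator",
               cost = samples$cost_comparator,
               qaly = samples$qaly_comparator))
  long <- long[order(long$draw, long$arm), ]
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
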