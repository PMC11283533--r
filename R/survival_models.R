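# Parametric extrapolation of digitized Kaplan-Meier curves and conversion
# to per-cycle, time-dependent transition probabilities.

#' Digitized Kaplan-Meier curve points
#'
#' Container for survival-curve coordinates as read off a published (or
#' synthetic) Kaplan-Meier plot: time in months and the survival fraction,
#' optionally with the number at risk.
#'
#' @param time Numeric vector of non-negative times (months), strictly
#'   increasing.
#' @param survival Numeric vector of survival fractions in `[0, 1]`,
#'   non-increasing.
#' @param n_at_risk Optional integer vector of subjects at risk.
#' @return A data frame of class `km_points` with columns `time_months`,
#'   `survival` and optionally `n_at_risk`.
#' @examples
#' km_points(time = c(6, 12, 24), survival = c(0.9, 0.8, 0.55))
#' @export
km_points <- function(time, survival, n_at_risk = NULL) {
  stopifnot(is.numeric(time), is.numeric(survival),
            length(time) == length(survival), length(time) >= 1)
  if (any(time < 0)) stop("KM times must be non-negative")
  if (any(diff(time) <= 0)) stop("KM times must be strictly increasing")
  if (any(survival < 0 | survival > 1)) stop("survival must lie in [0, 1]")
  if (any(diff(survival) > 1e-12)) stop("survival must be non-increasing")
  out <- data.frame(time_months = as.numeric(time),
                    survival = as.numeric(survival))
  if (!is.null(n_at_risk)) {
    stopifnot(length(n_at_risk) == length(time))
    out$n_at_risk <- as.integer(n_at_risk)
  }
  class(out) <- c("km_points", "data.frame")
  out
}

#' Read digitized KM points from CSV
#'
#' Expects a header row with columns `time_months,survival` and optionally
#' `n_at_risk`.
#'
#' @param path Path to a CSV file.
#' @return A [km_points()] object.
#' @export
read_km_points <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_months", "survival")
  if (!all(need %in% names(d)))
    stop("malformed KM file '", path, "': need columns ",
         paste(need, collapse = ", "))
  km_points(d$time_months, d$survival,
            n_at_risk = if ("n_at_risk" %in% names(d)) d$n_at_risk)
}

#' Write digitized KM points to CSV
#'
#' @param x A [km_points()] object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_km_points <- function(x, path) {
  stopifnot(inherits(x, "km_points"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

new_parametric_survival <- function(family, shape, scale,
                                    coef_covariance = NULL,
                                    r_squared = NA_real_,
                                    n_points = NA_integer_) {
  stopifnot(family %in% c("weibull", "exponential"), shape > 0, scale > 0)
  if (family == "exponential" && abs(shape - 1) > 1e-12)
    stop("exponential family fixes shape at 1")
  if (!is.null(coef_covariance)) {
    stopifnot(is.matrix(coef_covariance), all(dim(coef_covariance) == 2))
    coef_covariance <- (coef_covariance + t(coef_covariance)) / 2
    dimnames(coef_covariance) <- list(c("log_shape", "log_scale"),
                                      c("log_shape", "log_scale"))
  }
  structure(list(family = family, shape = shape, scale = scale,
                 coef_covariance = coef_covariance,
                 r_squared = r_squared, n_points = n_points),
            class = "parametric_survival")
}

#' Fit a parametric survival model to digitized KM points
#'
#' Fits a Weibull (or exponential) survival function
#' \eqn{S(t) = \exp(-(t/\lambda)^k)} by ordinary least squares on the
#' complementary log-log linearization
#' \eqn{\ln(-\ln S) = k \ln t - k \ln \lambda}. Points with survival exactly
#' 0 or 1 (or time 0) carry no information on that scale and are dropped with
#' a warning. The covariance of the regression coefficients is propagated to
#' the log-parameter scale \eqn{(\ln k, \ln \lambda)} by the delta method and
#' stored for probabilistic sensitivity analysis.
#'
#' @param points A [km_points()] object.
#' @param family `"weibull"` or `"exponential"` (shape fixed at 1).
#' @return A `parametric_survival` object with elements `family`, `shape`
#'   (k), `scale` (lambda, months), `coef_covariance` (2x2, log scale),
#'   `r_squared` of the linearized fit and `n_points` used.
#' @examples
#' tt <- 1:60
#' pts <- km_points(tt, exp(-(tt / 24)^1.5))
#' fit_parametric(pts, "weibull")
#' @export
fit_parametric <- function(points, family = c("weibull", "exponential")) {
  family <- match.arg(family)
  stopifnot(inherits(points, "km_points"))
  usable <- points$survival > 0 & points$survival < 1 & points$time_months > 0
  if (any(!usable))
    warning(sum(!usable), " point(s) with survival at 0/1 or time 0 dropped ",
            "from the linearized fit")
  t <- points$time_months[usable]
  s <- points$survival[usable]
  if (length(t) < 3)
    stop("insufficient data: need at least 3 points with 0 < survival < 1")
  y <- log(-log(s))
  x <- log(t)
  if (family == "weibull") {
    fit <- stats::lm(y ~ x)
    b <- unname(stats::coef(fit))
    k <- b[2]
    if (!is.finite(k) || k <= 0)
      stop("linearized fit produced non-positive shape; data not Weibull-like")
    lambda <- exp(-b[1] / k)
    # delta method from (intercept a, slope k) to (log k, log lambda):
    # log k = log b2; log lambda = -a/b2
    V <- suppressWarnings(stats::vcov(fit)) # silences lm's perfect-fit note
    J <- rbind(c(0, 1 / k), c(-1 / k, b[1] / k^2))
    cov_log <- J %*% V %*% t(J)
    r2 <- 1 - sum(stats::residuals(fit)^2) /
      max(sum((y - mean(y))^2), .Machine$double.eps)
    return(new_parametric_survival("weibull", k, lambda, cov_log, r2,
                                   length(t)))
  }
  # exponential: k = 1, so log lambda = log t - log(-log S) pointwise
  loglam_i <- x - y
  loglam <- mean(loglam_i)
  v <- stats::var(loglam_i) / length(loglam_i)
  cov_log <- matrix(c(0, 0, 0, v), 2, 2)
  resid <- y - (x - loglam)
  r2 <- 1 - sum(resid^2) / max(sum((y - mean(y))^2), .Machine$double.eps)
  new_parametric_survival("exponential", 1, exp(loglam), cov_log, r2,
                          length(t))
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat(sprintf("Parametric survival model (%s)\n", x$family))
  cat(sprintf("  shape k = %.6g, scale lambda = %.6g months\n",
              x$shape, x$scale))
  if (!is.na(x$r_squared))
    cat(sprintf("  linearized-fit R^2 = %.4f on %d points\n",
                x$r_squared, x$n_points))
  invisible(x)
}

#' Evaluate the fitted survival function
#'
#' @param model A `parametric_survival` object.
#' @param t Time(s) in months, non-negative; vectorized.
#' @return Survival fraction(s) in `[0, 1]`; `S(0) = 1`.
#' @examples
#' m <- weibull_survival(shape = 1, scale = 20)
#' survival_at(m, 20) # exp(-1)
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "parametric_survival"))
  if (any(t < 0)) stop("t must be non-negative")
  exp(-(t / model$scale)^model$shape)
}

#' Construct a parametric survival model from known parameters
#'
#' Convenience constructor used by the synthetic generator and in tests.
#'
#' @param shape Weibull shape k (> 0); 1 gives the exponential.
#' @param scale Weibull scale lambda in months (> 0).
#' @param family Distribution family; defaults to `"weibull"`.
#' @return A `parametric_survival` object.
#' @export
weibull_survival <- function(shape, scale,
                             family = if (shape == 1) "exponential" else "weibull") {
  new_parametric_survival(family, shape, scale)
}

#' Per-cycle event probability from a survival model
#'
#' Converts the fitted curve into the time-dependent per-cycle event
#' probability \eqn{p_i = 1 - S((i+1)\Delta) / S(i\Delta)} used by the
#' Markov engine; vectorized over `cycle_index`.
#'
#' @param model A `parametric_survival` object.
#' @param cycle_index Zero-based cycle index (or vector thereof).
#' @param cycle_length Cycle length in months (> 0), default 1.
#' @return Probability in `[0, 1]` per cycle. When `S` has already reached 0
#'   the event is certain and 1 is returned (with a message).
#' @export
per_cycle_event_prob <- function(model, cycle_index, cycle_length = 1) {
  stopifnot(all(cycle_index >= 0), cycle_length > 0)
  s0 <- survival_at(model, cycle_index * cycle_length)
  s1 <- survival_at(model, (cycle_index + 1) * cycle_length)
  p <- ifelse(s0 == 0, 1, 1 - s1 / s0)
  if (any(s0 == 0))
    message("survival already 0 at cycle start; event probability set to 1")
  pmin(pmax(p, 0), 1)
}

#' Decompose PFS and OS into per-cycle progression and death probabilities
#'
#' Death takes the per-cycle overall-survival event probability; progression
#' is the progression-free-survival event probability net of death, floored
#' at zero so the pair is a valid competing-risk split.
#'
#' @param pfs,os `parametric_survival` models for progression-free and
#'   overall survival.
#' @param cycle_index Zero-based cycle index (vectorized).
#' @param cycle_length Cycle length in months.
#' @return A list with numeric components `p_progression` and `p_death`,
#'   each in `[0, 1]` with `p_progression + p_death <= 1`.
#' @export
pfs_os_decompose <- function(pfs, os, cycle_index, cycle_length = 1) {
  p_pfs <- per_cycle_event_prob(pfs, cycle_index, cycle_length)
  p_death <- per_cycle_event_prob(os, cycle_index, cycle_length)
  p_prog <- pmax(0, p_pfs - p_death)
  # guard against float overshoot when both are ~1
  over <- (p_prog + p_death) > 1
  p_prog[over] <- 1 - p_death[over]
  list(p_progression = p_prog, p_death = p_death)
}

#' Serialize a fitted survival model to YAML
#'
#' @param model A `parametric_survival` object.
#' @param path Output path (YAML).
#' @return Invisibly, `path`.
#' @export
write_survival_model <- function(model, path) {
  stopifnot(inherits(model, "parametric_survival"))
  doc <- list(family = model$family, shape = model$shape,
              scale = model$scale,
              coef_covariance = if (!is.null(model$coef_covariance))
                as.vector(model$coef_covariance),
              r_squared = model$r_squared, n_points = model$n_points)
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Read a serialized survival model
#'
#' @param path Path to a YAML file written by [write_survival_model()].
#' @return A `parametric_survival` object.
#' @export
read_survival_model <- function(path) {
  doc <- yaml::read_yaml(path)
  cv <- if (!is.null(doc$coef_covariance))
    matrix(as.numeric(doc$coef_covariance), 2, 2)
  new_parametric_survival(doc$family, doc$shape, doc$scale, cv,
                          r_squared = doc$r_squared %||% NA_real_,
                          n_points = doc$n_points %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
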