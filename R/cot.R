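# Sigmoidal cost-of-time model: evaluation, sampling along a participant's
# amplitude-duration relationship, and nonlinear least-squares identification.

#' Cost-of-time parameters
#'
#' The integrated cost of time is modeled as a three-parameter sigmoid,
#' \deqn{G(T) = \alpha - \frac{\alpha}{1 + (T/\delta)^\beta}}
#' (symmetric variant), where alpha is the upper asymptote, beta the
#' relative steepness and delta the inflection time (`G(delta) = alpha/2`).
#' The asymmetric variant raises the denominator to the fixed outer power
#' 0.1: \eqn{G(T) = \alpha - \alpha (1 + (T/\delta)^\beta)^{-0.1}}, allowing
#' the density g to rise faster than it decays.
#'
#' @param alpha Upper asymptote of G (> 0), effort units.
#' @param beta Relative steepness (> 0).
#' @param delta Inflection-point time (> 0), s.
#' @param variant `"symmetric"` (default) or `"asymmetric"`.
#' @return An object of class `cot_params`.
#' @export
cot_params <- function(alpha, beta, delta,
                       variant = c("symmetric", "asymmetric")) {
  variant <- match.arg(variant)
  if (!is.finite(alpha) || alpha < 0) stop("'alpha' must be >= 0")
  if (!is.finite(beta) || beta <= 0) stop("'beta' must be > 0")
  if (!is.finite(delta) || delta <= 0) stop("'delta' must be > 0")
  structure(list(alpha = alpha, beta = beta, delta = delta, variant = variant),
            class = "cot_params")
}

#' @export
print.cot_params <- function(x, ...) {
  cat(sprintf("Cost of time (%s): alpha = %.4g, beta = %.4g, delta = %.4g s\n",
              x$variant, x$alpha, x$beta, x$delta))
  if (!is.null(x$ci)) {
    ci <- x$ci
    cat(sprintf("  95%% CI: alpha (%.4g, %.4g), beta (%.4g, %.4g), delta (%.4g, %.4g)\n",
                ci["alpha", 1], ci["alpha", 2], ci["beta", 1], ci["beta", 2],
                ci["delta", 1], ci["delta", 2]))
  }
  if (!is.null(x$r2)) cat(sprintf("  fit R2 = %.4f on %d samples\n", x$r2, x$n))
  invisible(x)
}

#' Integrated cost of time G(T)
#'
#' @param params A [cot_params()] object.
#' @param t Time(s), s (>= 0).
#' @return G(t); 0 at t = 0, increasing to alpha.
#' @export
eval_G <- function(params, t) {
  stopifnot(inherits(params, "cot_params"))
  if (any(t < 0)) stop("'t' must be >= 0")
  base <- 1 + (t / params$delta)^params$beta
  if (params$variant == "symmetric")
    params$alpha - params$alpha / base
  else
    params$alpha - params$alpha / base^0.1
}

#' Infinitesimal cost of time g(t)
#'
#' Analytic derivative of [eval_G()]. For the symmetric variant,
#' \deqn{g(t) = \frac{\alpha\beta}{\delta}
#'   \frac{(t/\delta)^{\beta-1}}{(1 + (t/\delta)^\beta)^2};}
#' the asymmetric variant replaces the squared denominator with the power
#' 1.1 and carries the outer 0.1 factor.
#'
#' @inheritParams eval_G
#' @return g(t) >= 0.
#' @export
eval_g <- function(params, t) {
  stopifnot(inherits(params, "cot_params"))
  if (any(t < 0)) stop("'t' must be >= 0")
  s <- t / params$delta
  base <- 1 + s^params$beta
  core <- (params$alpha * params$beta / params$delta) * s^(params$beta - 1)
  g <- if (params$variant == "symmetric") core / base^2
       else 0.1 * core / base^1.1
  # beta > 1 makes the t = 0 limit 0; beta = 1 gives a finite value
  g[t == 0 & params$beta > 1] <- 0
  g
}

#' Sample the time-cost density along an amplitude-duration relationship
#'
#' For each amplitude on a grid, the participant's duration is predicted by
#' the affine amplitude-duration fit and the time-cost density g at that
#' duration is computed from the fixed-time optimal control problem (the
#' maximized Hamiltonian, see [time_cost_sample()]). These (T, g) pairs are
#' what the sigmoid identification in [fit_sigmoid()] consumes.
#'
#' @param arm An [arm_model()].
#' @param ampdur An `ampdur_fit` from [fit_amplitude_duration()], or a list
#'   with `slope` and `intercept` (s/deg, s).
#' @param amplitudes Amplitude grid, deg. Default 40 values spanning 5-95.
#' @return Data frame with `amplitude_deg`, `duration_s` and `g_value`,
#'   sorted by duration.
#' @export
sample_cot <- function(arm, ampdur, amplitudes = seq(5, 95, length.out = 40)) {
  stopifnot(inherits(arm, "arm_model"))
  slope <- ampdur$slope; intercept <- ampdur$intercept
  if (!is.finite(slope) || slope <= 0)
    stop("amplitude-duration slope must be positive to map amplitudes to times")
  durations <- slope * amplitudes + intercept
  g <- vapply(seq_along(amplitudes), function(i)
    time_cost_sample(arm, amplitudes[i] * pi / 180, durations[i]), numeric(1))
  out <- data.frame(amplitude_deg = amplitudes, duration_s = durations,
                    g_value = g)
  out[order(out$duration_s), ]
}

#' Identify sigmoidal cost-of-time parameters from g samples
#'
#' Nonlinear least squares of the analytic density [eval_g()] against
#' sampled (T, g) pairs, using Levenberg-Marquardt with deterministic
#' multi-start initialization: delta starts at the median sample duration,
#' beta at each of `beta_starts`, and alpha from the peak heuristic
#' `max(g) * 4 * delta / beta` (the symmetric density peaks near
#' `alpha beta / (4 delta)`). Parameters are bounded to alpha in (0, 1e6],
#' beta in (0.5, 30], delta in (0.05, 10] s. 95% confidence intervals are
#' asymptotic (Jacobian-based).
#'
#' @param duration Sample durations, s.
#' @param g Sampled time-cost density values (>= 0).
#' @param variant `"symmetric"` (default) or `"asymmetric"`.
#' @param beta_starts Multi-start values for beta. Default `c(2, 5, 8)`.
#' @return A [cot_params()] object augmented with `ci` (2x3 matrix of 95%
#'   bounds), `r2`, `n` and `flag` (`"ok"` or `"unidentifiable"`).
#' @export
fit_sigmoid <- function(duration, g, variant = c("symmetric", "asymmetric"),
                        beta_starts = c(2, 5, 8)) {
  variant <- match.arg(variant)
  keep <- is.finite(duration) & is.finite(g)
  duration <- duration[keep]; g <- g[keep]
  if (length(duration) < 4 || diff(range(duration)) <= 0)
    stop("need at least 4 g samples spanning a nondegenerate duration range")
  if (all(g <= 1e-12 * max(1, mean(g))) || stats::sd(g) == 0) {
    out <- cot_params(max(mean(g), .Machine$double.eps), 2, stats::median(duration),
                      variant)
    out$flag <- "unidentifiable"; out$r2 <- NA_real_; out$n <- length(g)
    return(out)
  }

  dat <- data.frame(t = duration, y = g)
  gfun <- function(t, la, beta, delta) {
    eval_g(cot_params(exp(la), beta, delta, variant), t)
  }
  lower <- c(la = log(1e-12), beta = 0.5, delta = 0.05)
  upper <- c(la = log(1e6), beta = 30, delta = 10)
  d0 <- min(max(stats::median(duration), 0.06), 9.9)
  best <- NULL
  for (b0 in beta_starts) {
    a0 <- max(g) * 4 * d0 / b0
    st <- c(la = log(min(max(a0, 1e-10), 1e6)), beta = b0, delta = d0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ gfun(t, la, beta, delta), data = dat, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("sigmoid fit failed to converge from all starts")

  cf <- stats::coef(best$fit)
  out <- cot_params(unname(exp(cf["la"])), unname(cf["beta"]),
                    unname(cf["delta"]), variant)
  sst <- sum((g - mean(g))^2)
  out$r2 <- if (sst > 0) 1 - best$rss / sst else NA_real_
  out$n <- length(g)
  out$flag <- "ok"

  # asymptotic 95% CIs from the Jacobian at the optimum (delta method for
  # alpha = exp(la))
  ci <- matrix(NA_real_, 3, 2, dimnames = list(c("alpha", "beta", "delta"),
                                               c("lower", "upper")))
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e) NULL)
  if (!is.null(se) && all(is.finite(se))) {
    tcrit <- stats::qt(0.975, max(length(g) - 3, 1))
    a_se <- exp(cf["la"]) * se["la"]
    ci["alpha", ] <- exp(cf["la"]) + c(-1, 1) * tcrit * a_se
    ci["beta", ] <- cf["beta"] + c(-1, 1) * tcrit * se["beta"]
    ci["delta", ] <- cf["delta"] + c(-1, 1) * tcrit * se["delta"]
  }
  out$ci <- ci
  out
}
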