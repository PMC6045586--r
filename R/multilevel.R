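# Three-level variance decomposition of vigour and simple trait regressions.

#' Empty three-level hierarchical linear model
#'
#' Fits the random-intercept model
#' \deqn{y_{ijk} = \beta_0 + u_k + v_{jk} + e_{ijk}}
#' for block-level scores nested in sessions nested in participants, by
#' REML, and reports the level variances (level 1 between blocks, level 2
#' between sessions, level 3 between individuals) and their proportions of
#' the total. Confidence intervals for the proportions come from a
#' parametric bootstrap (simulate from the fitted model, refit).
#'
#' Participants observed in a single session still inform the individual and
#' block variances; the session variance is identified by the participants
#' with repeated sessions. If no participant has two sessions, the session
#' variance is fixed at 0 with a warning.
#'
#' @param score Numeric vigour scores, one per block.
#' @param participant,session,block Matching id labels (any atomic type).
#' @param nboot Parametric bootstrap draws for the proportion CIs; 0 (the
#'   default here) skips the bootstrap. 500 draws give stable 95% intervals.
#' @param conf Confidence level. Default 0.95.
#' @return An object of class `hlm_components`: `grand_mean`, `omega_e`,
#'   `omega_v`, `omega_u`, `proportions` (length 3, sums to 1), `ci`
#'   (3x2 matrix or NULL), and the `lme4` fit in `$model`.
#' @export
fit_empty_hlm <- function(score, participant, session, block, nboot = 0,
                          conf = 0.95) {
  n <- length(score)
  if (length(participant) != n || length(session) != n || length(block) != n)
    stop("score, participant, session, block must have equal length")
  if (anyNA(score) || anyNA(participant) || anyNA(session) || anyNA(block))
    stop("missing ids or scores")
  d <- data.frame(y = score,
                  pid = factor(participant),
                  sid = factor(paste(participant, session, sep = ":")))
  if (nlevels(d$pid) < 2) stop("need at least 2 participants")

  multi <- any(tapply(session, participant,
                      function(s) length(unique(s))) >= 2)
  props_of <- function(fit) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    omega_u <- vc$vcov[vc$grp == "pid"]
    omega_v <- if (any(vc$grp == "sid")) vc$vcov[vc$grp == "sid"] else 0
    omega_e <- vc$vcov[vc$grp == "Residual"]
    c(omega_e, omega_v, omega_u)
  }
  fit <- if (multi) {
    lme4::lmer(y ~ 1 + (1 | pid) + (1 | sid), data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  } else {
    warning("no participant with >= 2 sessions: session variance fixed at 0")
    lme4::lmer(y ~ 1 + (1 | pid), data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  }
  om <- props_of(fit)
  total <- sum(om)
  if (total <= 0) stop("degenerate fit: zero total variance")
  props <- om / total

  ci <- NULL
  if (nboot > 0) {
    bp <- matrix(NA_real_, nboot, 3)
    ys <- stats::simulate(fit, nsim = nboot)
    for (i in seq_len(nboot)) {
      bfit <- tryCatch(suppressWarnings(suppressMessages(
        lme4::refit(fit, ys[[i]]))), error = function(e) NULL)
      if (is.null(bfit)) next
      o <- props_of(bfit)
      bp[i, ] <- o / sum(o)
    }
    a <- (1 - conf) / 2
    ci <- t(apply(bp, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE))
    dimnames(ci) <- list(c("block", "session", "participant"),
                         c("lower", "upper"))
  }
  structure(
    list(grand_mean = unname(lme4::fixef(fit)[1]),
         omega_e = om[1], omega_v = om[2], omega_u = om[3],
         proportions = stats::setNames(props, c("block", "session", "participant")),
         ci = ci, n = n, model = fit),
    class = "hlm_components")
}

#' @export
print.hlm_components <- function(x, ...) {
  cat(sprintf("Empty 3-level HLM (n = %d): grand mean = %.4g\n", x$n,
              x$grand_mean))
  p <- 100 * x$proportions
  cat(sprintf("  variance shares: blocks %.1f%%, sessions %.1f%%, participants %.1f%%\n",
              p[1], p[2], p[3]))
  if (!is.null(x$ci)) {
    for (i in 1:3)
      cat(sprintf("    %s: [%.1f%%, %.1f%%]\n", rownames(x$ci)[i],
                  100 * x$ci[i, 1], 100 * x$ci[i, 2]))
  }
  invisible(x)
}

#' Simple linear regression between a trait and an outcome
#'
#' Ordinary least squares with a two-sided t-test on the slope, the tool
#' used for all trait/vigour and trait/cost-of-time-parameter analyses.
#'
#' @param x Predictor values (a trait or model parameter).
#' @param y Outcome values.
#' @return A one-row data frame: `slope`, `intercept`, `r2`, `p_value`, `n`.
#' @export
ols_regress <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("constant predictor: regression is rank deficient")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit)) # exact fits are legitimate here
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r2 = sm$r.squared,
             p_value = sm$coefficients[2, 4],
             n = length(x))
}
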