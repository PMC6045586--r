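# Shared fixtures: canonical arms, tiny cohort configs and synthetic trials
# built in code.

arm_jerk <- function() arm_model(1, friction = 0, effort_mode = "jerk_only")

arm_cohort_mean <- function(epsilon = 0.005, friction = 0.8,
                            effort_mode = "torque_jerk") {
  arm_model(estimate_inertia(68.7, 0.721), friction = friction,
            epsilon = epsilon, effort_mode = effort_mode)
}

tiny_config <- function(seed = 7, ...) {
  cohort_config(n_participants = 3, sessions_per_participant = c(2, 1, 1),
                blocks_per_session = 2, seed = seed, ...)
}

# noiseless minimum-jerk trial at 250 Hz; a is the signed scale of the
# velocity template (displacement = -a)
minjerk_trial <- function(a = -0.5, t0 = 0.8, tf = 1.75, t_end = 3,
                          fs = 250) {
  tg <- seq(0, t_end - 1 / fs, by = 1 / fs)
  d <- tf - t0
  s <- pmin(pmax(tg - t0, 0), d)
  ang <- -a * (10 * (s / d)^3 - 15 * (s / d)^4 + 6 * (s / d)^5)
  list(time = tg, angle = ang, a = a, t0 = t0, tf = tf)
}

# trapezoid integral
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
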