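# Fixed-time and free-time LQ solver: closed-form oracles, quadrature and
# finite-difference cross-checks, scaling laws.

test_that("problem matrices match the effort-cost definitions", {
  arm <- arm_model(1, friction = 0.8, epsilon = 0.01)
  p <- lq_problem(arm, 1, 1)
  expect_equal(p$state_cost,
               matrix(c(0, 0, 0, 0, 0.64, 0.8, 0, 0.8, 1), 3, 3))
  expect_equal(p$control_cost, 0.01)
  expect_equal(p$cross_cost, c(0, 0, 0))
  pj <- lq_problem(arm_jerk(), 1, 1)
  expect_equal(pj$control_cost, 1)
  expect_true(all(pj$state_cost == 0))
  # torque change with b = 0 reduces to I^2 u^2
  ptc <- lq_problem(arm_model(2, friction = 0, effort_mode = "torque_change"),
                    1, 1)
  expect_equal(ptc$control_cost, 4)
  expect_true(all(ptc$state_cost == 0))
  expect_equal(ptc$cross_cost, c(0, 0, 0))
  # with friction the torque-change cross term couples u and acceleration
  ptc2 <- lq_problem(arm_model(2, friction = 0.5,
                               effort_mode = "torque_change"), 1, 1)
  expect_equal(ptc2$cross_cost, c(0, 0, 1))
  expect_equal(ptc2$state_cost[3, 3], 0.25)
  expect_error(lq_problem(arm, 1, 0.001), "duration")
})

test_that("pure-jerk effort reproduces the minimum-jerk closed form", {
  sol <- solve_fixed_time(lq_problem(arm_jerk(), 1, 1))
  expect_equal(sol$effort, 720, tolerance = 1e-10)
  expect_equal(sol$hamiltonian, 3600, tolerance = 1e-10)
  expect_equal(velocity_ratio(sol$velocity, sol$time), 1.875,
               tolerance = 1e-5)
  # quadratic amplitude scaling
  sol2 <- solve_fixed_time(lq_problem(arm_jerk(), 2, 1))
  expect_equal(sol2$effort, 2880, tolerance = 1e-9)
  # L* = 720 A^2 / T^5 on a grid
  for (A in c(0.2, 1.3)) for (T in c(0.5, 2.1)) {
    s <- solve_fixed_time(lq_problem(arm_jerk(), A, T))
    expect_equal(s$effort, 720 * A^2 / T^5, tolerance = 1e-9)
    expect_equal(s$hamiltonian, 3600 * A^2 / T^6, tolerance = 1e-9)
  }
  # zero amplitude -> zero trajectory and cost
  s0 <- solve_fixed_time(lq_problem(arm_jerk(), 0, 1))
  expect_true(all(s0$angle == 0))
  expect_equal(s0$effort, 0)
})

test_that("boundary conditions hold and effort matches quadrature across modes", {
  for (mode in c("torque_jerk", "torque_change", "jerk_only")) {
    arm <- arm_model(0.743, friction = 0.8, epsilon = 0.005,
                     effort_mode = mode)
    prob <- lq_problem(arm, 0.9, 1.2)
    sol <- solve_fixed_time(prob)
    n <- length(sol$time)
    expect_equal(sol$angle[1], 0, tolerance = 1e-9)
    expect_equal(sol$angle[n], 0.9, tolerance = 1e-9)
    expect_equal(sol$velocity[c(1, n)], c(0, 0), tolerance = 1e-8)
    expect_equal(sol$acceleration[c(1, n)], c(0, 0), tolerance = 1e-7)
    # Simpson quadrature of the running cost vs closed-form effort
    integrand <- switch(mode,
      torque_jerk = sol$torque^2 + 0.005 * sol$control^2,
      torque_change = (0.743 * sol$control + 0.8 * sol$acceleration)^2,
      jerk_only = sol$control^2)
    h <- sol$time[2] - sol$time[1]
    w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
    expect_equal(sum(w * integrand) * h / 3, sol$effort, tolerance = 1e-6)
  }
})

test_that("the maximized Hamiltonian is constant and equals -dL*/dT", {
  for (mode in c("torque_jerk", "torque_change", "jerk_only")) {
    arm <- arm_model(0.743, friction = 0.8, epsilon = 0.005,
                     effort_mode = mode)
    for (Tn in c(0.4, 1.0, 2.5)) {
      A <- 0.9
      g <- time_cost_sample(arm, A, Tn)
      h <- 1e-4 * Tn
      fd <- -(solve_fixed_time(lq_problem(arm, A, Tn + h))$effort -
              solve_fixed_time(lq_problem(arm, A, Tn - h))$effort) / (2 * h)
      expect_lt(abs(g - fd) / abs(fd), 1e-4)
      expect_gt(g, 0)
      # constancy along the extremal: recompute at interior grid times via
      # the solution object
      sol <- solve_fixed_time(lq_problem(arm, A, Tn))
      expect_equal(sol$hamiltonian, g, tolerance = 1e-10)
    }
  }
})

test_that("effort decreases with duration and scales quadratically in amplitude", {
  arm <- arm_cohort_mean()
  Ts <- seq(0.4, 2.5, length.out = 8)
  L <- vapply(Ts, function(T) solve_fixed_time(lq_problem(arm, 0.9, T))$effort,
              numeric(1))
  expect_true(all(diff(L) < 0))
  expect_equal(solve_fixed_time(lq_problem(arm, 1.8, 1))$effort,
               4 * solve_fixed_time(lq_problem(arm, 0.9, 1))$effort,
               tolerance = 1e-9)
})

test_that("scaling the effort integrand scales g but leaves predictions alone", {
  # lambda-scaling: multiplying the running cost by lambda multiplies the
  # identified g by lambda; rescaling G accordingly leaves T* unchanged
  arm1 <- arm_model(1, friction = 0, epsilon = 1e-3,
                    effort_mode = "jerk_only") # R = 1
  g1 <- time_cost_sample(arm1, 0.8, 0.9)
  lam <- 3.7
  # same plant, cost scaled: R = lambda achieved through torque_change with
  # b = 0 and I = sqrt(lambda)
  arm_lam <- arm_model(sqrt(lam), friction = 0,
                       effort_mode = "torque_change")
  expect_equal(time_cost_sample(arm_lam, 0.8, 0.9), lam * g1,
               tolerance = 1e-8)
  G1 <- function(T) 3600 * 0.8^2 * T
  t1 <- solve_free_time(arm1, 0.8, G1)$duration
  t2 <- solve_free_time(arm_lam, 0.8, function(T) lam * G1(T))$duration
  expect_equal(t1, t2, tolerance = 1e-3)
})

test_that("free-time minimization finds interior optima and flags edges", {
  # stationarity oracle: jerk-only, G = 3600 T => T* = 1 for unit amplitude
  ft <- solve_free_time(arm_jerk(), 1, function(T) 3600 * T)
  expect_false(ft$boundary)
  expect_equal(ft$duration, 1, tolerance = 1e-3)
  # zero time cost: effort always favours slower movement -> upper edge
  expect_warning(ft0 <- solve_free_time(arm_jerk(), 1, function(T) 0),
                 "bracket edge")
  expect_true(ft0$boundary)
  expect_equal(ft0$duration, 5)
  # increasing alpha of a sigmoidal time cost never slows the movement
  arm <- arm_cohort_mean()
  ts <- vapply(c(40, 80, 160), function(al)
    solve_free_time(arm, 0.9, cot_params(al, 5.5, 1.19))$duration,
    numeric(1))
  expect_true(all(diff(ts) <= 1e-6))
})

test_that("velocity shape interpolates between regimes as the jerk weight grows", {
  I <- estimate_inertia(68.7, 0.721)
  ratios <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(eps) {
    sol <- solve_fixed_time(lq_problem(
      arm_model(I, epsilon = eps), 0.9, 1.0))
    velocity_ratio(sol$velocity, sol$time)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios > 1.4 & ratios < 1.876))
})
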