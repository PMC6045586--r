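# Fixed-time and free-time linear-quadratic optimal control for the
# single-joint arm. State x = (theta, theta', theta''), control u = angle
# jerk, plant xdot = Ax + Bu with A the 3x3 shift matrix and B = (0,0,1)'.
# The effort cost is  integral( u R u + x' Q x + 2 x' S u ) dt  with
# (R, Q, S) determined by the effort mode.

#' Build the linear-quadratic reaching problem
#'
#' Assembles the quadratic effort cost for a rest-to-rest movement of given
#' amplitude and duration. For the `torque_jerk` mode the state cost is
#' \deqn{Q = \begin{pmatrix} 0&0&0\\ 0&b^2&Ib\\ 0&Ib&I^2 \end{pmatrix},
#'   \quad R = \varepsilon,}
#' which makes \eqn{x'Qx + Ru^2 = \tau^2 + \varepsilon u^2}. The
#' `torque_change` mode is the quadratic form of \eqn{\dot\tau = Iu +
#' b\ddot\theta} (R = I^2, Q33 = b^2, with a state-control cross term
#' S = (0, 0, Ib)'), and `jerk_only` has R = 1, Q = 0.
#'
#' @param arm An [arm_model()].
#' @param amplitude Movement extent, rad (signed).
#' @param duration Movement time T, s; must be at least 0.01 s.
#' @return An object of class `lq_problem`.
#' @export
lq_problem <- function(arm, amplitude, duration) {
  stopifnot(inherits(arm, "arm_model"))
  if (!is.finite(amplitude)) stop("'amplitude' must be finite")
  if (!is.finite(duration) || duration < 0.01)
    stop("'duration' must be a finite time of at least 0.01 s")
  I <- arm$inertia; b <- arm$friction
  cost <- switch(arm$effort_mode,
    torque_jerk = list(
      R = arm$epsilon,
      Q = matrix(c(0, 0, 0, 0, b^2, I * b, 0, I * b, I^2), 3, 3),
      S = c(0, 0, 0)),
    torque_change = list(
      R = I^2,
      Q = diag(c(0, 0, b^2)),
      S = c(0, 0, I * b)),
    jerk_only = list(
      R = 1,
      Q = matrix(0, 3, 3),
      S = c(0, 0, 0)),
    stop("unknown effort mode: ", arm$effort_mode))
  structure(
    list(arm = arm, amplitude = amplitude, duration = duration,
         state_matrix = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3),
         input_vector = c(0, 0, 1),
         control_cost = cost$R, state_cost = cost$Q, cross_cost = cost$S),
    class = "lq_problem")
}

# Scalar cost coefficients entering the Euler-Lagrange equation
# R th^(6) - Q33 th'''' + Q22 th'' = 0 (the cross terms Q23, S3 drop out of
# the stationarity condition but enter costates and the running cost).
.lq_coefs <- function(problem) {
  list(R = problem$control_cost,
       Q22 = problem$state_cost[2, 2], Q23 = problem$state_cost[2, 3],
       Q33 = problem$state_cost[3, 3], S3 = problem$cross_cost[3])
}

# Roots (with multiplicity) of the Euler-Lagrange characteristic polynomial
# R r^6 - Q33 r^4 + Q22 r^2 = 0. Returned as a list of (root, multiplicity);
# complex roots allowed (conjugate quartet when the quartic discriminant is
# negative).
.lq_roots <- function(cf) {
  a <- cf$Q33 / cf$R
  c0 <- cf$Q22 / cf$R
  if (a == 0 && c0 == 0)
    return(list(list(r = 0 + 0i, mult = 6L)))
  if (c0 == 0) {
    w <- sqrt(as.complex(a))
    return(list(list(r = 0 + 0i, mult = 4L),
                list(r = w, mult = 1L), list(r = -w, mult = 1L)))
  }
  disc <- as.complex(a^2 - 4 * c0)
  r1 <- sqrt((a + sqrt(disc)) / 2)
  r2 <- sqrt((a - sqrt(disc)) / 2)
  if (abs(r1 - r2) < 1e-8 * abs(r1))
    return(list(list(r = 0 + 0i, mult = 2L),
                list(r = r1, mult = 2L), list(r = -r1, mult = 2L)))
  list(list(r = 0 + 0i, mult = 2L),
       list(r = r1, mult = 1L), list(r = -r1, mult = 1L),
       list(r = r2, mult = 1L), list(r = -r2, mult = 1L))
}

# Expand roots into 6 basis elements t^j exp(r (t - s)). Exponentials with
# Re(r) > 0 are anchored at the final time (s = T) so every basis function is
# bounded by ~1 on [0, T]: the boundary system stays well conditioned for
# arbitrarily stiff cost ratios.
.lq_basis <- function(roots, duration) {
  out <- vector("list", 6L)
  k <- 0L
  for (rt in roots) for (j in seq_len(rt$mult) - 1L) {
    k <- k + 1L
    out[[k]] <- list(r = rt$r, j = j,
                     s = if (Re(rt$r) > 0) duration else 0)
  }
  out
}

# k-th derivative of t^j exp(r (t - s)) at (vector) t, complex.
.lq_dbasis <- function(bf, t, k) {
  ffac <- function(j, i) if (i == 0L) 1 else prod(j:(j - i + 1L))
  r <- bf$r; j <- bf$j
  if (abs(r) == 0) {
    if (k > j) return(rep(0 + 0i, length(t)))
    return(as.complex(ffac(j, k) * t^(j - k)))
  }
  res <- rep(0 + 0i, length(t))
  for (i in 0:min(k, j))
    res <- res + choose(k, i) * ffac(j, i) * t^(j - i) * r^(k - i)
  res * exp(r * (t - bf$s))
}

# Solve the rest-to-rest boundary-value problem analytically. Returns the
# basis, its coefficients and a derivative evaluator (k up to 5).
.lq_extremal <- function(problem) {
  cf <- .lq_coefs(problem)
  Tdur <- problem$duration
  bas <- .lq_basis(.lq_roots(cf), Tdur)
  Mb <- matrix(0 + 0i, 6, 6)
  for (jb in 1:6) for (k in 0:2) {
    Mb[k + 1L, jb] <- .lq_dbasis(bas[[jb]], 0, k)
    Mb[k + 4L, jb] <- .lq_dbasis(bas[[jb]], Tdur, k)
  }
  rc <- rcond(Mod(Mb))
  if (!is.finite(rc) || rc < 1e-13)
    stop("ill-conditioned boundary map: duration ", Tdur,
         " s is out of the solvable range for this arm/cost")
  coef <- solve(Mb, as.complex(c(0, 0, 0, problem$amplitude, 0, 0)))
  deriv <- function(t, k) {
    v <- rep(0 + 0i, length(t))
    for (jb in 1:6) v <- v + coef[jb] * .lq_dbasis(bas[[jb]], t, k)
    Re(v)
  }
  list(cf = cf, deriv = deriv)
}

# Costates along the extremal, from the stationarity and adjoint equations:
#   p3 = -2 R u - 2 S3 th''
#   p2 =  2 R th'''' - 2 Q23 th' - 2 Q33 th''
#   p1 = -2 R th^(5) + 2 Q33 th''' - 2 Q22 th'   (constant in t)
# The maximized (Pontryagin) Hamiltonian is -(L + p.(Ax + Bu)), constant for
# this autonomous problem, and equals -dL*/dT >= 0 for rest-to-rest reaching.
.lq_hamiltonian <- function(cf, deriv, t) {
  th1 <- deriv(t, 1); th2 <- deriv(t, 2); th3 <- deriv(t, 3)
  th4 <- deriv(t, 4); th5 <- deriv(t, 5)
  run <- cf$R * th3^2 + cf$Q22 * th1^2 + 2 * cf$Q23 * th1 * th2 +
    cf$Q33 * th2^2 + 2 * cf$S3 * th2 * th3
  p1 <- -2 * cf$R * th5 + 2 * cf$Q33 * th3 - 2 * cf$Q22 * th1
  p2 <- 2 * cf$R * th4 - 2 * cf$Q23 * th1 - 2 * cf$Q33 * th2
  p3 <- -2 * cf$R * th3 - 2 * cf$S3 * th2
  -(run + p1 * th1 + p2 * th2 + p3 * th3)
}

# Minimal effort L*(T) and maximized Hamiltonian without building the full
# trajectory. Along the extremal d/dt(p.x) = -2 L, so with x(0) = 0,
# L* = -p(T).x(T)/2 = -p1 * amplitude / 2 (p1 is constant).
.lq_effort <- function(problem) {
  if (problem$amplitude == 0)
    return(list(effort = 0, hamiltonian = 0))
  ex <- .lq_extremal(problem)
  tm <- problem$duration / 2
  p1 <- -2 * ex$cf$R * ex$deriv(tm, 5) + 2 * ex$cf$Q33 * ex$deriv(tm, 3) -
    2 * ex$cf$Q22 * ex$deriv(tm, 1)
  list(effort = -0.5 * p1 * problem$amplitude,
       hamiltonian = .lq_hamiltonian(ex$cf, ex$deriv, tm))
}

#' Solve the fixed-time rest-to-rest problem
#'
#' Computes the effort-minimizing trajectory joining rest at angle 0 to rest
#' at the target amplitude in exactly the prescribed duration. The extremal
#' solves the Pontryagin two-point boundary-value problem; because the plant
#' is a chain of integrators with a constant-coefficient quadratic cost, the
#' optimal angle is an exponential-polynomial whose 6 coefficients are the
#' solution of the boundary system, evaluated here in closed form.
#'
#' @param problem An [lq_problem()].
#' @param n_grid Number of (uniform) time samples for returned trajectories.
#' @return An object of class `lq_solution` with elements `time`, `angle`,
#'   `velocity`, `acceleration`, `control` (jerk), `torque`, `effort` (the
#'   minimal cost L*(T)), and `hamiltonian` (the maximized Hamiltonian,
#'   equal to -dL*/dT).
#' @export
#' @examples
#' arm <- arm_model(1, friction = 0, effort_mode = "jerk_only")
#' sol <- solve_fixed_time(lq_problem(arm, amplitude = 1, duration = 1))
#' sol$effort # 720 = 720 A^2 / T^5
solve_fixed_time <- function(problem, n_grid = 501) {
  stopifnot(inherits(problem, "lq_problem"))
  tg <- seq(0, problem$duration, length.out = n_grid)
  if (problem$amplitude == 0) {
    z <- numeric(n_grid)
    return(structure(list(time = tg, angle = z, velocity = z,
                          acceleration = z, control = z, torque = z,
                          effort = 0, hamiltonian = 0, problem = problem),
                     class = "lq_solution"))
  }
  ex <- .lq_extremal(problem)
  ang <- ex$deriv(tg, 0); vel <- ex$deriv(tg, 1)
  acc <- ex$deriv(tg, 2); jrk <- ex$deriv(tg, 3)
  arm <- problem$arm
  tm <- problem$duration / 2
  p1 <- -2 * ex$cf$R * ex$deriv(tm, 5) + 2 * ex$cf$Q33 * ex$deriv(tm, 3) -
    2 * ex$cf$Q22 * ex$deriv(tm, 1)
  structure(
    list(time = tg, angle = ang, velocity = vel, acceleration = acc,
         control = jrk, torque = arm$inertia * acc + arm$friction * vel,
         effort = -0.5 * p1 * problem$amplitude,
         hamiltonian = .lq_hamiltonian(ex$cf, ex$deriv, tm),
         problem = problem),
    class = "lq_solution")
}

#' @export
print.lq_solution <- function(x, ...) {
  p <- x$problem
  cat(sprintf(
    "Fixed-time LQ solution: A = %.4g rad, T = %.4g s (%s)\n  L* = %.6g, maximized Hamiltonian g = %.6g\n",
    p$amplitude, p$duration, p$arm$effort_mode, x$effort, x$hamiltonian))
  invisible(x)
}

#' Sample the infinitesimal cost of time g(T)
#'
#' The value of the time-cost density at duration T equals minus the partial
#' derivative of the fixed-time optimal effort with respect to T, i.e. the
#' value of the maximized Hamiltonian along the fixed-time extremal. It is
#' non-negative for rest-to-rest reaching since slower movements always cost
#' less effort.
#'
#' @inheritParams lq_problem
#' @return g(T), in effort-per-second units.
#' @export
#' @examples
#' arm <- arm_model(1, friction = 0, effort_mode = "jerk_only")
#' time_cost_sample(arm, 1, 1) # 3600 = 3600 A^2 / T^6
time_cost_sample <- function(arm, amplitude, duration) {
  problem <- lq_problem(arm, amplitude, duration)
  .lq_effort(problem)$hamiltonian
}

#' Predict movement duration from a time/effort trade-off
#'
#' Solves the free-time problem: the optimal duration minimizes the total
#' cost \eqn{L^*(T) + G(T)} over a search bracket, where \eqn{L^*} is the
#' fixed-time minimal effort and G a non-decreasing cost of time. The
#' minimization scans a log-spaced duration grid and refines the best
#' bracket with bounded golden-section/parabolic search.
#'
#' @param arm An [arm_model()].
#' @param amplitude Movement extent, rad.
#' @param cot Either a [cot_params()] object or a function `G(T)` with
#'   `G(0) = 0`, non-decreasing.
#' @param t_min,t_max Search bracket, s. Defaults 0.2 and 5.
#' @param n_grid Number of log-spaced scan candidates. Default 60.
#' @param tol Refinement tolerance on T, s. Default 1e-4.
#' @return A list with `duration` (T*), `total_cost`, `solution` (the
#'   [solve_fixed_time()] trajectory at T*), and `boundary` (TRUE with a
#'   warning when the minimum sits at a bracket edge, meaning no interior
#'   time/effort trade-off was found).
#' @export
solve_free_time <- function(arm, amplitude, cot, t_min = 0.2, t_max = 5,
                            n_grid = 60, tol = 1e-4) {
  stopifnot(inherits(arm, "arm_model"))
  G <- if (inherits(cot, "cot_params")) function(t) eval_G(cot, t) else cot
  if (!is.function(G)) stop("'cot' must be a cot_params object or a function")
  total <- function(T) .lq_effort(lq_problem(arm, amplitude, T))$effort + G(T)
  tg <- exp(seq(log(t_min), log(t_max), length.out = n_grid))
  costs <- vapply(tg, total, numeric(1))
  i <- which.min(costs)
  boundary <- FALSE
  if (i == 1L || i == n_grid) {
    boundary <- TRUE
    warning("free-time minimum attained at the bracket edge (T = ",
            signif(tg[i], 4), " s): no interior time/effort trade-off")
    t_star <- tg[i]
    best <- costs[i]
  } else {
    opt <- stats::optimize(total, lower = tg[i - 1L], upper = tg[i + 1L],
                           tol = tol)
    t_star <- opt$minimum
    best <- opt$objective
  }
  list(duration = t_star, total_cost = best,
       solution = solve_fixed_time(lq_problem(arm, amplitude, t_star)),
       boundary = boundary)
}
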