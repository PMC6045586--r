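#' Single-joint arm model
#'
#' Constructs the plant used throughout the package: a fully extended arm
#' rotating about the shoulder in the horizontal plane, with dynamics
#' \eqn{\tau = I\ddot\theta + b\dot\theta}. The effort cost attached to the
#' model is one of three quadratic variants:
#' \describe{
#'   \item{`torque_jerk`}{integral of squared torque plus a jerk regularizer,
#'     \eqn{\int \tau^2 + \varepsilon u^2\,dt}, where \eqn{u =
#'     \dddot\theta} is the angle jerk (the control variable);}
#'   \item{`torque_change`}{integral of squared torque change
#'     \eqn{\int \dot\tau^2\,dt = \int (Iu + b\ddot\theta)^2\,dt};}
#'   \item{`jerk_only`}{integral of squared angle jerk \eqn{\int u^2\,dt},
#'     an inertia-independent ("subjective") effort measure.}
#' }
#'
#' @param inertia Moment of inertia about the shoulder, kg m^2. Must be > 0.
#' @param friction Viscous friction coefficient b, N m s/rad, in `[0, 1]`.
#'   Default 0.8.
#' @param epsilon Jerk-regularization weight for `torque_jerk`. Default 0.005.
#' @param effort_mode One of `"torque_jerk"`, `"torque_change"`, `"jerk_only"`.
#'
#' @return An object of class `arm_model`.
#' @seealso [estimate_inertia()], [lq_problem()]
#' @export
#' @examples
#' arm <- arm_model(inertia = estimate_inertia(68.7, 0.721))
#' torque_of(arm, c(0, 1, 2))
arm_model <- function(inertia, friction = 0.8, epsilon = 0.005,
                      effort_mode = c("torque_jerk", "torque_change", "jerk_only")) {
  effort_mode <- match.arg(effort_mode)
  if (!is.numeric(inertia) || length(inertia) != 1L || !is.finite(inertia) || inertia <= 0)
    stop("'inertia' must be a single positive number (kg m^2)")
  if (!is.numeric(friction) || length(friction) != 1L || friction < 0)
    stop("'friction' must be a single non-negative number")
  if (effort_mode == "torque_jerk" &&
      (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0))
    stop("'epsilon' must be > 0 when effort_mode = 'torque_jerk'")
  structure(
    list(inertia = inertia, friction = friction, epsilon = epsilon,
         effort_mode = effort_mode),
    class = "arm_model")
}

#' @export
print.arm_model <- function(x, ...) {
  cat(sprintf(
    "Single-joint arm: I = %.4g kg m^2, b = %.3g N m s/rad, effort = %s",
    x$inertia, x$friction, x$effort_mode))
  if (x$effort_mode == "torque_jerk")
    cat(sprintf(" (epsilon = %.4g)", x$epsilon))
  cat("\n")
  invisible(x)
}

#' Estimate the arm's moment of inertia from anthropometry
#'
#' Models the fully extended arm as a single rigid segment and applies
#' standard anthropometric table coefficients: segment mass as a fraction of
#' body mass, and radius of gyration about the proximal (shoulder) joint as
#' a fraction of segment length, so that
#' \deqn{I = m_f \, M \, (\rho_f \, L)^2.}
#' The defaults are the whole-upper-limb coefficients (mass fraction 0.050,
#' proximal radius-of-gyration fraction 0.645); both are exposed so that an
#' alternative segment-wise summation can be substituted.
#'
#' @param body_mass Body mass, kg.
#' @param arm_length Fully extended arm length, m.
#' @param mass_fraction Segment mass as a fraction of body mass.
#' @param rog_fraction Radius of gyration about the proximal joint as a
#'   fraction of segment length.
#' @return Moment of inertia, kg m^2. Vectorized over mass/length.
#' @export
#' @examples
#' estimate_inertia(68.7, 0.721) # ~0.743 kg m^2
estimate_inertia <- function(body_mass, arm_length,
                             mass_fraction = 0.050, rog_fraction = 0.645) {
  if (any(!is.finite(body_mass)) || any(body_mass <= 0) ||
      any(!is.finite(arm_length)) || any(arm_length <= 0))
    stop("invalid anthropometry: body mass and arm length must be positive")
  if (mass_fraction <= 0 || rog_fraction <= 0)
    stop("anthropometric fractions must be positive")
  mass_fraction * body_mass * (rog_fraction * arm_length)^2
}

#' Joint torque for a kinematic state
#'
#' @param arm An [arm_model()].
#' @param state Numeric vector `(angle, angular velocity, angular
#'   acceleration)` in rad, rad/s, rad/s^2, or a matrix with three columns.
#' @return Torque in N m (the angle does not enter the dynamics).
#' @export
torque_of <- function(arm, state) {
  stopifnot(inherits(arm, "arm_model"))
  if (is.matrix(state)) {
    if (ncol(state) != 3L) stop("'state' matrix must have 3 columns")
    vel <- state[, 2L]; acc <- state[, 3L]
  } else {
    if (length(state) != 3L) stop("'state' must have 3 elements")
    vel <- state[2L]; acc <- state[3L]
  }
  if (any(!is.finite(vel)) || any(!is.finite(acc)))
    stop("'state' must be finite")
  arm$inertia * acc + arm$friction * vel
}
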