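#' Passive suppression torque
#'
#' The stiffness + gravity-compensation law of the equilibrium-point
#' controller:
#' \deqn{\tau_{in} = -K(\theta - \theta^d) + G(\theta^d).}
#' Gravity is compensated at the *desired* posture, so the compensation term
#' is constant over time and the desired posture is an equilibrium of the
#' static arm for any stiffness value, including \eqn{K = 0}.
#'
#' @param gains A [gain_set()] object.
#' @param angles Length-3 joint angles, rad.
#' @param params An [arm_parameters()] object (used for the gravity term).
#'
#' @return Length-3 torque, N m.
#' @export
passive_torque <- function(gains, angles, params = arm_parameters()) {
  stopifnot(inherits(gains, "gain_set"), length(angles) == 3)
  as.vector(-gains$stiffness %*% (angles - gains$posture)) +
    gravity_torque(params, gains$posture)
}

#' Hand velocity relative to the skyhook virtual plane
#'
#' The skyhook controller tethers the hand to a virtual plane fixed in the
#' workspace, so the relevant velocity is the absolute workspace hand
#' velocity: \eqn{\dot x_{ha} = J\dot\theta + \dot X}, the joint contribution
#' plus the base (shoulder) velocity.
#'
#' @inheritParams passive_torque
#' @param velocities Length-3 joint angular velocities, rad/s.
#' @param base_velocity Length-2 shoulder velocity, m/s.
#'
#' @return Length-2 numeric, m/s.
#' @export
relative_hand_velocity <- function(params, angles, velocities,
                                   base_velocity = c(0, 0)) {
  stopifnot(length(velocities) == 3, length(base_velocity) == 2)
  as.vector(hand_jacobian(params, angles) %*% velocities) + base_velocity
}

#' Active suppression torque
#'
#' Adds the skyhook virtual-damper torque to the passive law:
#' \deqn{\tau_{in} = -K(\theta - \theta^d) + G(\theta^d)
#'       - J^\top C \dot x_{ha|vp},}
#' where \eqn{C} is the diagonal workspace damper and
#' \eqn{\dot x_{ha|vp}} the hand velocity relative to the virtual plane.
#' With `damper = c(0, 0)` this reduces exactly to [passive_torque()].
#'
#' @inheritParams relative_hand_velocity
#' @inheritParams passive_torque
#' @return Length-3 torque, N m.
#' @export
active_torque <- function(gains, angles, velocities,
                          base_velocity = c(0, 0),
                          params = arm_parameters()) {
  tau <- passive_torque(gains, angles, params)
  if (any(gains$damper != 0)) {
    J <- hand_jacobian(params, angles)
    xdot <- as.vector(J %*% velocities) + base_velocity
    tau <- tau - as.vector(t(J) %*% (gains$damper * xdot))
  }
  tau
}

#' Instantaneous equilibrium point of the active controller
#'
#' Rewriting the active torque as a pure spring law
#' \eqn{\tau_{in} = -K(\theta - \theta_{eq})} gives the moving equilibrium
#' point
#' \deqn{\theta_{eq} = \theta^d + K^{-1}G(\theta^d)
#'       - K^{-1}J^\top C \dot x_{ha|vp}.}
#' (The positive sign on the gravity term is what makes the identity hold:
#' the spring must pull past the desired posture to support the arm's
#' weight.)
#' The first two terms are constant (the posture the spring alone would
#' hold); the skyhook term shifts the equilibrium point continuously against
#' the workspace hand velocity. Requires invertible stiffness.
#'
#' @inheritParams active_torque
#' @return Length-3 numeric, rad.
#' @export
equilibrium_point <- function(gains, angles, velocities,
                              base_velocity = c(0, 0),
                              params = arm_parameters()) {
  K <- gains$stiffness
  if (abs(det(K)) < 1e-12) {
    stop("equilibrium point undefined: stiffness matrix is singular",
         call. = FALSE)
  }
  J <- hand_jacobian(params, angles)
  xdot <- as.vector(J %*% velocities) + base_velocity
  gd <- gravity_torque(params, gains$posture)
  gains$posture + as.vector(solve(K, gd)) -
    as.vector(solve(K, t(J) %*% (gains$damper * xdot)))
}
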