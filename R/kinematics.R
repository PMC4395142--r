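#' Forward kinematics of the three-link arm
#'
#' Workspace positions of the elbow, wrist and hand for given joint angles and
#' base (shoulder) position.
#'
#' Angle convention: `angles[1]` is the absolute upper-arm angle measured
#' counter-clockwise from the forward horizontal axis; `angles[2]` and
#' `angles[3]` are the relative elbow and wrist angles, so the absolute link
#' angles are `cumsum(angles)`. The workspace frame is `x` forward
#' (the oscillation axis), `y` up.
#'
#' @param params An [arm_parameters()] object.
#' @param angles Length-3 numeric, joint angles in rad.
#' @param base_position Length-2 numeric, shoulder position in m.
#'
#' @return A 4x2 numeric matrix with rows `shoulder`, `elbow`, `wrist`,
#'   `hand` and columns `x`, `y` (m).
#' @examples
#' forward_kinematics(arm_parameters(), c(0, 0, 0), c(0, 0))
#' @export
forward_kinematics <- function(params, angles, base_position = c(0, 0)) {
  stopifnot(inherits(params, "arm_parameters"), length(angles) == 3,
            length(base_position) == 2)
  phi <- cumsum(angles)
  pts <- matrix(0, 4, 2, dimnames = list(
    c("shoulder", "elbow", "wrist", "hand"), c("x", "y")))
  pts[1, ] <- base_position
  for (i in 1:3) {
    pts[i + 1, ] <- pts[i, ] + params$length[i] * c(cos(phi[i]), sin(phi[i]))
  }
  pts
}

#' Hand Jacobian
#'
#' The 2x3 matrix mapping joint angular velocities to the hand velocity
#' relative to the (possibly moving) base: the absolute hand velocity is
#' `J %*% angular_velocities + base_velocity`.
#'
#' The Jacobian is only ever used forward or transposed (to map the skyhook
#' damper force into joint torques), so kinematically singular configurations
#' are allowed.
#'
#' @inheritParams forward_kinematics
#' @return A 2x3 numeric matrix, m/rad.
#' @export
hand_jacobian <- function(params, angles) {
  stopifnot(inherits(params, "arm_parameters"), length(angles) == 3)
  phi <- cumsum(angles)
  j_abs <- rbind(-params$length * sin(phi), params$length * cos(phi))
  # chain rule from absolute link angles to relative joint angles:
  # column j of the joint-space Jacobian sums the absolute columns j..3
  cbind(rowSums(j_abs), rowSums(j_abs[, 2:3, drop = FALSE]), j_abs[, 3])
}
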