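#' @title Rigid-body dynamics of the arm on a translating base
#'
#' @description
#' The arm obeys
#' \deqn{I(\theta)\ddot\theta + M(\theta)\ddot X + V(\theta,\dot\theta)
#'       + G(\theta) + D\dot\theta = \tau_{in},}
#' where \eqn{\theta} are the joint angles, \eqn{X} the prescribed shoulder
#' position in the workspace, \eqn{I(\theta)} the joint-space inertia matrix,
#' \eqn{M(\theta)} the base-coupling matrix mapping shoulder acceleration into
#' joint-space generalized forces, \eqn{V} the centripetal/Coriolis vector,
#' \eqn{G} the gravity torque, \eqn{D} the joint viscosity and
#' \eqn{\tau_{in}} the controller torque.
#'
#' The closed forms are derived from the Lagrangian of three planar rigid
#' links whose base translates along an exogenous trajectory. In absolute
#' link angles \eqn{\phi = B\theta} (with \eqn{B} the lower-triangular matrix
#' of ones) the kinetic energy has constant coefficient matrices
#' \eqn{z_{jk} = \sum_{i \ge \max(j,k)} m_i r_{ij} r_{ik}} and
#' \eqn{w_j = \sum_{i \ge j} m_i r_{ij}}, where \eqn{r_{ij}} is the distance
#' from joint \eqn{j} to either the next joint (\eqn{j < i}) or link
#' \eqn{i}'s centre of mass (\eqn{j = i}). The Euler-Lagrange equations then
#' give, in absolute coordinates,
#' \eqn{A_{jk} = z_{jk}\cos(\phi_j-\phi_k) + \delta_{jk} I_k},
#' \eqn{h_j = \sum_k z_{jk}\sin(\phi_j-\phi_k)\dot\phi_k^2},
#' \eqn{M_j = w_j(-\sin\phi_j, \cos\phi_j)} and
#' \eqn{G_j = g\,w_j\cos\phi_j}; each term is pulled back to joint space
#' through \eqn{B^\top(\cdot)B} or \eqn{B^\top(\cdot)}. Base velocity cancels
#' exactly, so the terms depend on the base only through its acceleration.
#'
#' @name arm-dynamics
NULL

# Constant coefficient tables (z, w, B) reused by every dynamics evaluation.
arm_constants <- function(params) {
  m <- params$mass; l <- params$length; lg <- params$com_offset
  r <- rbind(c(lg[1], 0, 0),
             c(l[1], lg[2], 0),
             c(l[1], l[2], lg[3]))
  z <- matrix(0, 3, 3)
  w <- numeric(3)
  for (j in 1:3) {
    for (k in 1:3) {
      i <- max(j, k):3
      z[j, k] <- sum(m[i] * r[i, j] * r[i, k])
    }
    w[j] <- sum(m[j:3] * r[j:3, j])
  }
  B <- matrix(c(1, 0, 0, 1, 1, 0, 1, 1, 1), 3, 3, byrow = TRUE)
  list(z = z, w = w, B = B, inertia = params$inertia, g = params$gravity)
}

dynamics_terms_core <- function(cst, angles, velocities) {
  phi <- cumsum(angles)
  phid <- cumsum(velocities)
  dphi <- outer(phi, phi, "-")
  A <- cst$z * cos(dphi)
  diag(A) <- diag(A) + cst$inertia
  h <- as.vector((cst$z * sin(dphi)) %*% (phid^2))
  Mb <- cbind(-cst$w * sin(phi), cst$w * cos(phi))
  G <- cst$g * cst$w * cos(phi)
  B <- cst$B
  tB <- t(B)
  list(inertia_matrix = tB %*% A %*% B,
       base_coupling = tB %*% Mb,
       coriolis = as.vector(tB %*% h),
       gravity_torque = as.vector(tB %*% G))
}

#' Configuration-dependent terms of the motion equation
#'
#' Evaluates the inertia matrix \eqn{I(\theta)}, base-coupling matrix
#' \eqn{M(\theta)}, centripetal/Coriolis vector \eqn{V(\theta,\dot\theta)}
#' and gravity torque \eqn{G(\theta)} at one arm state. See
#' [arm-dynamics] for the derivation and sign conventions.
#'
#' @param params An [arm_parameters()] object.
#' @param angles Length-3 joint angles, rad.
#' @param velocities Length-3 joint angular velocities, rad/s.
#'
#' @return A list with elements `inertia_matrix` (3x3, kg m^2),
#'   `base_coupling` (3x2, kg m), `coriolis` (length 3, N m) and
#'   `gravity_torque` (length 3, N m).
#' @examples
#' dynamics_terms(arm_parameters(), default_posture(), c(0, 0, 0))
#' @export
dynamics_terms <- function(params, angles, velocities = c(0, 0, 0)) {
  stopifnot(inherits(params, "arm_parameters"),
            length(angles) == 3, length(velocities) == 3)
  if (!all(is.finite(c(angles, velocities)))) {
    stop("arm state must be finite", call. = FALSE)
  }
  dynamics_terms_core(arm_constants(params), angles, velocities)
}

#' Gravity torque at a posture
#'
#' Convenience wrapper returning \eqn{G(\theta)}, used by the controllers'
#' gravity-compensation term.
#'
#' @inheritParams dynamics_terms
#' @return Length-3 numeric, N m.
#' @export
gravity_torque <- function(params, angles) {
  dynamics_terms(params, angles)$gravity_torque
}

#' Forward dynamics
#'
#' Joint angular accelerations produced by an input torque under prescribed
#' base acceleration:
#' \eqn{\ddot\theta = I(\theta)^{-1}(\tau_{in} - M(\theta)\ddot X - V - G - D\dot\theta)}.
#'
#' @inheritParams dynamics_terms
#' @param base_acceleration Length-2 shoulder acceleration, m/s^2.
#' @param torque Length-3 input torque, N m.
#' @param viscosity 3x3 joint viscosity matrix, N m s/rad.
#'
#' @return Length-3 numeric, rad/s^2.
#' @export
forward_dynamics <- function(params, angles, velocities,
                             base_acceleration = c(0, 0),
                             torque = c(0, 0, 0),
                             viscosity = default_viscosity()) {
  stopifnot(length(base_acceleration) == 2, length(torque) == 3)
  if (!all(is.finite(c(angles, velocities, base_acceleration, torque)))) {
    stop("forward_dynamics: non-finite state or torque", call. = FALSE)
  }
  d <- dynamics_terms(params, angles, velocities)
  rhs <- torque - as.vector(d$base_coupling %*% base_acceleration) -
    d$coriolis - d$gravity_torque - as.vector(viscosity %*% velocities)
  as.vector(solve(d$inertia_matrix, rhs))
}
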