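#' Physical parameters of the three-link arm
#'
#' Builds the parameter set describing a three-link arm (upper arm, forearm,
#' hand-plus-cup) moving in the sagittal plane. The defaults are anthropometric
#' estimates for a 172 cm / 64 kg adult; the distal link mass includes a
#' 0.39 kg cup held in the hand.
#'
#' @param mass Numeric length-3, link masses in kg (proximal to distal).
#' @param length Numeric length-3, link lengths in m.
#' @param com_offset Numeric length-3, distance from each link's proximal
#'   joint to its centre of mass, in m. Must satisfy
#'   `0 < com_offset[i] <= length[i]`.
#' @param inertia Numeric length-3, link moments of inertia about each link's
#'   centre of mass, in kg m^2.
#' @param gravity Gravitational acceleration in m/s^2, acting along the
#'   negative vertical axis.
#'
#' @return An object of class `arm_parameters`: a named list with the
#'   validated fields above.
#' @examples
#' p <- arm_parameters()
#' sum(p$length) # full reach, m
#' @export
arm_parameters <- function(mass = c(1.79, 1.02, 0.77),
                           length = c(0.24, 0.22, 0.17),
                           com_offset = c(0.10, 0.09, 0.08),
                           inertia = c(3.00e-2, 1.34e-2, 0.73e-2),
                           gravity = 9.81) {
  stopifnot(
    length(mass) == 3, length(length) == 3,
    length(com_offset) == 3, length(inertia) == 3,
    is.numeric(gravity), length(gravity) == 1
  )
  if (!all(is.finite(c(mass, length, com_offset, inertia, gravity)))) {
    stop("arm parameters must be finite", call. = FALSE)
  }
  if (any(mass <= 0)) stop("link masses must be strictly positive", call. = FALSE)
  if (any(length <= 0)) stop("link lengths must be strictly positive", call. = FALSE)
  if (any(com_offset <= 0) || any(com_offset > length)) {
    stop("com_offset must satisfy 0 < com_offset[i] <= length[i]", call. = FALSE)
  }
  if (any(inertia < 0)) stop("link inertias must be non-negative", call. = FALSE)
  structure(
    list(mass = as.numeric(mass), length = as.numeric(length),
         com_offset = as.numeric(com_offset), inertia = as.numeric(inertia),
         gravity = gravity),
    class = "arm_parameters"
  )
}

#' @export
print.arm_parameters <- function(x, ...) {
  cat("<arm_parameters>\n")
  cat("  mass      [kg]   :", format(x$mass), "\n")
  cat("  length    [m]    :", format(x$length), "\n")
  cat("  com_offset[m]    :", format(x$com_offset), "\n")
  cat("  inertia   [kgm^2]:", format(x$inertia), "\n")
  cat("  gravity   [m/s^2]:", format(x$gravity), "\n")
  invisible(x)
}

#' Default joint viscosity matrix
#'
#' Joint-space damping used by the arm's motion equation. Diagonal entries are
#' the viscosities of the monoarticular muscle groups at the shoulder, elbow
#' and wrist; the single off-diagonal pair couples shoulder and elbow through
#' the biarticular muscles.
#'
#' @return A 3x3 numeric matrix, N m s/rad.
#' @export
default_viscosity <- function() {
  matrix(c(1.5, 0.5, 0,
           0.5, 1.0, 0,
           0, 0, 0.4), nrow = 3, byrow = TRUE,
         dimnames = joint_dimnames())
}

#' Standard joint stiffness matrix
#'
#' Spring-constant matrix of the equilibrium-point controller, based on
#' empirical estimates of multi-joint arm stiffness during posture
#' maintenance. Scalar multiples of this matrix (including zero) represent a
#' subject softening all joints together.
#'
#' @return A 3x3 numeric matrix, N m/rad.
#' @export
default_stiffness <- function() {
  matrix(c(20, 5, 0,
           5, 10, 0,
           0, 0, 5), nrow = 3, byrow = TRUE,
         dimnames = joint_dimnames())
}

joint_dimnames <- function() {
  list(c("shoulder", "elbow", "wrist"), c("shoulder", "elbow", "wrist"))
}

#' Default desired arm posture
#'
#' Joint angles of the cup-holding posture the controllers try to maintain.
#' The convention is: `theta[1]` is the upper-arm angle measured
#' counter-clockwise from the forward horizontal axis, `theta[2]` and
#' `theta[3]` are the relative elbow and wrist angles (positive = flexion that
#' raises the distal link). The default is `(-80, 90, -5)` degrees: upper arm
#' hanging close to vertical, elbow flexed a right angle so the forearm
#' points forward and `10` degrees above horizontal, hand segment tilted
#' slightly down from the forearm — a natural seated cup-holding posture.
#' It is a modelling choice, not a measured value: subject postures vary, and
#' this one was selected from the plausible cup-holding family (see the
#' package vignette) as the representative whose simulated stiffness and
#' damper sweeps show the orderings observed experimentally.
#'
#' @return Numeric length-3, rad.
#' @export
default_posture <- function() {
  deg <- pi / 180
  c(-80, 90, -5) * deg
}

#' Controller gain set
#'
#' Bundles the gains of the equilibrium-point controllers: joint stiffness
#' `K`, joint viscosity `D` (part of the plant's motion equation), the
#' workspace virtual damper `C` of the skyhook term, and the desired posture.
#'
#' @param stiffness 3x3 symmetric positive semi-definite matrix, N m/rad.
#' @param viscosity 3x3 matrix, N m s/rad.
#' @param damper Length-2 numeric, the diagonal of the workspace virtual
#'   damper `C`, N s/m; entries must be non-negative. `c(0, 0)` disables the
#'   skyhook term, making the active controller identical to the passive one.
#' @param posture Length-3 numeric, desired joint angles, rad.
#'
#' @return An object of class `gain_set`.
#' @examples
#' gain_set(damper = c(40, 40))
#' @export
gain_set <- function(stiffness = default_stiffness(),
                     viscosity = default_viscosity(),
                     damper = c(0, 0),
                     posture = default_posture()) {
  stiffness <- as.matrix(stiffness); viscosity <- as.matrix(viscosity)
  stopifnot(identical(dim(stiffness), c(3L, 3L)),
            identical(dim(viscosity), c(3L, 3L)),
            length(damper) == 2, length(posture) == 3)
  if (!all(is.finite(c(stiffness, viscosity, damper, posture)))) {
    stop("gains must be finite", call. = FALSE)
  }
  if (max(abs(stiffness - t(stiffness))) > 1e-9) {
    stop("stiffness matrix must be symmetric", call. = FALSE)
  }
  if (min(eigen(stiffness, symmetric = TRUE, only.values = TRUE)$values) < -1e-9) {
    stop("stiffness matrix must be positive semi-definite", call. = FALSE)
  }
  if (any(damper < 0)) stop("virtual damper entries must be non-negative", call. = FALSE)
  structure(
    list(stiffness = unname(stiffness), viscosity = unname(viscosity),
         damper = as.numeric(damper), posture = as.numeric(posture)),
    class = "gain_set"
  )
}

#' @export
print.gain_set <- function(x, ...) {
  cat("<gain_set>\n")
  cat("  stiffness K [Nm/rad], rows:",
      paste(apply(x$stiffness, 1, function(r) paste0("(", paste(r, collapse = ", "), ")")),
            collapse = " "), "\n")
  cat("  damper C diag [Ns/m]:", format(x$damper), "\n")
  cat("  posture [deg]:", format(round(x$posture * 180 / pi, 1)), "\n")
  invisible(x)
}

#' Sinusoidal base-oscillation specification
#'
#' The shoulder base translates horizontally as
#' `x(t) = amplitude * sin(2 * pi * frequency * t + phase)`; the vertical
#' component is identically zero.
#'
#' @param amplitude Oscillation amplitude in m (half the peak-to-peak range).
#' @param frequency Oscillation frequency in Hz.
#' @param phase Phase offset in rad at `t = 0`.
#'
#' @return An object of class `oscillation_spec`.
#' @export
oscillation_spec <- function(amplitude = 0.03, frequency = 1.09, phase = 0) {
  stopifnot(is.numeric(amplitude), is.numeric(frequency), is.numeric(phase))
  if (amplitude < 0) stop("amplitude must be non-negative", call. = FALSE)
  if (frequency <= 0) stop("frequency must be strictly positive", call. = FALSE)
  structure(list(amplitude = amplitude, frequency = frequency, phase = phase),
            class = "oscillation_spec")
}

#' Simulation plan
#'
#' Time-stepping configuration for [simulate_arm()]: fixed step `dt`, total
#' duration, and the steady-state analysis window (the initial transient
#' before the window is discarded by the analysis).
#'
#' @param dt Integration and sampling step, s.
#' @param duration Total simulated time, s.
#' @param steady_window Length-2 numeric, start and end of the steady-state
#'   window in s; must lie within `[0, duration]`.
#' @param controller `"passive"` or `"active"`. The passive controller is the
#'   stiffness + gravity-compensation law; the active controller adds the
#'   skyhook virtual-damper torque.
#' @param initial_angles Initial joint angles, rad; defaults to the gain set's
#'   desired posture when `NULL`.
#' @param initial_velocities Initial joint angular velocities, rad/s.
#'
#' @return An object of class `simulation_plan`.
#' @export
simulation_plan <- function(dt = 0.01, duration = 100,
                            steady_window = c(30, 90),
                            controller = c("active", "passive"),
                            initial_angles = NULL,
                            initial_velocities = c(0, 0, 0)) {
  controller <- match.arg(controller)
  stopifnot(dt > 0, duration > 0, length(steady_window) == 2,
            length(initial_velocities) == 3)
  if (steady_window[1] < 0 || steady_window[2] > duration ||
      steady_window[1] >= steady_window[2]) {
    stop("steady_window must be an increasing interval within [0, duration]",
         call. = FALSE)
  }
  if (!is.null(initial_angles)) stopifnot(length(initial_angles) == 3)
  structure(
    list(dt = dt, duration = duration, steady_window = as.numeric(steady_window),
         controller = controller,
         initial_angles = if (is.null(initial_angles)) NULL else as.numeric(initial_angles),
         initial_velocities = as.numeric(initial_velocities)),
    class = "simulation_plan"
  )
}

#' Marker-noise specification for synthetic motion-capture data
#'
#' Describes the additive measurement noise of the synthetic marker generator:
#' independent zero-mean Gaussian noise on every recorded coordinate, with a
#' standard deviation typical of optical marker systems (0.5 mm).
#'
#' @param noise_sd Noise standard deviation, m.
#' @param seed Integer seed making the generated table reproducible.
#' @param rate Sampling rate, Hz.
#' @param duration Recording duration, s.
#'
#' @return An object of class `marker_noise_spec`.
#' @export
marker_noise_spec <- function(noise_sd = 5e-4, seed = 1L, rate = 100,
                              duration = 120) {
  stopifnot(noise_sd >= 0, rate > 0, duration > 0)
  structure(list(noise_sd = noise_sd, seed = as.integer(seed),
                 rate = rate, duration = duration),
            class = "marker_noise_spec")
}
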