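#' Base motion at given times
#'
#' Analytic position, velocity and acceleration of the sinusoidally
#' oscillating shoulder base. The vertical components are identically zero.
#'
#' @param spec An [oscillation_spec()].
#' @param t Numeric vector of times, s.
#'
#' @return A tibble with columns `time`, `x`, `y`, `vx`, `vy`, `ax`, `ay`.
#' @examples
#' base_motion(oscillation_spec(), c(0, 0.25, 0.5))
#' @export
base_motion <- function(spec, t) {
  stopifnot(inherits(spec, "oscillation_spec"))
  om <- 2 * pi * spec$frequency
  ph <- om * t + spec$phase
  tibble::tibble(
    time = t,
    x = spec$amplitude * sin(ph), y = 0,
    vx = spec$amplitude * om * cos(ph), vy = 0,
    ax = -spec$amplitude * om^2 * sin(ph), ay = 0
  )
}

#' Simulate the controlled arm under base oscillation
#'
#' Integrates the arm's motion equation with classic fixed-step fourth-order
#' Runge-Kutta. The controller torque and the analytic base motion are
#' re-evaluated at every internal Runge-Kutta stage (continuous control, no
#' zero-order hold), so the scheme retains its fourth-order accuracy. The
#' run is fully deterministic.
#'
#' @param params An [arm_parameters()] object.
#' @param gains A [gain_set()] object. With `plan$controller = "passive"` the
#'   damper is ignored; with `"active"` the skyhook term uses
#'   `gains$damper`.
#' @param spec An [oscillation_spec()] describing the base motion.
#' @param plan A [simulation_plan()]. When `plan$initial_angles` is `NULL`
#'   the arm starts at rest in the desired posture.
#'
#' @return An `arm_trajectory`: a tibble with one row per sample and columns
#'   `time`; `shoulder_x/y`, `elbow_x/y`, `wrist_x/y`, `hand_x/y` (m);
#'   `theta1..3` (rad); `omega1..3` (rad/s); `tau1..3` (N m). The
#'   oscillation spec, plan and gains travel along as attributes.
#' @examples
#' traj <- simulate_arm(plan = simulation_plan(duration = 2))
#' dplyr::glimpse(traj)
#' @export
simulate_arm <- function(params = arm_parameters(),
                         gains = gain_set(),
                         spec = oscillation_spec(),
                         plan = simulation_plan()) {
  stopifnot(inherits(params, "arm_parameters"), inherits(gains, "gain_set"),
            inherits(spec, "oscillation_spec"), inherits(plan, "simulation_plan"))
  cst <- arm_constants(params)
  l <- params$length
  K <- gains$stiffness
  thd <- gains$posture
  gd <- dynamics_terms_core(cst, thd, c(0, 0, 0))$gravity_torque
  Dv <- gains$viscosity
  damper <- if (plan$controller == "active") gains$damper else c(0, 0)
  use_skyhook <- any(damper != 0)
  A <- spec$amplitude; om <- 2 * pi * spec$frequency; ph0 <- spec$phase

  control <- function(th, thv, base_vel) {
    tau <- as.vector(-K %*% (th - thd)) + gd
    if (use_skyhook) {
      phi <- cumsum(th)
      j_abs <- rbind(-l * sin(phi), l * cos(phi))
      J <- cbind(rowSums(j_abs), j_abs[, 2] + j_abs[, 3], j_abs[, 3])
      xdot <- as.vector(J %*% thv) + base_vel
      tau <- tau - as.vector(t(J) %*% (damper * xdot))
    }
    tau
  }
  step_k <- 0L
  deriv <- function(t, y) {
    if (!all(is.finite(y))) {
      stop(sprintf("simulate_arm: state diverged at step %d (t = %.3f s)",
                   step_k + 1L, t), call. = FALSE)
    }
    th <- y[1:3]; thv <- y[4:6]
    s <- om * t + ph0
    vel <- c(A * om * cos(s), 0)
    acc <- c(-A * om^2 * sin(s), 0)
    tau <- control(th, thv, vel)
    d <- dynamics_terms_core(cst, th, thv)
    rhs <- tau - as.vector(d$base_coupling %*% acc) - d$coriolis -
      d$gravity_torque - as.vector(Dv %*% thv)
    c(thv, solve(d$inertia_matrix, rhs))
  }

  n <- round(plan$duration / plan$dt)
  dt <- plan$dt
  th0 <- if (is.null(plan$initial_angles)) thd else plan$initial_angles
  y <- c(th0, plan$initial_velocities)
  out <- matrix(NA_real_, n + 1, 18)
  for (k in 0:n) {
    t <- k * dt
    th <- y[1:3]
    phi <- cumsum(th)
    bx <- A * sin(om * t + ph0)
    ex <- bx + l[1] * cos(phi[1]); ey <- l[1] * sin(phi[1])
    wx <- ex + l[2] * cos(phi[2]); wy <- ey + l[2] * sin(phi[2])
    hx <- wx + l[3] * cos(phi[3]); hy <- wy + l[3] * sin(phi[3])
    tau <- control(th, y[4:6], c(A * om * cos(om * t + ph0), 0))
    out[k + 1, ] <- c(t, bx, 0, ex, ey, wx, wy, hx, hy, th, y[4:6], tau)
    if (k < n) {
      step_k <- k
      k1 <- deriv(t, y)
      k2 <- deriv(t + dt / 2, y + dt / 2 * k1)
      k3 <- deriv(t + dt / 2, y + dt / 2 * k2)
      k4 <- deriv(t + dt, y + dt * k3)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!all(is.finite(y))) {
        stop(sprintf("simulate_arm: state diverged at step %d (t = %.3f s)",
                     k + 1, t + dt), call. = FALSE)
      }
    }
  }
  colnames(out) <- c("time", "shoulder_x", "shoulder_y", "elbow_x", "elbow_y",
                     "wrist_x", "wrist_y", "hand_x", "hand_y",
                     "theta1", "theta2", "theta3",
                     "omega1", "omega2", "omega3", "tau1", "tau2", "tau3")
  traj <- tibble::as_tibble(out)
  attr(traj, "oscillation") <- spec
  attr(traj, "plan") <- plan
  attr(traj, "gains") <- gains
  class(traj) <- c("arm_trajectory", class(traj))
  traj
}

#' @export
print.arm_trajectory <- function(x, ...) {
  spec <- attr(x, "oscillation")
  plan <- attr(x, "plan")
  cat(sprintf("<arm_trajectory> %d samples at dt = %g s, %s controller, drive %g m @ %g Hz\n",
              nrow(x), plan$dt, plan$controller, spec$amplitude, spec$frequency))
  NextMethod()
}

#' Extract one arm part's positions from a trajectory table
#'
#' @param traj A trajectory or marker table containing `<part>_x` and
#'   `<part>_y` columns.
#' @param part One of `"shoulder"`, `"elbow"`, `"wrist"`, `"hand"`.
#' @return A two-column numeric matrix (x, y), m.
#' @export
part_positions <- function(traj, part = c("hand", "shoulder", "elbow", "wrist")) {
  part <- match.arg(part)
  cols <- paste0(part, c("_x", "_y"))
  if (!all(cols %in% names(traj))) {
    stop("trajectory table lacks columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  cbind(x = traj[[cols[1]]], y = traj[[cols[2]]])
}
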