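test_that("forward kinematics places joints at link-vector sums", {
  p <- test_params()
  # fully extended along the horizontal from the origin
  pts <- forward_kinematics(p, c(0, 0, 0), c(0, 0))
  expect_equal(unname(pts["hand", ]), c(sum(p$length), 0))
  expect_equal(unname(pts["elbow", ]), c(p$length[1], 0))

  # rigid translation of the base translates every point identically
  pts2 <- forward_kinematics(p, c(0, 0, 0), c(0.03, 0))
  expect_equal(pts2, pts + rep(c(0.03, 0), each = 4))

  # consecutive-joint distances equal link lengths for random angles
  set.seed(11)
  for (i in 1:20) {
    st <- random_state()
    pts <- forward_kinematics(p, st$angles, runif(2, -1, 1))
    d <- sqrt(rowSums(diff(pts)^2))
    expect_equal(unname(d), p$length, tolerance = 1e-12)
  }
})

test_that("hand Jacobian matches finite differences of forward kinematics", {
  p <- test_params()

  # rigid rotation about the base: fully extended arm, shoulder velocity only
  J <- hand_jacobian(p, c(0, 0, 0))
  v <- J %*% c(1, 0, 0)
  expect_equal(as.vector(v), c(0, sum(p$length)))

  set.seed(21)
  for (i in 1:20) {
    th <- runif(3, -pi, pi)
    J <- hand_jacobian(p, th)
    eps <- 1e-6
    J_fd <- sapply(1:3, function(j) {
      e <- rep(0, 3); e[j] <- eps
      (forward_kinematics(p, th + e)["hand", ] -
         forward_kinematics(p, th - e)["hand", ]) / (2 * eps)
    })
    expect_lt(max(abs(J - J_fd)) / max(abs(J)), 1e-6)
  }
})

test_that("gravity torque and Coriolis vanish where they must", {
  p <- test_params()
  # all links hanging straight down: zero moment arm about every joint
  d <- dynamics_terms(p, hanging_posture(), c(0, 0, 0))
  expect_equal(d$gravity_torque, c(0, 0, 0), tolerance = 1e-12)
  # zero velocity kills the centripetal/Coriolis vector at any posture
  set.seed(5)
  for (i in 1:10) {
    d <- dynamics_terms(p, runif(3, -pi, pi), c(0, 0, 0))
    expect_equal(d$coriolis, c(0, 0, 0))
  }
})

test_that("inertia matrix is symmetric positive definite across configurations", {
  p <- test_params()
  set.seed(31)
  for (i in 1:1000) {
    I <- dynamics_terms(p, runif(3, -pi, pi), c(0, 0, 0))$inertia_matrix
    expect_lt(max(abs(I - t(I))), 1e-12)
    expect_gt(min(eigen(I, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("closed-form dynamics agree with the Euler-Lagrange oracle", {
  p <- test_params()
  set.seed(101)
  base <- oracle_sine_base(0.05, 1.3)
  for (i in 1:100) {
    traj <- oracle_random_trajectory()
    t0 <- runif(1, 0.1, 2)
    Q_oracle <- oracle_generalized_force(p, traj, base, t0)
    d <- dynamics_terms(p, traj$th(t0), traj$thd(t0))
    Q_closed <- as.vector(d$inertia_matrix %*% traj$thdd(t0)) +
      as.vector(d$base_coupling %*% base$acc(t0)) +
      d$coriolis + d$gravity_torque
    expect_lt(max(abs(Q_oracle - Q_closed)) / max(abs(Q_closed)), 1e-8)
  }
})

test_that("forward dynamics satisfies the defining identity and statics", {
  p <- test_params()
  # static equilibrium: gravity-compensating torque, zero velocity, still base
  th <- default_posture()
  acc <- forward_dynamics(p, th, c(0, 0, 0), c(0, 0),
                          torque = gravity_torque(p, th))
  expect_equal(acc, c(0, 0, 0), tolerance = 1e-12)

  # residual of the motion equation is zero at the returned acceleration
  set.seed(41)
  for (i in 1:20) {
    st <- random_state()
    tau <- runif(3, -5, 5)
    xdd <- runif(2, -2, 2)
    thdd <- forward_dynamics(p, st$angles, st$velocities, xdd, tau)
    d <- dynamics_terms(p, st$angles, st$velocities)
    resid <- d$inertia_matrix %*% thdd + d$base_coupling %*% xdd +
      d$coriolis + d$gravity_torque +
      default_viscosity() %*% st$velocities - tau
    expect_lt(max(abs(resid)), 1e-10)
  }

  expect_error(forward_dynamics(p, c(NA, 0, 0), c(0, 0, 0)), "non-finite")
  expect_error(forward_dynamics(p, c(0, 0, 0), c(0, 0, 0), torque = c(Inf, 0, 0)),
               "non-finite")
})

test_that("mechanical energy is conserved with dissipation and input removed", {
  p <- test_params()
  gains <- gain_set(stiffness = zero_matrix(), viscosity = zero_matrix(),
                    damper = c(0, 0), posture = hanging_posture())
  # hanging posture has zero gravity torque, so the passive law outputs
  # exactly zero torque at K = 0: a free conservative system
  plan <- simulation_plan(dt = 1e-4, duration = 1, steady_window = c(0, 1),
                          controller = "passive",
                          initial_angles = c(-1.2, 0.5, 0.3),
                          initial_velocities = c(0.5, -0.4, 0.8))
  traj <- simulate_arm(p, gains, oscillation_spec(amplitude = 0), plan)
  state_at <- function(i) {
    list(th = unlist(traj[i, c("theta1", "theta2", "theta3")], use.names = FALSE),
         thd = unlist(traj[i, c("omega1", "omega2", "omega3")], use.names = FALSE))
  }
  n <- nrow(traj)
  s0 <- state_at(1); s1 <- state_at(n)
  expect_lt(abs(oracle_energy(p, s1$th, s1$thd) -
                  oracle_energy(p, s0$th, s0$thd)), 1e-6)
})

test_that("parameter validation rejects unphysical arms", {
  expect_error(arm_parameters(mass = c(-1, 1, 1)), "positive")
  expect_error(arm_parameters(com_offset = c(0.3, 0.09, 0.08)), "com_offset")
  expect_error(arm_parameters(gravity = NaN), "finite")
})
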