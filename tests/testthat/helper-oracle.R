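# Independent dynamics oracle used to verify the closed-form terms.
#
# The Lagrangian is assembled by brute force from per-link centre-of-mass
# positions/velocities (plain chain-rule accumulation, no z/w coefficient
# tables, no Euler-Lagrange algebra). Generalized forces are then obtained
# numerically: complex-step differentiation for the exact partial gradients
# of L, and a five-point central stencil in time for d/dt(dL/dqdot).

# Per-link COM position and velocity, complex-safe (all operations analytic).
oracle_links <- function(params, th, thd, base_pos, base_vel) {
  phi <- cumsum(th); phid <- cumsum(thd)
  l <- params$length; lg <- params$com_offset
  p <- base_pos; v <- base_vel
  com <- vector("list", 3); vcom <- vector("list", 3)
  for (i in 1:3) {
    e <- c(cos(phi[i]), sin(phi[i]))
    ep <- c(-sin(phi[i]), cos(phi[i]))
    com[[i]] <- p + lg[i] * e
    vcom[[i]] <- v + lg[i] * phid[i] * ep
    p <- p + l[i] * e
    v <- v + l[i] * phid[i] * ep
  }
  list(com = com, vcom = vcom, phid = phid)
}

oracle_lagrangian <- function(params, th, thd, base_pos, base_vel) {
  lk <- oracle_links(params, th, thd, base_pos, base_vel)
  m <- params$mass; Ic <- params$inertia; g <- params$gravity
  Tk <- 0; V <- 0
  for (i in 1:3) {
    Tk <- Tk + 0.5 * m[i] * sum(lk$vcom[[i]]^2) + 0.5 * Ic[i] * lk$phid[i]^2
    V <- V + m[i] * g * lk$com[[i]][2]
  }
  Tk - V
}

oracle_energy <- function(params, th, thd, base_vel = c(0, 0)) {
  lk <- oracle_links(params, th, thd, c(0, 0), base_vel)
  m <- params$mass; Ic <- params$inertia; g <- params$gravity
  Tk <- 0; V <- 0
  for (i in 1:3) {
    Tk <- Tk + 0.5 * m[i] * sum(lk$vcom[[i]]^2) + 0.5 * Ic[i] * lk$phid[i]^2
    V <- V + m[i] * g * lk$com[[i]][2]
  }
  Tk + V
}

# exact partial derivatives of L via complex step (h = 1e-20, no cancellation)
oracle_dL <- function(params, th, thd, base_pos, base_vel, wrt = c("th", "thd")) {
  wrt <- match.arg(wrt)
  h <- 1e-20
  vapply(1:3, function(j) {
    e <- complex(real = rep(0, 3)); e[j] <- complex(imaginary = h)
    val <- if (wrt == "th") {
      oracle_lagrangian(params, th + e, thd + 0i, base_pos + 0i, base_vel + 0i)
    } else {
      oracle_lagrangian(params, th + 0i, thd + e, base_pos + 0i, base_vel + 0i)
    }
    Im(val) / h
  }, numeric(1))
}

# Generalized force Q(t0) = d/dt dL/dthd - dL/dth along a smooth test
# trajectory. `traj` supplies th(t), thd(t) analytically; `base` supplies
# base position/velocity analytically.
oracle_generalized_force <- function(params, traj, base, t0, h = 1e-3) {
  p_of_t <- function(t) {
    oracle_dL(params, traj$th(t), traj$thd(t), base$pos(t), base$vel(t), "thd")
  }
  dp <- (-p_of_t(t0 + 2 * h) + 8 * p_of_t(t0 + h) -
           8 * p_of_t(t0 - h) + p_of_t(t0 - 2 * h)) / (12 * h)
  dp - oracle_dL(params, traj$th(t0), traj$thd(t0), base$pos(t0),
                 base$vel(t0), "th")
}

# random smooth test trajectory with analytic derivatives
oracle_random_trajectory <- function() {
  a <- runif(3, -1.2, 1.2); b <- runif(3, -1, 1)
  cc <- runif(3, -0.8, 0.8); amp <- runif(3, -0.4, 0.4)
  om <- runif(3, 1, 3)
  list(
    th = function(t) a + b * t + cc * t^2 + amp * sin(om * t),
    thd = function(t) b + 2 * cc * t + amp * om * cos(om * t),
    thdd = function(t) 2 * cc - amp * om^2 * sin(om * t)
  )
}

oracle_sine_base <- function(A = 0.03, f = 1.09) {
  om <- 2 * pi * f
  list(pos = function(t) c(A * sin(om * t), 0),
       vel = function(t) c(A * om * cos(om * t), 0),
       acc = function(t) c(-A * om^2 * sin(om * t), 0))
}
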