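# shared defaults for the test suite
test_params <- function() arm_parameters()

random_state <- function() {
  list(angles = runif(3, -pi, pi), velocities = runif(3, -3, 3))
}

# posture whose links all hang straight down: zero gravity torque
hanging_posture <- function() c(-pi / 2, 0, 0)

zero_matrix <- function() matrix(0, 3, 3)

# amplitude of a sinusoid at known frequency, by least squares on a
# sin/cos basis (robust to phase shifts)
fitted_amplitude <- function(x, t, freq) {
  X <- cbind(1, sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- qr.solve(X, x)
  sqrt(cf[2]^2 + cf[3]^2)
}
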