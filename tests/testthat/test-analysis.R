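rate <- 100
t_long <- seq(0, 60, by = 1 / rate)

test_that("zero-phase low-pass keeps DC and the passband, rejects the stopband", {
  # constant series: DC gain exactly 1
  expect_equal(lowpass(rep(2.5, 500), 5, rate), rep(2.5, 500))

  # single-pass 2nd-order Butterworth magnitude; filtfilt applies it twice
  mag2 <- function(f, fc = 5) 1 / (1 + (f / fc)^4)

  x <- sin(2 * pi * 1.09 * t_long)
  amp <- fitted_amplitude(lowpass(x, 5, rate), t_long, 1.09)
  expect_gt(amp, 0.99)            # passband: amplitude preserved within 1%
  expect_lt(abs(amp - mag2(1.09)), 0.01)

  x20 <- sin(2 * pi * 20 * t_long)
  amp20 <- fitted_amplitude(lowpass(x20, 5, rate), t_long, 20)
  expect_lt(amp20, mag2(20) + 0.01)

  expect_error(lowpass(rep(1, 10), 5, rate), "short")
  expect_error(lowpass(x, 60, rate))
})

test_that("jerk of a cubic is its constant third derivative", {
  a3 <- 0.4
  pos <- cbind(a3 * t_long^3 - 0.2 * t_long^2 + 0.05 * t_long + 1, 0 * t_long)
  js <- jerk_series(pos, rate = rate, cutoff = 5)
  interior <- js$jerk[500:5500, 1]
  expect_equal(mean(interior), 6 * a3, tolerance = 1e-6)
  expect_lt(diff(range(interior)), 1e-5)
})

test_that("jerk of a passband sinusoid has amplitude A * omega^3", {
  A <- 0.03; f <- 1.09; om <- 2 * pi * f
  pos <- cbind(A * sin(om * t_long), 0 * t_long)
  js <- jerk_series(pos, rate = rate, cutoff = 5)
  sel <- 500:5500
  amp <- fitted_amplitude(js$jerk[sel, 1], t_long[js$index][sel], f)
  expect_lt(abs(amp - A * om^3) / (A * om^3), 0.02)

  # constant position: zero jerk
  js0 <- jerk_series(cbind(rep(1, 1000), rep(-2, 1000)), rate = rate)
  expect_lt(max(abs(js0$jerk)), 1e-9)
})

test_that("mean sum of squared jerk matches the closed form for a sinusoid", {
  A <- 0.03; f <- 1.09; om <- 2 * pi * f
  pos <- cbind(A * sin(om * t_long), 0 * t_long)
  js <- jerk_series(pos, rate = rate, cutoff = 5)
  tj <- t_long[js$index]
  mssj <- mean_sum_squared_jerk(js$jerk, tj, c(5, 55))
  # time-average of (A w^3 cos)^2 = A^2 w^6 / 2
  expect_lt(abs(mssj - A^2 * om^6 / 2) / (A^2 * om^6 / 2), 0.03)

  # homogeneity: doubling the amplitude quadruples the metric
  js2 <- jerk_series(2 * pos, rate = rate, cutoff = 5)
  mssj2 <- mean_sum_squared_jerk(js2$jerk, tj, c(5, 55))
  expect_equal(mssj2 / mssj, 4, tolerance = 1e-9)

  expect_equal(mean_sum_squared_jerk(matrix(0, 100, 2), 1:100, c(10, 50)), 0)
  expect_error(mean_sum_squared_jerk(js$jerk, tj, c(100, 200)), "empty")
})

test_that("cycle averaging recovers the periodic component", {
  f <- 1.09; period <- 1 / f
  sig <- function(t) cbind(0.02 * sin(2 * pi * f * t),
                           0.005 * cos(4 * pi * f * t))
  # perfectly periodic input: the mean cycle equals any single cycle
  mc <- cycle_average(sig(t_long), t_long, f, c(5, 55))
  phase <- seq(0, period, length.out = 65)[1:64]
  expect_lt(max(abs(mc - sig(5 + phase))), 1e-4)

  # constant input: constant mean cycle
  mc0 <- cycle_average(cbind(rep(1, length(t_long)), rep(2, length(t_long))),
                       t_long, f, c(5, 55))
  expect_equal(mc0, cbind(rep(1, 64), rep(2, 64)))

  # zero-mean noise shrinks roughly as 1/sqrt(n_cycles)
  set.seed(99)
  sd_n <- 5e-4
  noisy <- sig(t_long) + matrix(rnorm(2 * length(t_long), sd = sd_n), ncol = 2)
  mcn <- cycle_average(noisy, t_long, f, c(0.5, 56))  # ~60 cycles
  rmse <- sqrt(mean((mcn - sig(0.5 + phase))^2))
  expect_lt(rmse, 3 * sd_n / sqrt(60))
  expect_gt(rmse, 0.3 * sd_n / sqrt(60))

  expect_error(cycle_average(sig(t_long), t_long, f, c(5, 7)), "5 drive cycles")
})

test_that("trajectory amplitude is half the peak-to-peak range per direction", {
  f <- 1.09
  drive <- cbind(0.03 * sin(2 * pi * f * t_long), 0 * t_long)
  mc <- cycle_average(drive, t_long, f, c(5, 55))
  amp <- trajectory_amplitude(mc)
  expect_equal(amp$amplitude[amp$direction == "horizontal"], 0.03,
               tolerance = 1e-3)
  expect_equal(amp$amplitude[amp$direction == "vertical"], 0)
  expect_equal(amp$peak_to_peak, amp$amplitude * 2)

  expect_equal(trajectory_amplitude(cbind(rep(1, 10), rep(2, 10)))$amplitude,
               c(0, 0))
  th <- seq(0, 2 * pi, length.out = 101)  # grid hits all four extremes exactly
  expect_equal(trajectory_amplitude(0.07 * cbind(cos(th), sin(th)))$amplitude,
               c(0.07, 0.07))
})

test_that("the pipeline is translation invariant and scales correctly", {
  plan <- simulation_plan(duration = 30, steady_window = c(10, 28))
  traj <- simulate_arm(gains = gain_set(damper = c(40, 40)), plan = plan)
  m0 <- analyze_trajectory(traj)

  shifted <- traj
  for (cc in grep("_x$", names(traj), value = TRUE)) shifted[[cc]] <- traj[[cc]] + 0.5
  for (cc in grep("_y$", names(traj), value = TRUE)) shifted[[cc]] <- traj[[cc]] - 0.2
  m1 <- analyze_trajectory(shifted)
  expect_equal(m1$jerk$mean_squared_jerk, m0$jerk$mean_squared_jerk,
               tolerance = 1e-10)
  expect_equal(m1$amplitude$amplitude, m0$amplitude$amplitude, tolerance = 1e-10)

  scaled <- traj
  for (cc in grep("_(x|y)$", names(traj), value = TRUE)) scaled[[cc]] <- 3 * traj[[cc]]
  m3 <- analyze_trajectory(scaled)
  expect_equal(m3$amplitude$amplitude, 3 * m0$amplitude$amplitude,
               tolerance = 1e-10)
  expect_equal(m3$jerk$mean_squared_jerk, 9 * m0$jerk$mean_squared_jerk,
               tolerance = 1e-10)
})

test_that("analysis applied to the simulated shoulder recovers the drive metrics", {
  plan <- simulation_plan(duration = 60, steady_window = c(10, 55))
  traj <- simulate_arm(plan = plan)
  m <- analyze_trajectory(traj)
  A <- 0.03; om <- 2 * pi * 1.09
  shoulder <- m$jerk$mean_squared_jerk[m$jerk$part == "shoulder"]
  expect_lt(abs(shoulder - A^2 * om^6 / 2) / (A^2 * om^6 / 2), 0.03)
  mc_sh <- cycle_average(part_positions(traj, "shoulder"), traj$time, 1.09,
                         c(10, 55))
  amp_sh <- trajectory_amplitude(mc_sh)$amplitude[1]
  expect_lt(abs(amp_sh - A) / A, 0.01)
})
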