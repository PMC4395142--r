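#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth low-pass applied forward and backward, giving
#' zero phase distortion — important here because jerk and amplitude metrics
#' are compared across arm parts, and a phase-shifting filter would misalign
#' them. The effective magnitude response is the square of the single-pass
#' Butterworth response.
#'
#' Edge transients are controlled the way scientific signal pipelines
#' usually do it: the series is extended by odd (antisymmetric) reflection
#' at both ends and each pass is initialized at the local signal level, so a
#' constant series passes through exactly unchanged and edges carry no
#' filter ringing.
#'
#' @param x Numeric vector or matrix (columns filtered independently),
#'   uniformly sampled.
#' @param cutoff Cut-off frequency, Hz.
#' @param rate Sampling rate, Hz; must exceed `2 * cutoff`.
#' @param order Filter order of each pass (default 2).
#'
#' @return Filtered data with the same shape as `x`.
#' @export
lowpass <- function(x, cutoff = 5, rate = 100, order = 2) {
  stopifnot(rate > 2 * cutoff, cutoff > 0)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  pad <- min(n - 1, max(9, ceiling(3 * rate / cutoff)))
  if (n < 9 * (order + 1)) {
    stop("lowpass: series too short for stable zero-phase filtering",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  one_pass <- function(v) {
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1], order),
                              init.y = rep(v[1], order)))
  }
  ff <- function(v) {
    vp <- c(2 * v[1] - v[(pad + 1):2], v, 2 * v[n] - v[(n - 1):(n - pad)])
    y <- one_pass(vp)
    y <- rev(one_pass(rev(y)))
    y[(pad + 1):(pad + n)]
  }
  if (is.matrix(x)) apply(x, 2, ff) else ff(x)
}

central_diff <- function(x, dt) {
  n <- nrow(x)
  (x[c(2:n, n), , drop = FALSE] - x[c(1, 1:(n - 1)), , drop = FALSE]) / (2 * dt)
}

#' Jerk of a position time series
#'
#' Third time-derivative of position, computed the way motion-capture
#' kinematics are conventionally processed: the positions are zero-phase
#' low-pass filtered, differentiated three times by central first
#' differences (exact for cubic trajectories), and the differentiated series
#' is low-pass filtered again. The three samples at each edge, where the
#' difference stencil is incomplete, are trimmed.
#'
#' @param positions Numeric matrix `[T x 2]` of x/y positions, m, uniformly
#'   sampled.
#' @param rate Sampling rate, Hz.
#' @param cutoff Low-pass cut-off, Hz.
#'
#' @return A list: `jerk`, a `[T' x 2]` matrix in m/s^3, and `index`, the
#'   rows of `positions` the jerk samples correspond to (edges trimmed).
#' @export
jerk_series <- function(positions, rate = 100, cutoff = 5) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2)
  n <- nrow(positions)
  if (n < 50) stop("jerk_series: series too short", call. = FALSE)
  dt <- 1 / rate
  x <- lowpass(positions, cutoff, rate)
  for (i in 1:3) x <- central_diff(x, dt)
  keep <- 4:(n - 3)
  jk <- lowpass(x[keep, , drop = FALSE], cutoff, rate)
  list(jerk = jk, index = keep)
}

#' Mean sum of squared jerk over a window
#'
#' Time-average of \eqn{j_x^2 + j_y^2} over the steady-state window — the
#' vibration metric used to compare arm parts.
#'
#' @param jerk Numeric matrix `[T' x 2]`, m/s^3.
#' @param time Numeric vector of the jerk samples' times, s.
#' @param window Length-2 numeric, window start and end, s.
#'
#' @return A scalar, m^2/s^6.
#' @export
mean_sum_squared_jerk <- function(jerk, time, window) {
  jerk <- as.matrix(jerk)
  stopifnot(nrow(jerk) == length(time), length(window) == 2)
  sel <- time >= window[1] & time <= window[2]
  if (!any(sel)) stop("mean_sum_squared_jerk: empty window", call. = FALSE)
  mean(rowSums(jerk[sel, , drop = FALSE]^2))
}

#' Phase-locked cycle average
#'
#' Splits the steady-state window into consecutive periods of the drive
#' oscillation (phase-locked to the known drive frequency, no event
#' detection), resamples each cycle onto a common phase grid by linear
#' interpolation, and averages pointwise. Averaging over many cycles
#' suppresses components that are not phase-locked to the drive (noise,
#' residual transients).
#'
#' @param positions Numeric matrix `[T x 2]`, m.
#' @param time Numeric vector of sample times, s.
#' @param frequency Drive frequency, Hz.
#' @param window Length-2 numeric window, s; must span at least 5 cycles.
#' @param n_phase Number of phase-grid points per cycle.
#'
#' @return A `[n_phase x 2]` matrix: the mean one-cycle trajectory, m.
#' @export
cycle_average <- function(positions, time, frequency, window,
                          n_phase = 64) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(time), length(window) == 2)
  period <- 1 / frequency
  t0 <- window[1]
  n_cycles <- floor((window[2] - window[1]) / period)
  if (n_cycles < 5) {
    stop("cycle_average: window must span at least 5 drive cycles",
         call. = FALSE)
  }
  phase <- seq(0, period, length.out = n_phase + 1)[seq_len(n_phase)]
  acc <- matrix(0, n_phase, 2)
  for (c_i in seq_len(n_cycles) - 1) {
    tq <- t0 + c_i * period + phase
    acc <- acc + cbind(approx(time, positions[, 1], xout = tq)$y,
                       approx(time, positions[, 2], xout = tq)$y)
  }
  acc / n_cycles
}

#' Amplitude of a mean one-cycle trajectory
#'
#' Per direction, half the peak-to-peak range of the mean cycle — the same
#' convention in which a sinusoidal drive `A sin(wt)` has amplitude `A`.
#' (The full peak-to-peak range is also returned for reference.)
#'
#' @param cycle Numeric matrix `[Tc x 2]`, m.
#'
#' @return A tibble with columns `direction` (`"horizontal"`, `"vertical"`),
#'   `amplitude` (half peak-to-peak, m) and `peak_to_peak` (m).
#' @export
trajectory_amplitude <- function(cycle) {
  cycle <- as.matrix(cycle)
  stopifnot(ncol(cycle) == 2, nrow(cycle) >= 1)
  rng <- apply(cycle, 2, function(v) diff(range(v)))
  tibble::tibble(
    direction = c("horizontal", "vertical"),
    amplitude = rng / 2,
    peak_to_peak = rng
  )
}

#' Full kinematic evaluation of a trajectory
#'
#' Runs the complete evaluation pipeline on a simulated or measured
#' trajectory table: for every available arm part, zero-phase filtering,
#' third-difference jerk and the steady-window mean sum of squared jerk; for
#' the hand, additionally the phase-locked mean one-cycle trajectory and its
#' horizontal/vertical amplitudes. Simulated and measured data go through
#' the identical code path, which is what makes their metrics comparable.
#'
#' @param traj A data frame with a `time` column and `<part>_x`/`<part>_y`
#'   position columns for at least one of shoulder, elbow, wrist, hand (as
#'   produced by [simulate_arm()] or [generate_markers()]).
#' @param rate Sampling rate, Hz.
#' @param cutoff Low-pass cut-off, Hz.
#' @param frequency Drive frequency used for phase-locked cycle averaging,
#'   Hz; taken from the trajectory's oscillation attribute when `NULL`.
#' @param window Steady-state window, s; taken from the trajectory's plan
#'   attribute when `NULL`, else defaults to `c(30, 90)`.
#'
#' @return An `arm_metrics` object: a list with `jerk` (tibble: `part`,
#'   `mean_squared_jerk`), `amplitude` (tibble from
#'   [trajectory_amplitude()]), `mean_cycle` (matrix), and the settings
#'   used. Use [tidy()] / [glance()] to extract tidy tables.
#' @examples
#' traj <- simulate_arm(plan = simulation_plan(duration = 20,
#'                                             steady_window = c(5, 19)))
#' metrics <- analyze_trajectory(traj)
#' tidy(metrics)
#' glance(metrics)
#' @export
analyze_trajectory <- function(traj, rate = NULL, cutoff = 5,
                               frequency = NULL, window = NULL) {
  stopifnot(is.data.frame(traj), "time" %in% names(traj))
  time <- traj$time
  if (is.null(rate)) rate <- 1 / stats::median(diff(time))
  if (is.null(frequency)) {
    spec <- attr(traj, "oscillation")
    if (is.null(spec)) stop("frequency not given and trajectory has no oscillation attribute",
                            call. = FALSE)
    frequency <- spec$frequency
  }
  if (is.null(window)) {
    plan <- attr(traj, "plan")
    window <- if (!is.null(plan)) plan$steady_window else c(30, 90)
  }
  parts <- c("shoulder", "elbow", "wrist", "hand")
  parts <- parts[paste0(parts, "_x") %in% names(traj)]
  if (length(parts) == 0) stop("no arm-part position columns found", call. = FALSE)

  jerk_tbl <- purrr::map_dfr(parts, function(p) {
    pos <- part_positions(traj, p)
    js <- jerk_series(pos, rate = rate, cutoff = cutoff)
    tibble::tibble(
      part = p,
      mean_squared_jerk = mean_sum_squared_jerk(js$jerk, time[js$index], window)
    )
  })
  jerk_tbl$part <- factor(jerk_tbl$part, levels = parts)

  amp <- NULL; mean_cycle <- NULL
  if ("hand" %in% parts) {
    hand <- lowpass(part_positions(traj, "hand"), cutoff, rate)
    mean_cycle <- cycle_average(hand, time, frequency, window)
    amp <- trajectory_amplitude(mean_cycle)
  }
  structure(
    list(jerk = jerk_tbl, amplitude = amp, mean_cycle = mean_cycle,
         rate = rate, cutoff = cutoff, frequency = frequency, window = window),
    class = "arm_metrics"
  )
}

#' @export
print.arm_metrics <- function(x, ...) {
  cat(sprintf("<arm_metrics> window %g-%g s, drive %g Hz, cutoff %g Hz\n",
              x$window[1], x$window[2], x$frequency, x$cutoff))
  cat("mean sum of squared jerk [m^2/s^6]:\n")
  print(as.data.frame(x$jerk), row.names = FALSE)
  if (!is.null(x$amplitude)) {
    cat("hand amplitude (half peak-to-peak) [m]:\n")
    print(as.data.frame(x$amplitude), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy the per-part jerk metrics
#'
#' @param x An `arm_metrics` object.
#' @param ... Unused.
#' @return A tibble with one row per arm part: `part`,
#'   `mean_squared_jerk` (m^2/s^6).
#' @export
tidy.arm_metrics <- function(x, ...) {
  x$jerk
}

#' One-row summary of an analysis
#'
#' @param x An `arm_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble: hand and shoulder jerk metrics, their ratio,
#'   and the hand amplitudes.
#' @export
glance.arm_metrics <- function(x, ...) {
  jk <- setNames(x$jerk$mean_squared_jerk, as.character(x$jerk$part))
  out <- tibble::tibble(
    hand_jerk = unname(jk["hand"]),
    shoulder_jerk = unname(jk["shoulder"]),
    jerk_ratio = unname(jk["hand"] / jk["shoulder"])
  )
  if (!is.null(x$amplitude)) {
    out$amplitude_horizontal <- x$amplitude$amplitude[1]
    out$amplitude_vertical <- x$amplitude$amplitude[2]
  }
  out
}
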