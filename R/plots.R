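#' Plot the hand path of a trajectory
#'
#' Hand path over the steady-state window, with the phase-locked mean
#' one-cycle trajectory overlaid, centred on the mean hand position.
#'
#' @param object An `arm_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arm_trajectory <- function(object, ...) {
  plan <- attr(object, "plan")
  spec <- attr(object, "oscillation")
  win <- plan$steady_window
  steady <- dplyr::filter(object, .data$time >= win[1], .data$time <= win[2])
  ctr <- c(mean(steady$hand_x), mean(steady$hand_y))
  mc <- cycle_average(part_positions(steady, "hand"), steady$time,
                      spec$frequency, win)
  mc_df <- tibble::tibble(x = mc[, 1] - ctr[1], y = mc[, 2] - ctr[2])
  ggplot2::ggplot(steady,
                  ggplot2::aes(.data$hand_x - ctr[1], .data$hand_y - ctr[2])) +
    ggplot2::geom_path(alpha = 0.25, linewidth = 0.2) +
    ggplot2::geom_path(data = mc_df, ggplot2::aes(.data$x, .data$y),
                       colour = "red", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "horizontal hand displacement [m]",
                  y = "vertical hand displacement [m]",
                  title = "Hand path (grey) and mean one-cycle trajectory (red)") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-part jerk metrics
#'
#' @param object An `arm_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arm_metrics <- function(object, ...) {
  ggplot2::ggplot(object$jerk,
                  ggplot2::aes(.data$part, .data$mean_squared_jerk)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = NULL, y = expression("mean sum of squared jerk" ~ (m^2 / s^6))) +
    ggplot2::theme_minimal()
}

#' Jerk metrics across sweep conditions
#'
#' One bar group per arm part, one fill level per condition (damper value or
#' stiffness scale), mirroring how suppression-method comparisons are
#' usually displayed.
#'
#' @param sweep An `arm_sweep` tibble from [sweep_damper()] or
#'   [sweep_stiffness()].
#' @return A ggplot object.
#' @export
plot_sweep_jerk <- function(sweep) {
  cond <- attr(sweep, "condition")
  long <- tidyr::pivot_longer(sweep, dplyr::starts_with("jerk_"),
                              names_to = "part", names_prefix = "jerk_",
                              values_to = "jerk")
  long$part <- factor(long$part, levels = c("shoulder", "elbow", "wrist", "hand"))
  ggplot2::ggplot(long, ggplot2::aes(.data$part, .data$jerk,
                                     fill = factor(.data[[cond]]))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression("mean sum of squared jerk" ~ (m^2 / s^6)),
                  fill = cond) +
    ggplot2::theme_minimal()
}

#' Hand amplitudes across sweep conditions
#'
#' @inheritParams plot_sweep_jerk
#' @return A ggplot object.
#' @export
plot_sweep_amplitude <- function(sweep) {
  cond <- attr(sweep, "condition")
  long <- tidyr::pivot_longer(sweep, dplyr::starts_with("amplitude_"),
                              names_to = "direction", names_prefix = "amplitude_",
                              values_to = "amplitude")
  ggplot2::ggplot(long, ggplot2::aes(.data$direction, .data$amplitude,
                                     fill = factor(.data[[cond]]))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.03, linetype = 2) +
    ggplot2::labs(x = NULL, y = "hand amplitude [m]", fill = cond,
                  caption = "dashed line: platform oscillation amplitude") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
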