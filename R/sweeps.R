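#' Sweep the virtual damper of the active controller
#'
#' Simulates the active suppression controller for each damper value
#' (applied to both workspace directions, `C = diag(c, c)`) and evaluates
#' the steady-state metrics. `c = 0` is the passive controller with the
#' standard stiffness — the stones-in-the-cup condition; increasing `c`
#' represents the water-carrying strategy.
#'
#' @param damper_values Numeric vector of diagonal damper values, N s/m.
#' @param params,gains,spec,plan Model configuration; see [simulate_arm()].
#'   `plan$controller` is forced to `"active"`.
#'
#' @return A tibble with one row per condition: `damper`, per-part
#'   `jerk_<part>` (m^2/s^6), `amplitude_horizontal`, `amplitude_vertical`
#'   (m). Class `arm_sweep`.
#' @export
sweep_damper <- function(damper_values = c(0, 20, 40, 60),
                         params = arm_parameters(),
                         gains = gain_set(),
                         spec = oscillation_spec(),
                         plan = simulation_plan(controller = "active")) {
  plan$controller <- "active"
  purrr::map_dfr(damper_values, function(cv) {
    g <- gains; g$damper <- c(cv, cv)
    m <- analyze_trajectory(simulate_arm(params, g, spec, plan))
    summarise_condition(m, tibble::tibble(damper = cv))
  }) |> as_arm_sweep("damper")
}

#' Sweep scalar multiples of the stiffness matrix
#'
#' Simulates the passive suppression controller with the whole stiffness
#' matrix scaled by each factor (1 = standard stiffness, 0 = pure
#' gravity-compensation torque) and evaluates the steady-state metrics.
#' Lowering all joint stiffnesses together represents a subject softening
#' the arm to let vibrations pass less effectively to the hand.
#'
#' @param scales Numeric vector of multiplicative stiffness factors.
#' @inheritParams sweep_damper
#'
#' @return A tibble with one row per condition: `stiffness_scale`, per-part
#'   `jerk_<part>`, `amplitude_horizontal`, `amplitude_vertical`. Class
#'   `arm_sweep`.
#' @export
sweep_stiffness <- function(scales = c(1, 0.1, 0.01, 0),
                            params = arm_parameters(),
                            gains = gain_set(),
                            spec = oscillation_spec(),
                            plan = simulation_plan(controller = "passive")) {
  plan$controller <- "passive"
  base_K <- gains$stiffness
  purrr::map_dfr(scales, function(s) {
    g <- gains; g$stiffness <- base_K * s
    m <- analyze_trajectory(simulate_arm(params, g, spec, plan))
    summarise_condition(m, tibble::tibble(stiffness_scale = s))
  }) |> as_arm_sweep("stiffness_scale")
}

summarise_condition <- function(metrics, id) {
  jk <- tidyr::pivot_wider(metrics$jerk, names_from = "part",
                           values_from = "mean_squared_jerk",
                           names_prefix = "jerk_")
  dplyr::bind_cols(
    id, jk,
    tibble::tibble(amplitude_horizontal = metrics$amplitude$amplitude[1],
                   amplitude_vertical = metrics$amplitude$amplitude[2])
  )
}

as_arm_sweep <- function(x, condition) {
  attr(x, "condition") <- condition
  class(x) <- c("arm_sweep", class(x))
  x
}
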