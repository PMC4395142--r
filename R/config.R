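#' Read a model configuration from a YAML file
#'
#' Loads arm parameters, controller gains, base-oscillation spec and the
#' simulation plan from a plain-text YAML file. Every section and field is
#' optional; omitted values fall back to the package defaults. Matrices are
#' given row-major as lists of rows.
#'
#' @param path Path to a YAML file; see
#'   `system.file("extdata", "default_config.yaml", package = "armvib")`
#'   for the full schema with the default values.
#'
#' @return A list with elements `params` ([arm_parameters()]), `gains`
#'   ([gain_set()]), `spec` ([oscillation_spec()]) and `plan`
#'   ([simulation_plan()]).
#' @export
read_arm_config <- function(path) {
  raw <- yaml::read_yaml(path)
  grab <- function(section, field, default) {
    v <- raw[[section]][[field]]
    if (is.null(v)) default else v
  }
  as_mat <- function(v, default) {
    if (is.null(v)) return(default)
    do.call(rbind, lapply(v, as.numeric))
  }
  params <- arm_parameters(
    mass = as.numeric(grab("arm", "mass", c(1.79, 1.02, 0.77))),
    length = as.numeric(grab("arm", "length", c(0.24, 0.22, 0.17))),
    com_offset = as.numeric(grab("arm", "com_offset", c(0.10, 0.09, 0.08))),
    inertia = as.numeric(grab("arm", "inertia", c(3.00e-2, 1.34e-2, 0.73e-2))),
    gravity = grab("arm", "gravity", 9.81)
  )
  gains <- gain_set(
    stiffness = as_mat(raw$gains$stiffness, default_stiffness()),
    viscosity = as_mat(raw$gains$viscosity, default_viscosity()),
    damper = as.numeric(grab("gains", "damper", c(0, 0))),
    posture = as.numeric(grab("gains", "posture", default_posture()))
  )
  spec <- oscillation_spec(
    amplitude = grab("oscillation", "amplitude", 0.03),
    frequency = grab("oscillation", "frequency", 1.09),
    phase = grab("oscillation", "phase", 0)
  )
  plan <- simulation_plan(
    dt = grab("plan", "dt", 0.01),
    duration = grab("plan", "duration", 100),
    steady_window = as.numeric(grab("plan", "steady_window", c(30, 90))),
    controller = grab("plan", "controller", "active")
  )
  list(params = params, gains = gains, spec = spec, plan = plan)
}
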