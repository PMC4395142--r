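#' Generate synthetic motion-capture marker data
#'
#' Emulates an optical marker recording of the oscillation task: runs the
#' simulator, keeps the marker-visible quantities (time and the four arm
#' parts' planar positions), and adds independent zero-mean Gaussian noise
#' to every coordinate — the short-range error model of optical
#' motion-capture systems. Deterministic given the seed.
#'
#' @param params,gains,spec Model configuration; see [simulate_arm()].
#' @param plan A [simulation_plan()]; when `NULL`, one is built from the
#'   noise spec's `rate` and `duration` with the active controller.
#' @param noise A [marker_noise_spec()].
#'
#' @return A tibble with columns `time` and `<part>_x`/`<part>_y` for
#'   shoulder, elbow, wrist and hand (m), carrying the same `oscillation`
#'   and `plan` attributes as a simulated trajectory so it can be passed
#'   straight to [analyze_trajectory()].
#' @examples
#' mk <- generate_markers(plan = simulation_plan(duration = 10),
#'                        noise = marker_noise_spec(seed = 7))
#' @export
generate_markers <- function(params = arm_parameters(),
                             gains = gain_set(),
                             spec = oscillation_spec(),
                             plan = NULL,
                             noise = marker_noise_spec()) {
  stopifnot(inherits(noise, "marker_noise_spec"))
  if (is.null(plan)) {
    plan <- simulation_plan(dt = 1 / noise$rate, duration = noise$duration,
                            steady_window = c(30, min(90, noise$duration * 0.75)),
                            controller = "active")
  }
  traj <- simulate_arm(params, gains, spec, plan)
  cols <- c(paste0(rep(c("shoulder", "elbow", "wrist", "hand"), each = 2),
                   c("_x", "_y")))
  mk <- traj[, c("time", cols)]
  if (noise$noise_sd > 0) {
    withr_seed <- .Random.seed_exists()
    old <- if (withr_seed) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(noise$seed)
    for (cc in cols) mk[[cc]] <- mk[[cc]] + rnorm(nrow(mk), sd = noise$noise_sd)
    if (withr_seed) assign(".Random.seed", old, envir = globalenv())
  }
  attr(mk, "oscillation") <- attr(traj, "oscillation")
  attr(mk, "plan") <- attr(traj, "plan")
  attr(mk, "noise") <- noise
  mk
}

.Random.seed_exists <- function() {
  exists(".Random.seed", envir = globalenv(), inherits = FALSE)
}
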