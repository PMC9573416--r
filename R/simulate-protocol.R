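# Exercise-protocol generation: posture, rest, then a continuous ramp.

#' Simulate a maximal graded test protocol
#'
#' Builds the phase table for one subject: six minutes sitting or standing,
#' two minutes of rest on the ergometer, then a continuous ramp whose rate
#' depends on age (20 W/min for children of 12 years or younger, 30 W/min
#' otherwise). The ramp ends at exhaustion, defined as the time at which the
#' linear oxygen-uptake response reaches the subject's VO2max plus a short
#' terminal plateau during which VO2 stays at VO2max despite the still
#' increasing load (the plateau attainment criterion).
#'
#' @param profile a [simulate_subject()] profile.
#' @param posture `"sitting"` or `"standing"` for the initial phase.
#' @param config a [simulator_config()].
#' @param seed optional integer seed; jitters the terminal plateau length
#'   uniformly in 75-105 s (90 s when `seed` is `NULL`; long enough that the
#'   final minute lies entirely on the plateau).
#' @return an object of class `protocol_phases`: a data frame with columns
#'   `label` (sitting/standing, rest, ramp), `start`, `end` (s) and
#'   `ramp_rate` (W/min, 0 outside the ramp).
#' @examples
#' p <- simulate_subject("P", seed = 1)
#' simulate_protocol(p, "sitting")
#' @export
simulate_protocol <- function(profile, posture = c("sitting", "standing"),
                              config = simulator_config(), seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  posture <- match.arg(posture)
  validate_simulator_config(config)
  ramp_rate <- if (profile$age <= 12) 20 else 30
  vo2_rest_ml <- config$vo2_rest * profile$body_mass
  vo2max_ml <- profile$vo2max * 1000
  if (vo2max_ml <= vo2_rest_ml)
    stop("profile VO2max does not exceed resting VO2", call. = FALSE)
  # VO2 rises at vo2_per_watt * ramp_rate mL/min per minute of ramp
  t_to_max <- 60 * (vo2max_ml - vo2_rest_ml) / (config$vo2_per_watt * ramp_rate)
  plateau <- if (is.null(seed)) 90 else with_local_seed(seed, runif(1, 75, 105))
  ramp_start <- 480
  phases <- data.frame(
    label = c(posture, "rest", "ramp"),
    start = c(0, 360, ramp_start),
    end = c(360, ramp_start, ramp_start + t_to_max + plateau),
    ramp_rate = c(0, 0, ramp_rate),
    stringsAsFactors = FALSE
  )
  structure(phases, class = c("protocol_phases", "data.frame"),
            t_vo2max = ramp_start + t_to_max)
}

validate_phases <- function(phases) {
  stopifnot(is.data.frame(phases),
            all(c("label", "start", "end", "ramp_rate") %in% names(phases)))
  if (any(phases$end <= phases$start))
    stop("each protocol phase must have end > start", call. = FALSE)
  if (nrow(phases) > 1 &&
      any(abs(phases$start[-1] - phases$end[-nrow(phases)]) > 1e-9))
    stop("protocol phases must be contiguous and non-overlapping",
         call. = FALSE)
  if (!all(phases$ramp_rate %in% c(0, 20, 30)))
    stop("ramp_rate must be 0, 20 or 30 W/min", call. = FALSE)
  invisible(phases)
}
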