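# Breath-by-breath gas-exchange simulation for a graded protocol.

# kcal released per litre of oxygen consumed (caloric equivalent used to
# convert oxygen uptake to energy expenditure)
KCAL_PER_L_O2 <- 4.825

#' Energy expenditure from oxygen uptake
#'
#' Converts oxygen uptake to energy expenditure with the caloric equivalent
#' EE (kcal/min) = VO2 (L/min) x 4.825.
#'
#' @param vo2_ml oxygen uptake in mL/min.
#' @return energy expenditure in kcal/min.
#' @examples
#' ee_from_vo2(1000)  # 4.825
#' @export
ee_from_vo2 <- function(vo2_ml) vo2_ml / 1000 * KCAL_PER_L_O2

# Piecewise-linear ventilatory equivalent for O2 as a function of VO2:
# flat below the first threshold, rising to `between` at the second, rising
# further to `above` at VO2max.
eq_o2_of_vo2 <- function(v, v1, v2, vmax, cfg) {
  e1 <- cfg$ve_vo2_equiv_below_th1
  e2 <- cfg$ve_vo2_equiv_between
  e3 <- cfg$ve_vo2_equiv_above_th2
  ifelse(v <= v1, e1,
         ifelse(v <= v2, e1 + (e2 - e1) * (v - v1) / (v2 - v1),
                e2 + (e3 - e2) * pmin(v - v2, vmax - v2) / (vmax - v2)))
}

# VE/VCO2: flat (isocapnic buffering) below the second threshold, rising
# linearly above it.
eq_co2_of_vo2 <- function(v, v2, vmax, cfg) {
  c1 <- cfg$eq_co2_base
  c2 <- cfg$eq_co2_max
  ifelse(v <= v2, c1, c1 + (c2 - c1) * pmin(v - v2, vmax - v2) / (vmax - v2))
}

#' Simulate breath-by-breath gas exchange
#'
#' Generates an indirect-calorimetry record for one subject over a protocol:
#' resting oxygen uptake during the posture and rest phases, then a linear
#' rise with ramp power capped at VO2max. Minute ventilation follows VO2
#' through a ventilatory-equivalent curve whose slope steepens at
#' `th1_frac * VO2max` and again at `th2_frac * VO2max`, so the series
#' contains two recoverable ventilatory-threshold breakpoints; VCO2 is
#' derived from the CO2 equivalent, which stays flat until the second
#' threshold. The respiratory exchange ratio rises from about 0.84 at rest
#' to above 1.1 at exhaustion. Breath durations shrink from the upper to
#' the lower end of `breath_dur_range` as intensity rises and are further
#' shortened whenever tidal volume would exceed
#' `vt_fraction_max * vc_per_kg * body_mass`. Gas values receive
#' multiplicative gaussian noise of fraction `noise_sd_gas`; energy
#' expenditure is derived exactly from the (noisy) VO2 as
#' `VO2 (L/min) x 4.825`.
#'
#' @param profile a [simulate_subject()] profile.
#' @param phases a [simulate_protocol()] phase table.
#' @param config a [simulator_config()].
#' @param seed optional integer seed; identical seeds give identical output.
#' @return an object of class `breath_samples`: a data frame with one row
#'   per breath and columns `t` (end-of-breath time, s), `duration` (s),
#'   `vo2`, `vco2` (mL/min), `ve` (L/min), `ee` (kcal/min), `rer`.
#'   Attributes `t_th1_true`, `t_th2_true` and `t_vo2max_true` carry the
#'   generator's breakpoint times for validation.
#' @examples
#' p <- simulate_subject("A", seed = 1)
#' ph <- simulate_protocol(p, "sitting")
#' b <- simulate_gas_exchange(p, ph, seed = 1)
#' head(b)
#' @export
simulate_gas_exchange <- function(profile, phases,
                                  config = simulator_config(), seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  validate_phases(phases)
  validate_simulator_config(config)

  vo2_rest_ml <- config$vo2_rest * profile$body_mass
  vo2max_ml <- profile$vo2max * 1000
  v1 <- config$th1_frac * vo2max_ml
  v2 <- config$th2_frac * vo2max_ml
  if (vo2_rest_ml >= v1)
    stop("resting VO2 exceeds the first-threshold VO2; config implausible",
         call. = FALSE)
  ramp <- phases[phases$label == "ramp", ]
  slope_per_s <- if (nrow(ramp) == 1)
    config$vo2_per_watt * ramp$ramp_rate / 60 else 0

  vo2_at <- function(t) {
    if (nrow(ramp) == 1 && t >= ramp$start)
      min(vo2_rest_ml + slope_per_s * (t - ramp$start), vo2max_ml)
    else vo2_rest_ml
  }

  t_end <- max(phases$end)
  dmin <- min(config$breath_dur_range)
  dmax <- max(config$breath_dur_range)
  vt_cap <- config$vt_fraction_max * config$vc_per_kg * profile$body_mass

  out <- with_local_seed(seed, {
    ts <- dur <- vo2 <- vco2 <- ve <- numeric(0)
    t_cur <- 0
    while (t_cur < t_end) {
      v_det <- vo2_at(t_cur)
      phi <- max(0, min(1, (v_det - vo2_rest_ml) / (vo2max_ml - vo2_rest_ml)))
      d <- dmax - (dmax - dmin) * phi
      if (config$noise_sd_gas > 0)
        d <- d * exp(rnorm(1L, 0, config$noise_sd_gas))
      eo <- eq_o2_of_vo2(v_det, v1, v2, vo2max_ml, config)
      ve_det <- eo * v_det / 1000
      if (ve_det * d / 60 > vt_cap) d <- 60 * vt_cap / ve_det
      d <- min(max(d, 1), 10)
      ec <- eq_co2_of_vo2(v_det, v2, vo2max_ml, config)
      vco2_det <- ve_det / ec * 1000
      nz <- function(x) if (config$noise_sd_gas > 0)
        x * max(1 + rnorm(1L, 0, config$noise_sd_gas), 0.5) else x
      ts <- c(ts, t_cur + d)
      dur <- c(dur, d)
      vo2 <- c(vo2, nz(v_det))
      vco2 <- c(vco2, nz(vco2_det))
      ve <- c(ve, nz(ve_det))
      t_cur <- t_cur + d
    }
    list(ts = ts, dur = dur, vo2 = vo2, vco2 = vco2, ve = ve)
  })

  breaths <- data.frame(
    t = out$ts, duration = out$dur, vo2 = out$vo2, vco2 = out$vco2,
    ve = out$ve, ee = ee_from_vo2(out$vo2), rer = out$vco2 / out$vo2
  )
  t_th1 <- t_th2 <- NA_real_
  if (nrow(ramp) == 1 && slope_per_s > 0) {
    t_th1 <- ramp$start + (v1 - vo2_rest_ml) / slope_per_s
    t_th2 <- ramp$start + (v2 - vo2_rest_ml) / slope_per_s
  }
  structure(breaths, class = c("breath_samples", "data.frame"),
            t_th1_true = t_th1, t_th2_true = t_th2,
            t_vo2max_true = attr(phases, "t_vo2max"))
}
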