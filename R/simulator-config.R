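#' Simulator configuration
#'
#' Collects the free parameters of the graded-exercise respiratory simulator.
#' Defaults are standard cycle-ergometry and exercise-physiology values; the
#' equivalents shape produces a flat oxygen equivalent up to the first
#' ventilatory threshold, a rise between the thresholds while the CO2
#' equivalent stays flat, and a steeper joint rise above the second
#' threshold, so both breakpoints are recoverable downstream.
#'
#' @param vo2_rest resting oxygen uptake, mL/min/kg (default 3.5, one MET).
#' @param vo2_per_watt oxygen cost of external power, mL/min/W (default
#'   10.3).
#' @param ve_vo2_equiv_below_th1 ventilatory equivalent for O2 (VE/VO2) at
#'   and below the first threshold (dimensionless, default 23).
#' @param ve_vo2_equiv_between VE/VO2 reached at the second threshold
#'   (default 30); the equivalent rises linearly with VO2 between the
#'   thresholds.
#' @param ve_vo2_equiv_above_th2 VE/VO2 reached at VO2max (default 38);
#'   linear rise above the second threshold.
#' @param eq_co2_base VE/VCO2 below the second threshold (default 27.5).
#' @param eq_co2_max VE/VCO2 at VO2max (default 31).
#' @param th1_frac,th2_frac positions of the two ventilatory thresholds as
#'   fractions of VO2max (defaults 0.55 and 0.80); must satisfy
#'   `0 < th1_frac < th2_frac < 1`.
#' @param vt_fraction_max cap on tidal volume as a fraction of the estimated
#'   vital capacity (default 0.55).
#' @param vc_per_kg vital-capacity estimate, L per kg body mass (default
#'   0.065).
#' @param breath_dur_range nominal breath duration range in seconds; the
#'   duration shrinks linearly from the upper to the lower end as intensity
#'   rises (default `c(2, 4)`).
#' @param compartment_gains named gains (L/cm) of the four-compartment
#'   chest-wall volume model: rib cage (rc), abdomen (ab), chest wall (cw),
#'   spine (sp). The gain-weighted sum of channel excursions equals tidal
#'   volume.
#' @param channel_shares fraction of each breath's tidal volume carried by
#'   each channel; must sum to 1.
#' @param baselines resting channel distances, cm.
#' @param noise_sd_distance additive gaussian noise on the distance traces,
#'   cm (default 0.02).
#' @param noise_sd_gas multiplicative gaussian noise fraction on
#'   breath-by-breath gas values and durations (default 0.03).
#' @return an object of class `simulator_config` (a validated list).
#' @export
simulator_config <- function(vo2_rest = 3.5,
                             vo2_per_watt = 10.3,
                             ve_vo2_equiv_below_th1 = 23,
                             ve_vo2_equiv_between = 30,
                             ve_vo2_equiv_above_th2 = 38,
                             eq_co2_base = 27.5,
                             eq_co2_max = 31,
                             th1_frac = 0.55,
                             th2_frac = 0.80,
                             vt_fraction_max = 0.55,
                             vc_per_kg = 0.065,
                             breath_dur_range = c(2, 4),
                             compartment_gains = c(rc = 0.35, ab = 0.45,
                                                   cw = 0.20, sp = 0.30),
                             channel_shares = c(rc = 0.42, ab = 0.45,
                                                cw = 0.08, sp = 0.05),
                             noise_sd_distance = 0.02,
                             noise_sd_gas = 0.03) {
  cfg <- list(vo2_rest = vo2_rest, vo2_per_watt = vo2_per_watt,
              ve_vo2_equiv_below_th1 = ve_vo2_equiv_below_th1,
              ve_vo2_equiv_between = ve_vo2_equiv_between,
              ve_vo2_equiv_above_th2 = ve_vo2_equiv_above_th2,
              eq_co2_base = eq_co2_base, eq_co2_max = eq_co2_max,
              th1_frac = th1_frac, th2_frac = th2_frac,
              vt_fraction_max = vt_fraction_max, vc_per_kg = vc_per_kg,
              breath_dur_range = breath_dur_range,
              compartment_gains = compartment_gains,
              channel_shares = channel_shares,
              noise_sd_distance = noise_sd_distance,
              noise_sd_gas = noise_sd_gas)
  validate_simulator_config(cfg)
  structure(cfg, class = "simulator_config")
}

validate_simulator_config <- function(cfg) {
  assert_scalar_number(cfg$th1_frac, "th1_frac", 0, 1)
  assert_scalar_number(cfg$th2_frac, "th2_frac", 0, 1)
  if (!(cfg$th1_frac < cfg$th2_frac))
    stop("invalid simulator config: need 0 < th1_frac < th2_frac < 1",
         call. = FALSE)
  ch <- c("rc", "ab", "cw", "sp")
  if (!all(ch %in% names(cfg$compartment_gains)))
    stop("compartment_gains must be named rc, ab, cw, sp", call. = FALSE)
  if (cfg$compartment_gains[["rc"]] + cfg$compartment_gains[["ab"]] <= 0)
    stop("rib-cage plus abdomen compartment gain must be positive",
         call. = FALSE)
  if (!all(ch %in% names(cfg$channel_shares)) ||
      abs(sum(cfg$channel_shares) - 1) > 1e-8)
    stop("channel_shares must be named rc, ab, cw, sp and sum to 1",
         call. = FALSE)
  if (!(cfg$ve_vo2_equiv_below_th1 <= cfg$ve_vo2_equiv_between &&
        cfg$ve_vo2_equiv_between <= cfg$ve_vo2_equiv_above_th2))
    stop("ventilatory equivalents must be non-decreasing with intensity",
         call. = FALSE)
  assert_scalar_number(cfg$noise_sd_distance, "noise_sd_distance", lo = 0)
  assert_scalar_number(cfg$noise_sd_gas, "noise_sd_gas", lo = 0, hi = 0.3)
  invisible(cfg)
}
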