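# Ventilatory-threshold detection from respiratory equivalents and
# intensity labeling of windows.

#' Compute respiratory equivalents
#'
#' Returns the ventilatory equivalents VE/VO2 and VE/VCO2 per breath,
#' lightly smoothed with a running median. The first ventilatory threshold
#' is the point where VE/VO2 starts to rise while VE/VCO2 stays flat; the
#' second where VE/VCO2 starts to rise as well.
#'
#' @param breaths a `breath_samples` data frame.
#' @param smooth odd window length of the running median (1 disables
#'   smoothing; default 5 breaths).
#' @return an `equivalents_series` data frame with columns `t`, `eq_o2`,
#'   `eq_co2` and carried-along `vo2` and `ve` for later interpolation.
#' @examples
#' b <- data.frame(t = 1:3, duration = 1, vo2 = 1200, vco2 = 1100,
#'                 ve = 30, ee = ee_from_vo2(1200), rer = 1100 / 1200)
#' compute_equivalents(b, smooth = 1)$eq_o2  # 25 25 25
#' @export
compute_equivalents <- function(breaths, smooth = 5) {
  stopifnot(inherits(breaths, "data.frame"))
  bad <- which(breaths$vo2 <= 0 | breaths$vco2 <= 0)
  if (length(bad) > 0)
    stop(sprintf("non-positive VO2/VCO2 at breath index %d", bad[1]),
         call. = FALSE)
  eq_o2 <- breaths$ve / (breaths$vo2 / 1000)
  eq_co2 <- breaths$ve / (breaths$vco2 / 1000)
  if (smooth > 1 && nrow(breaths) > smooth) {
    k <- if (smooth %% 2 == 1) smooth else smooth + 1
    eq_o2 <- as.numeric(runmed(eq_o2, k, endrule = "median"))
    eq_co2 <- as.numeric(runmed(eq_co2, k, endrule = "median"))
  }
  structure(data.frame(t = breaths$t, eq_o2 = eq_o2, eq_co2 = eq_co2,
                       vo2 = breaths$vo2, ve = breaths$ve),
            class = c("equivalents_series", "data.frame"))
}

# Best two-segment continuous piecewise-linear ("hinge") fit y ~ t with a
# single breakpoint searched over interior observation times; returns the
# breakpoint, segment slopes and the SSE reduction relative to a straight
# line.
fit_hinge <- function(t, y, margin = 5L) {
  n <- length(t)
  X0 <- cbind(1, t)
  f0 <- stats::lm.fit(X0, y)
  sse0 <- sum(f0$residuals^2)
  cand <- unique(t[seq(margin + 1L, n - margin)])
  best <- list(sse = Inf)
  for (b in cand) {
    X <- cbind(1, t, pmax(t - b, 0))
    f <- stats::lm.fit(X, y)
    sse <- sum(f$residuals^2)
    if (sse < best$sse)
      best <- list(b = b, sse = sse, coef = f$coefficients)
  }
  list(breakpoint = best$b,
       slope_pre = unname(best$coef[2]),
       slope_post = unname(best$coef[2] + best$coef[3]),
       slope_change = unname(best$coef[3]),
       sse = best$sse, sse_line = sse0,
       improvement = if (sse0 > 0) 1 - best$sse / sse0 else 0)
}

#' Detect the two ventilatory thresholds
#'
#' Reproducible surrogate for visual threshold placement: the second
#' threshold is the breakpoint of a two-segment piecewise-linear fit to
#' VE/VCO2 over the ramp; the first is the breakpoint of the same fit to
#' VE/VO2 restricted to times before the second threshold. The pair is
#' admissible only if both fits show a positive slope increase with a
#' material SSE reduction over a straight line, the VE/VCO2 slope before its
#' breakpoint is flat (at most `stability_frac` of the post-breakpoint
#' VE/VO2 slope in magnitude), and the ordering t_th1 < t_th2 holds.
#'
#' @param series a [compute_equivalents()] series.
#' @param ramp the ramp `protocol_phases` row (or a full phase table, from
#'   which the ramp row is taken).
#' @param stability_frac flatness tolerance for the pre-breakpoint VE/VCO2
#'   slope (default 0.1).
#' @param min_improvement minimum fractional SSE reduction of the hinge fit
#'   over a straight line for a breakpoint to count (default 0.05).
#' @param min_breaths minimum ramp breaths required (default 30).
#' @return an `intensity_partition`: list with `t_th1`, `t_th2` (s) and
#'   `vo2_at_th1`, `vo2_at_th2` (mL/min, interpolated).
#' @export
detect_thresholds <- function(series, ramp, stability_frac = 0.1,
                              min_improvement = 0.05, min_breaths = 30L) {
  stopifnot(inherits(series, "data.frame"))
  if (is.data.frame(ramp) && nrow(ramp) > 1)
    ramp <- ramp[ramp$label == "ramp", ]
  stopifnot(nrow(ramp) == 1)
  s <- series[series$t >= ramp$start & series$t <= ramp$end, ]
  # equivalents during the terminal VO2max plateau no longer track exercise
  # intensity; fit only up to the plateau onset
  if (!is.null(s$vo2) && nrow(s) > 11) {
    v_s <- as.numeric(runmed(s$vo2, 11, endrule = "median"))
    t_peak <- s$t[which(v_s >= 0.995 * max(v_s))[1]]
    s <- s[s$t <= t_peak, ]
  }
  if (nrow(s) < min_breaths)
    stop(sprintf("need at least %d ramp breaths, got %d", min_breaths,
                 nrow(s)), call. = FALSE)
  indeterminate <- function(why)
    stop(paste0("thresholds indeterminate: ", why), call. = FALSE)

  if (sd(s$eq_co2) < 1e-9 || sd(s$eq_o2) < 1e-9)
    indeterminate("equivalents are constant over the ramp")

  f2 <- fit_hinge(s$t, s$eq_co2)
  if (f2$slope_change <= 0 || f2$improvement < min_improvement)
    indeterminate("no rising VE/VCO2 breakpoint")
  t_th2 <- f2$breakpoint

  s1 <- s[s$t <= t_th2, ]
  if (nrow(s1) < min_breaths / 2)
    indeterminate("too few breaths before the VE/VCO2 breakpoint")
  f1 <- fit_hinge(s1$t, s1$eq_o2)
  if (f1$slope_change <= 0 || f1$improvement < min_improvement)
    indeterminate("no rising VE/VO2 breakpoint below t_th2")
  t_th1 <- f1$breakpoint
  if (!(t_th1 < t_th2)) indeterminate("t_th1 is not below t_th2")

  # stability of the CO2 equivalent before its own breakpoint, judged
  # against the post-threshold slope of the O2 equivalent
  if (abs(f2$slope_pre) > stability_frac * abs(f1$slope_post))
    indeterminate("VE/VCO2 is not stable before its breakpoint")

  vo2_at <- function(tt) approx(series$t, series$vo2, xout = tt, rule = 2)$y
  structure(list(t_th1 = t_th1, t_th2 = t_th2,
                 vo2_at_th1 = vo2_at(t_th1), vo2_at_th2 = vo2_at(t_th2)),
            class = "intensity_partition")
}

#' @export
print.intensity_partition <- function(x, ...) {
  cat(sprintf("<intensity_partition> t_th1 = %.1f s (VO2 %.0f mL/min), t_th2 = %.1f s (VO2 %.0f mL/min)\n",
              x$t_th1, x$vo2_at_th1, x$t_th2, x$vo2_at_th2))
  invisible(x)
}

INTENSITY_LEVELS <- c("sitting", "standing", "rest_to_th1", "th1_to_th2",
                      "th2_to_vo2max")

#' Label windows with intensity levels
#'
#' Assigns each window one of five intensity labels by its midpoint:
#' `sitting`/`standing` in the posture phase, `rest_to_th1` from the rest
#' phase until the first threshold, `th1_to_th2` between the thresholds and
#' `th2_to_vo2max` above the second. Ranges are left-closed: a midpoint
#' exactly at a threshold takes the higher intensity. Windows outside all
#' phases are labeled `unknown`.
#'
#' @param ws a window set.
#' @param partition a [detect_thresholds()] partition.
#' @param phases the subject's `protocol_phases`.
#' @return the window set with `meta$label` filled.
#' @export
label_windows <- function(ws, partition, phases) {
  stopifnot(inherits(ws, "window_set"), inherits(partition, "intensity_partition"))
  validate_phases(phases)
  mid <- ws$meta$start + ws$window_s / 2
  lab <- rep("unknown", length(mid))
  for (j in seq_len(nrow(phases))) {
    sel <- mid >= phases$start[j] & mid < phases$end[j]
    ph <- phases$label[j]
    if (ph %in% c("sitting", "standing")) lab[sel] <- ph
    else if (ph == "rest") lab[sel] <- "rest_to_th1"
    else if (ph == "ramp") {
      lab[sel & mid < partition$t_th1] <- "rest_to_th1"
      lab[sel & mid >= partition$t_th1 & mid < partition$t_th2] <- "th1_to_th2"
      lab[sel & mid >= partition$t_th2] <- "th2_to_vo2max"
    }
  }
  out <- ws
  out$meta$label <- lab
  out
}

#' Evaluate VO2max attainment criteria
#'
#' Checks the maximal-test criteria on ramp breaths: a respiratory exchange
#' ratio above 1.1 in any 30 s average; a VO2 plateau (mass-relative VO2
#' rising by less than 2.1 mL/kg/min from the penultimate to the final
#' minute); heart rate steady within 10 bpm of the age-predicted maximum
#' `220 - age` (when HR data are supplied); and a caller-supplied cadence
#' failure flag. Attainment requires at least three criteria.
#'
#' @param breaths ramp-phase `breath_samples`.
#' @param age subject age, years.
#' @param body_mass subject body mass, kg.
#' @param hr optional data frame with columns `t` (s) and `hr` (bpm).
#' @param cadence_failure logical flag supplied by the operator.
#' @return a `vo2max_criteria` list with the four flags, `hr_max_pred` and
#'   `attained`.
#' @examples
#' check_vo2max(data.frame(t = 1, duration = 1, vo2 = 300, vco2 = 250,
#'                         ve = 9, ee = 1.45, rer = 0.83),
#'              age = 28, body_mass = 70)$hr_max_pred  # 192
#' @export
check_vo2max <- function(breaths, age, body_mass, hr = NULL,
                         cadence_failure = FALSE) {
  stopifnot(inherits(breaths, "data.frame"), nrow(breaths) >= 1)
  assert_scalar_number(age, "age", lo = 1, hi = 120)
  assert_scalar_number(body_mass, "body_mass", lo = 1)
  hr_max_pred <- 220 - age

  roll30 <- function(t, v)
    vapply(seq_along(t), function(i) mean(v[t > t[i] - 30 & t <= t[i]]),
           numeric(1))
  rer_flag <- any(roll30(breaths$t, breaths$rer) > 1.1)

  t_end <- max(breaths$t)
  last <- breaths$t > t_end - 60
  prev <- breaths$t > t_end - 120 & breaths$t <= t_end - 60
  plateau_flag <- FALSE
  if (any(last) && any(prev)) {
    rise <- (mean(breaths$vo2[last]) - mean(breaths$vo2[prev])) / body_mass
    plateau_flag <- rise < 2.1
  }

  hr_flag <- FALSE
  if (!is.null(hr) && nrow(hr) > 0)
    hr_flag <- max(roll30(hr$t, hr$hr)) >= hr_max_pred - 10

  flags <- c(hr_steady_near_max = hr_flag, rer_gt_1_1 = rer_flag,
             vo2_plateau = plateau_flag,
             cadence_failure = isTRUE(cadence_failure))
  structure(list(hr_steady_near_max = hr_flag, rer_gt_1_1 = rer_flag,
                 vo2_plateau = plateau_flag,
                 cadence_failure = isTRUE(cadence_failure),
                 hr_max_pred = hr_max_pred, attained = sum(flags) >= 3),
            class = "vo2max_criteria")
}
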