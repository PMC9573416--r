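# Subject-profile generation for the synthetic graded-exercise study.

# Group-level anthropometric statistics (mean, sd) used by the generator:
# adults (A), post-pubertal adolescents (PP) and pubertal children (P).
# Age bounds keep each draw consistent with its group definition
# (A > 18 y, PP 13-17 y, P <= 12 y).
group_stats <- function() {
  list(
    A = list(n = 9L, age = c(28.11, 2.93), height = c(175.67, 12.98),
             body_mass = c(70.66, 18.51), vo2max = c(3.16, 1.21),
             age_bounds = c(20.0, 36.0)),
    PP = list(n = 8L, age = c(14.75, 0.71), height = c(172.06, 7.79),
              body_mass = c(56.61, 7.61), vo2max = c(3.29, 0.58),
              age_bounds = c(13.0, 16.9)),
    P = list(n = 6L, age = c(11.67, 0.52), height = c(152.10, 4.29),
             body_mass = c(41.65, 4.84), vo2max = c(1.99, 0.17),
             age_bounds = c(10.0, 12.0))
  )
}

#' Simulate one subject profile
#'
#' Draws age, height, body mass and maximal oxygen uptake from normal
#' distributions with group-specific means and standard deviations
#' (adult / post-pubertal / pubertal cohorts), truncated to physiological
#' bounds. Body-mass index is derived from the drawn mass and height so the
#' profile is internally consistent.
#'
#' @param group one of `"A"` (adult), `"PP"` (post-pubertal), `"P"`
#'   (pubertal).
#' @param seed integer seed; identical seeds give identical profiles.
#' @param sd_scale multiplier on all group standard deviations; `0` returns
#'   the group means exactly.
#' @param id optional subject identifier (defaults to `"<group><seed>"`).
#' @return an object of class `subject_profile`: a list with `group`, `age`
#'   (years), `height` (cm), `body_mass` (kg), `bmi` (kg/m^2), `vo2max`
#'   (L/min), `seed` and `id`.
#' @examples
#' simulate_subject("A", seed = 1)
#' simulate_subject("P", seed = 1, sd_scale = 0)$age  # exactly 11.67
#' @export
simulate_subject <- function(group, seed, sd_scale = 1, id = NULL) {
  stats <- group_stats()
  if (!is.character(group) || length(group) != 1L || !group %in% names(stats))
    stop("unknown group label: must be one of 'A', 'PP', 'P'", call. = FALSE)
  assert_scalar_number(sd_scale, "sd_scale", lo = 0)
  g <- stats[[group]]
  prof <- with_local_seed(seed, {
    # truncate at +/- 2.5 sd (symmetric, so means are preserved) and then at
    # the group's hard age bounds
    tr <- function(ms, lo = -Inf, hi = Inf) {
      s <- ms[2] * sd_scale
      rtnorm1(ms[1], s, max(lo, ms[1] - 2.5 * s), min(hi, ms[1] + 2.5 * s))
    }
    list(
      age = tr(g$age, g$age_bounds[1], g$age_bounds[2]),
      height = tr(g$height, lo = 100),
      body_mass = tr(g$body_mass, lo = 25),
      vo2max = tr(g$vo2max, lo = 0.5)
    )
  })
  prof$bmi <- prof$body_mass / (prof$height / 100)^2
  out <- c(list(group = group), prof[c("age", "height", "body_mass")],
           list(bmi = prof$bmi, vo2max = prof$vo2max, seed = seed,
                id = if (is.null(id)) paste0(group, seed) else id))
  structure(out, class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile %s> group %s: age %.1f y, height %.1f cm, mass %.1f kg, BMI %.1f, VO2max %.2f L/min\n",
    x$id, x$group, x$age, x$height, x$body_mass, x$bmi, x$vo2max))
  invisible(x)
}
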