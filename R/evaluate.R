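# Agreement statistics: R^2, RMSE, Bland-Altman limits of agreement,
# per-intensity paired comparisons and window sample-size bookkeeping.

#' Coefficient of determination
#'
#' `r2 = 1 - SS_res / SS_tot`, the regression-through-data coefficient of
#' determination (not a squared correlation).
#'
#' @param pred predicted values.
#' @param ref reference values (must not be constant).
#' @return R-squared (at most 1; can be negative for models worse than the
#'   mean).
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 3))  # 1
#' @export
r_squared <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(ref) >= 2)
  ss_tot <- sum((ref - mean(ref))^2)
  if (ss_tot == 0)
    stop("R-squared undefined: reference values are constant", call. = FALSE)
  1 - sum((pred - ref)^2) / ss_tot
}

#' Root mean square error
#' @inheritParams r_squared
#' @return RMSE in the units of `ref`.
#' @export
rmse <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(ref) >= 1)
  sqrt(mean((pred - ref)^2))
}

#' Bland-Altman agreement analysis
#'
#' Differences `pred - ref` against pair averages, with mean bias, the
#' standard deviation of the differences and the limits of agreement
#' `bias +/- multiplier * SD` (1.96 for 95% limits).
#'
#' @inheritParams r_squared
#' @param multiplier limits-of-agreement multiplier (default 1.96; use 2
#'   for the plus/minus-2SD convention).
#' @return a `bland_altman` list: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `frac_within` (fraction of points inside the limits), `multiplier`,
#'   `n`, and the per-pair `data` (columns `avg`, `diff`).
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 2, 2))$bias  # 0
#' @export
bland_altman <- function(pred, ref, multiplier = 1.96) {
  stopifnot(length(pred) == length(ref), length(ref) >= 3)
  d <- pred - ref
  bias <- mean(d)
  sd_diff <- sd(d)
  loa <- bias + c(-1, 1) * multiplier * sd_diff
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = loa[1], loa_high = loa[2],
                 frac_within = mean(d >= loa[1] & d <= loa[2]),
                 multiplier = multiplier, n = length(d),
                 data = data.frame(avg = (pred + ref) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, SD %.3f, LoA [%.3f, %.3f] (x%.2f), %.1f%% within (n = %d)\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$multiplier,
              100 * x$frac_within, x$n))
  invisible(x)
}

significance_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}

#' Per-intensity paired comparison of predicted and reference values
#'
#' For every intensity level present: means and SDs of both series, mean
#' paired difference and its SD, a normality check of the differences
#' (Kolmogorov-Smirnov against a normal with the sample moments), a paired
#' t-test (on log-transformed series when normality fails and all values
#' are positive; otherwise untransformed with a warning), and the
#' significance tier `NS` / `*` / `**` / `***` at p < 0.05 / 0.01 / 0.001.
#'
#' @inheritParams r_squared
#' @param labels intensity label per pair.
#' @param alpha_normal significance level of the normality check
#'   (default 0.05).
#' @return a data frame with one row per level: `intensity`, `n`,
#'   `mean_ref`, `sd_ref`, `mean_pred`, `sd_pred`, `mean_diff`, `sd_diff`,
#'   `normal`, `log_transformed`, `p_value`, `tier`.
#' @export
per_intensity_comparison <- function(pred, ref, labels, alpha_normal = 0.05) {
  stopifnot(length(pred) == length(ref), length(ref) == length(labels))
  levels_present <- intersect(INTENSITY_LEVELS, unique(labels))
  rows <- lapply(levels_present, function(lv) {
    sel <- labels == lv
    if (sum(sel) < 2) return(NULL)
    p <- pred[sel]
    r <- ref[sel]
    d <- p - r
    normal <- TRUE
    if (sd(d) > 0) {
      ksp <- suppressWarnings(ks.test(d, "pnorm", mean(d), sd(d))$p.value)
      normal <- ksp >= alpha_normal
    }
    log_tr <- FALSE
    p_t <- r_t <- NULL
    if (!normal) {
      if (all(p > 0) && all(r > 0)) {
        p_t <- log(p)
        r_t <- log(r)
        log_tr <- TRUE
      } else {
        warning(sprintf("level '%s': non-normal differences but non-positive values; using untransformed t-test", lv))
      }
    }
    if (!log_tr) {
      p_t <- p
      r_t <- r
    }
    dt <- p_t - r_t
    pv <- if (sd(dt) == 0) {
      if (mean(dt) == 0) 1 else 0
    } else t.test(p_t, r_t, paired = TRUE)$p.value
    data.frame(intensity = lv, n = sum(sel),
               mean_ref = mean(r), sd_ref = sd(r),
               mean_pred = mean(p), sd_pred = sd(p),
               mean_diff = mean(d), sd_diff = sd(d),
               normal = normal, log_transformed = log_tr,
               p_value = pv, tier = significance_tier(pv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Required number of analysis windows
#'
#' Sample-size formula `n = z^2 p (1 - p) / m^2`, rounded up: e.g.
#' z = 1.96, p = 0.05, m = 0.02 gives 457 windows.
#'
#' @param z confidence quantile (1.96 for 95%).
#' @param p expected proportion.
#' @param m margin of error.
#' @return the required window count (integer).
#' @examples
#' required_windows(1.96, 0.05, 0.02)  # 457
#' @export
required_windows <- function(z = 1.96, p = 0.05, m = 0.02) {
  assert_scalar_number(z, "z", lo = 0)
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1)
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1 || m <= 0)
    stop("m must be positive", call. = FALSE)
  as.integer(ceiling(z^2 * p * (1 - p) / m^2))
}

#' Analyzable-window bookkeeping
#'
#' With five minutes of recording per intensity level cut into contiguous
#' 5 s windows, a subject contributes 120 analyzable windows; cohorts of
#' 6, 8 and 9 subjects contribute 720, 960 and 1080.
#'
#' @param subjects number of subjects (at least 1).
#' @param per_subject windows per subject (default 120).
#' @return total window count.
#' @examples
#' bookkeep_windows(9)  # 1080
#' @export
bookkeep_windows <- function(subjects, per_subject = 120L) {
  assert_scalar_number(subjects, "subjects", lo = 1)
  assert_scalar_number(per_subject, "per_subject", lo = 1)
  as.integer(subjects) * as.integer(per_subject)
}

#' Bundle the evaluation statistics for one model
#'
#' @inheritParams r_squared
#' @param labels optional intensity labels enabling the per-intensity table.
#' @param multiplier Bland-Altman limits multiplier.
#' @return an `eval_report`: `r2`, `rmse`, `n`, `bland_altman` and (when
#'   labels are given) `per_intensity`.
#' @export
evaluate_model <- function(pred, ref, labels = NULL, multiplier = 1.96) {
  rep <- list(r2 = r_squared(pred, ref), rmse = rmse(pred, ref),
              n = length(ref),
              bland_altman = bland_altman(pred, ref, multiplier),
              per_intensity = if (!is.null(labels))
                per_intensity_comparison(pred, ref, labels) else NULL)
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, R^2 = %.3f, RMSE = %.3f\n",
              x$n, x$r2, x$rmse))
  print(x$bland_altman)
  if (!is.null(x$per_intensity) && nrow(x$per_intensity) > 0) {
    cat("per-intensity comparison:\n")
    print(x$per_intensity, digits = 3)
  }
  invisible(x)
}
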