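# Sliding-window segmentation of RMP traces and alignment with
# breath-by-breath targets.

new_window_set <- function(signal, meta, window_s = 5, step_s = 1, fs = RMP_FS,
                           norm_stats = NULL) {
  stopifnot(is.array(signal), length(dim(signal)) == 3L,
            dim(signal)[3] == nrow(meta))
  structure(list(signal = signal, meta = meta, window_s = window_s,
                 step_s = step_s, fs = fs, norm_stats = norm_stats),
            class = "window_set")
}

#' Number of windows in a window set
#' @param ws a `window_set`.
#' @return integer count.
#' @export
n_windows <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  nrow(ws$meta)
}

#' @export
`[.window_set` <- function(x, i) {
  new_window_set(x$signal[, , i, drop = FALSE],
                 x$meta[i, , drop = FALSE],
                 window_s = x$window_s, step_s = x$step_s, fs = x$fs,
                 norm_stats = x$norm_stats)
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %g s (%d ch x %d samples), step %g s%s\n",
              n_windows(x), x$window_s, dim(x$signal)[1], dim(x$signal)[2],
              x$step_s, if (!is.null(x$norm_stats)) ", normalized" else ""))
  invisible(x)
}

#' Combine window sets
#' @param ... `window_set` objects with identical geometry.
#' @return a single `window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, logical(1), "window_set")))
  sets <- Filter(function(s) n_windows(s) > 0, sets)
  if (length(sets) == 0L) stop("no non-empty window sets", call. = FALSE)
  sig <- array(unlist(lapply(sets, `[[`, "signal")),
               dim = c(dim(sets[[1]]$signal)[1:2],
                       sum(vapply(sets, n_windows, integer(1)))))
  meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  rownames(meta) <- NULL
  new_window_set(sig, meta, sets[[1]]$window_s, sets[[1]]$step_s, sets[[1]]$fs)
}

#' Segment an RMP trace into overlapping windows
#'
#' Cuts the 15 Hz four-channel trace into fixed-length windows anchored at
#' the start of the recording, with step `window_s * (1 - overlap)`. The
#' window count follows the closed form
#' `floor((T - window_s) / step) + 1`.
#'
#' @param trace an [simulate_rmp()] `rmp_trace` (or one read from CSV).
#' @param window_s window length in seconds (default 5).
#' @param overlap fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.8, i.e. a 1 s step).
#' @param subject_id identifier stored with every window.
#' @return a `window_set` whose `signal` array has dimension
#'   `4 x (window_s * fs) x n_windows`; targets are `NA` until
#'   [align_targets()] fills them. A trace shorter than one window yields an
#'   empty set with a warning.
#' @examples
#' p <- simulate_subject("A", 1); ph <- simulate_protocol(p, "sitting")
#' b <- simulate_gas_exchange(p, ph, seed = 1)
#' tr <- simulate_rmp(b, p, seed = 1)
#' segment_windows(tr)
#' @export
segment_windows <- function(trace, window_s = 5, overlap = 0.8,
                            subject_id = "s1") {
  stopifnot(inherits(trace, "rmp_trace"))
  assert_scalar_number(window_s, "window_s", lo = 1e-9)
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1)
    stop("overlap must be in [0, 1)", call. = FALSE)
  fs <- trace$fs
  win <- round(window_s * fs)
  step <- round(window_s * (1 - overlap) * fs)
  if (step < 1) stop("overlap too large: window step below one sample",
                     call. = FALSE)
  n_avail <- nrow(trace$channels)
  n_win <- if (n_avail < win) 0L else (n_avail - win) %/% step + 1L
  if (n_win == 0L) {
    warning("trace shorter than one window; returning an empty window set")
    sig <- array(numeric(0), dim = c(4L, win, 0L))
    meta <- data.frame(subject_id = character(0), start = numeric(0),
                       target_ee = numeric(0), target_vo2 = numeric(0),
                       label = character(0), stringsAsFactors = FALSE)
    return(new_window_set(sig, meta, window_s, window_s * (1 - overlap), fs))
  }
  sig <- array(NA_real_, dim = c(4L, win, n_win))
  starts <- numeric(n_win)
  for (i in seq_len(n_win)) {
    r0 <- (i - 1L) * step
    sig[, , i] <- t(trace$channels[r0 + seq_len(win), , drop = FALSE])
    starts[i] <- trace$t0 + r0 / fs
  }
  meta <- data.frame(subject_id = subject_id, start = starts,
                     target_ee = NA_real_, target_vo2 = NA_real_,
                     label = NA_character_, stringsAsFactors = FALSE)
  new_window_set(sig, meta, window_s, window_s * (1 - overlap), fs)
}

#' Attach per-window calorimetry targets
#'
#' Sets each window's target energy expenditure (kcal/min) and mass-relative
#' oxygen uptake (mL/min/kg) to the time-weighted mean of the breath values
#' whose breath interval `[t - duration, t)` overlaps the window
#' `[start, start + window_s)`; weights are overlap durations. Windows with
#' no overlapping breath are dropped; the number dropped is stored in the
#' `n_dropped` attribute.
#'
#' @param ws a [segment_windows()] window set.
#' @param breaths a `breath_samples` data frame spanning the windows.
#' @param body_mass subject body mass in kg (for the VO2 target).
#' @return the window set with `target_ee` / `target_vo2` filled.
#' @export
align_targets <- function(ws, breaths, body_mass) {
  stopifnot(inherits(ws, "window_set"), inherits(breaths, "data.frame"))
  if (nrow(breaths) == 0) stop("empty breath list", call. = FALSE)
  assert_scalar_number(body_mass, "body_mass", lo = 1)
  b0 <- breaths$t - breaths$duration
  b1 <- breaths$t
  n <- n_windows(ws)
  tee <- tvo2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w0 <- ws$meta$start[i]
    w1 <- w0 + ws$window_s
    ov <- pmin(b1, w1) - pmax(b0, w0)
    sel <- ov > 0
    if (!any(sel)) next
    w <- ov[sel]
    tee[i] <- sum(w * breaths$ee[sel]) / sum(w)
    tvo2[i] <- sum(w * breaths$vo2[sel]) / sum(w) / body_mass
  }
  keep <- !is.na(tee)
  out <- ws[keep]
  out$meta$target_ee <- tee[keep]
  out$meta$target_vo2 <- tvo2[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Z-score window signals per channel
#'
#' Standardizes every channel using means and standard deviations computed
#' on `stats_source` only (normally the training split), so no test
#' information leaks into the scaling. [denormalize_signals()] inverts the
#' transform.
#'
#' @param ws window set to transform.
#' @param stats_source window set providing the statistics (defaults to
#'   `ws` itself).
#' @return `ws` with standardized signals and the statistics stored in
#'   `$norm_stats`.
#' @export
normalize_signals <- function(ws, stats_source = ws) {
  stopifnot(inherits(ws, "window_set"), inherits(stats_source, "window_set"))
  if (n_windows(stats_source) == 0)
    stop("stats_source is empty", call. = FALSE)
  ch <- RMP_CHANNELS
  mu <- sdv <- numeric(4L)
  for (c in 1:4) {
    v <- stats_source$signal[c, , ]
    mu[c] <- mean(v)
    sdv[c] <- sd(as.numeric(v))
    if (!is.finite(sdv[c]) || sdv[c] < 1e-12)
      stop(sprintf("channel '%s' has zero variance in stats_source; cannot normalize",
                   ch[c]), call. = FALSE)
  }
  out <- ws
  for (c in 1:4) out$signal[c, , ] <- (ws$signal[c, , ] - mu[c]) / sdv[c]
  out$norm_stats <- list(mean = stats::setNames(mu, ch),
                         sd = stats::setNames(sdv, ch))
  out
}

#' Invert [normalize_signals()]
#' @param ws a normalized window set (with `$norm_stats`).
#' @return the window set on the original centimeter scale.
#' @export
denormalize_signals <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  if (is.null(ws$norm_stats)) stop("window set is not normalized", call. = FALSE)
  out <- ws
  for (c in 1:4)
    out$signal[c, , ] <- ws$signal[c, , ] * ws$norm_stats$sd[c] +
      ws$norm_stats$mean[c]
  out$norm_stats <- NULL
  out
}

# (T*N) x C matrix view of the window signals, row t + (i-1)*T, used by the
# TCN forward/backward passes.
as_tcn_input <- function(ws) {
  d <- dim(ws$signal)
  x <- aperm(ws$signal, c(2, 3, 1))
  dim(x) <- c(d[2] * d[3], d[1])
  x
}
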