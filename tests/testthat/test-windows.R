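make_flat_trace <- function(T_s, fs = 15) {
  n <- floor(T_s * fs)
  ch <- matrix(rep(c(25, 27, 30, 32), each = n), n, 4,
               dimnames = list(NULL, c("rc", "ab", "cw", "sp")))
  ch <- ch + matrix(rnorm(4 * n, 0, 0.1), n, 4)
  structure(list(fs = fs, t0 = 0, t = (seq_len(n) - 1) / fs, channels = ch),
            class = "rmp_trace")
}

test_that("window counts follow the closed form", {
  withr::with_seed(1, {
    expect_equal(n_windows(segment_windows(make_flat_trace(5))), 1L)
    expect_equal(n_windows(segment_windows(make_flat_trace(300))), 296L)
    expect_warning(ws0 <- segment_windows(make_flat_trace(4)), "shorter")
    expect_equal(n_windows(ws0), 0L)
    # five minutes of contiguous (overlap-free) 5 s windows: 60 per level,
    # the per-subject bookkeeping unit
    expect_equal(n_windows(segment_windows(make_flat_trace(300),
                                           overlap = 0)), 60L)
    for (T_s in c(5, 6.2, 12.4, 61, 120)) {
      tr <- make_flat_trace(T_s)
      for (ov in c(0, 0.2, 0.4, 0.6, 0.8)) {
        step <- 5 * (1 - ov)
        expected <- floor((T_s - 5) / step) + 1
        expect_equal(n_windows(segment_windows(tr, 5, ov)), expected,
                     info = sprintf("T=%g overlap=%g", T_s, ov))
      }
    }
  })
})

test_that("window signals are contiguous slices anchored at zero", {
  withr::with_seed(2, tr <- make_flat_trace(12))
  ws <- segment_windows(tr, subject_id = "sX")
  expect_equal(ws$meta$start, 0:7)
  expect_equal(ws$step_s, 1)
  expect_equal(dim(ws$signal), c(4L, 75L, 8L))
  expect_equal(ws$signal[, , 3], t(tr$channels[31:105, ]),
               ignore_attr = TRUE)
  expect_true(all(ws$meta$subject_id == "sX"))
})

test_that("target alignment is a time-weighted breath mean", {
  withr::with_seed(3, tr <- make_flat_trace(10))
  ws <- segment_windows(tr)
  # one breath covering everything
  b1 <- data.frame(t = 10, duration = 10, vo2 = 1000, vco2 = 900, ve = 25,
                   ee = 4.825, rer = 0.9)
  a1 <- align_targets(ws, b1, body_mass = 70)
  expect_equal(a1$meta$target_ee, rep(4.825, n_windows(a1)))
  expect_equal(a1$meta$target_vo2, rep(1000 / 70, n_windows(a1)))
  # two equal 2.5 s breaths tiling the first window with EE 2 and 4
  b2 <- data.frame(t = c(2.5, 5, 10), duration = c(2.5, 2.5, 5),
                   vo2 = c(2, 4, 4) / 4.825 * 1000,
                   vco2 = 900, ve = 25, ee = c(2, 4, 4), rer = 0.9)
  a2 <- align_targets(ws[1], b2, body_mass = 70)
  expect_equal(a2$meta$target_ee, 3)
})

test_that("alignment matches a brute-force integral under staggered breaths", {
  withr::with_seed(4, tr <- make_flat_trace(20))
  ws <- segment_windows(tr)
  durs <- c(1.7, 3.3, 2.1, 4.4, 2.8, 1.9, 3.8)
  durs <- rep(durs, length.out = 12)
  ends <- cumsum(durs)
  ee <- seq(1, 4, length.out = length(durs))
  b <- data.frame(t = ends, duration = durs, vo2 = ee / 4.825 * 1000,
                  vco2 = 900, ve = 25, ee = ee, rer = 0.9)
  al <- align_targets(ws, b, body_mass = 60)
  # oracle: integrate the piecewise-constant EE(t) on a fine grid
  grid_ee <- function(w0, w1) {
    tt <- seq(w0, w1 - 1e-9, by = 1e-4)
    idx <- findInterval(tt, c(0, ends), rightmost.closed = FALSE)
    mean(ee[pmin(idx, length(ee))])
  }
  for (i in seq_len(n_windows(al))) {
    w0 <- al$meta$start[i]
    expect_equal(al$meta$target_ee[i], grid_ee(w0, w0 + 5), tolerance = 1e-3)
  }
  # exact check against a direct overlap-weight oracle
  w0 <- 3
  ov <- pmin(ends, w0 + 5) - pmax(ends - durs, w0)
  keep <- ov > 0
  expect_equal(al$meta$target_ee[al$meta$start == w0],
               sum(ov[keep] * ee[keep]) / sum(ov[keep]), tolerance = 1e-9)
})

test_that("windows without breath support are dropped and counted", {
  withr::with_seed(5, tr <- make_flat_trace(20))
  ws <- segment_windows(tr)
  b <- data.frame(t = 8, duration = 8, vo2 = 1000, vco2 = 900, ve = 25,
                  ee = 4.825, rer = 0.9)
  al <- align_targets(ws, b, body_mass = 70)
  expect_true(all(al$meta$start < 8))
  expect_equal(attr(al, "n_dropped"),
               n_windows(ws) - n_windows(al))
  expect_error(align_targets(ws, b[0, ], 70), "empty breath")
})

test_that("normalization standardizes channels and round-trips", {
  ws <- make_amplitude_windows(n = 40, seed = 6)
  nw <- normalize_signals(ws)
  for (c in 1:4) {
    expect_equal(mean(nw$signal[c, , ]), 0, tolerance = 1e-10)
    expect_equal(sd(as.numeric(nw$signal[c, , ])), 1, tolerance = 1e-10)
  }
  back <- denormalize_signals(nw)
  expect_equal(back$signal, ws$signal, tolerance = 1e-12)
  const <- ws
  const$signal[2, , ] <- 5
  expect_error(normalize_signals(ws, const), "'ab'")
})
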