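# Shared fixtures: small synthetic objects built in code at test time.

# A window set whose target is a smooth deterministic function of the
# signal's oscillation amplitude: learnable by a small TCN in few epochs.
make_amplitude_windows <- function(n = 80, T_len = 75L, seed = 1,
                                   noise = 0.01) {
  withr::with_seed(seed, {
    sig <- array(0, dim = c(4L, T_len, n))
    amp <- runif(n, 0.2, 2)
    tt <- seq_len(T_len) / 15
    for (i in seq_len(n)) {
      for (c in 1:4) {
        sig[c, , i] <- 25 + c + amp[i] * (0.2 + 0.2 * c) *
          sin(2 * pi * tt / 3) + rnorm(T_len, 0, noise)
      }
    }
    meta <- data.frame(subject_id = rep(c("s1", "s2", "s3", "s4"),
                                        length.out = n),
                       start = seq_len(n) - 1,
                       target_ee = 2 + 3 * amp,
                       target_vo2 = 10 + 15 * amp,
                       label = rep(c("sitting", "rest_to_th1", "th1_to_th2",
                                     "th2_to_vo2max"), length.out = n),
                       stringsAsFactors = FALSE)
    rmpee:::new_window_set(sig, meta)
  })
}

# window_set with a single sample per window: cheap carrier for split
# arithmetic at realistic counts
counting_windows <- function(n, subjects = 4L) {
  sig <- array(0, dim = c(4L, 1L, n))
  meta <- data.frame(subject_id = rep(paste0("s", seq_len(subjects)),
                                      length.out = n),
                     start = seq_len(n), target_ee = 1, target_vo2 = 1,
                     label = NA_character_, stringsAsFactors = FALSE)
  rmpee:::new_window_set(sig, meta)
}

tiny_tcn_config <- function() {
  tcn_config(filters = 8L, n_dilations = 3L, kernel = 3L,
             residual_blocks = 2L)
}

# One cached default-noise subject pipeline, reused across test files run in
# the same file scope.
quick_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_subject_windows("P", seed = 101)
    cache
  }
})
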