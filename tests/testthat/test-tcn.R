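test_that("the receptive field follows the dilation closed form", {
  expect_equal(receptive_field(3, 5), 63)
  expect_equal(receptive_field(3, 1), 3)
  for (n in 1:6) expect_equal(receptive_field(1, n), 1)
  expect_equal(receptive_field(2, 4), 1 + (2 - 1) * (2^4 - 1))
  expect_error(receptive_field(0, 3), "kernel")
  expect_error(receptive_field(3, 0), "n_dilations")
})

test_that("analytic receptive field equals the perturbation-oracle count", {
  grid <- list(c(3, 5), c(2, 3), c(3, 2), c(1, 4))
  T_len <- 80L
  withr::with_seed(11, x0 <- matrix(rnorm(T_len * 4), T_len, 4))
  for (g in grid) {
    cfg <- tcn_config(filters = 8L, n_dilations = g[2], kernel = g[1],
                      residual_blocks = min(2L, g[2]))
    m <- build_tcn(cfg, in_channels = 4L, seed = 21)
    p0 <- rmpee:::tcn_forward(m, x0, T_len)$pred
    infl <- sum(vapply(seq_len(T_len), function(t) {
      xp <- x0
      xp[t, ] <- xp[t, ] + 10
      abs(rmpee:::tcn_forward(m, xp, T_len)$pred - p0) > 1e-9
    }, logical(1)))
    expect_equal(infl, min(receptive_field(g[1], g[2]), T_len),
                 info = sprintf("kernel=%d n=%d", g[1], g[2]))
  }
})

test_that("the network is causal: future samples cannot change past features", {
  T_len <- 40L
  cfg <- tcn_config(filters = 6L, n_dilations = 3L)
  withr::with_seed(31, {
    for (rep in 1:5) {
      m <- build_tcn(cfg, in_channels = 4L, seed = 100 + rep)
      x1 <- matrix(rnorm(T_len * 4), T_len, 4)
      t_cut <- sample(5:(T_len - 5), 1)
      x2 <- x1
      x2[(t_cut + 1):T_len, ] <- rnorm((T_len - t_cut) * 4)
      f1 <- rmpee:::tcn_forward(m, x1, T_len, cache = TRUE)
      f2 <- rmpee:::tcn_forward(m, x2, T_len, cache = TRUE)
      h1 <- rmpee:::relu(f1$bcaches[[length(f1$bcaches)]]$R)
      h2 <- rmpee:::relu(f2$bcaches[[length(f2$bcaches)]]$R)
      expect_equal(h1[1:t_cut, ], h2[1:t_cut, ], tolerance = 1e-12)
    }
  })
})

test_that("backpropagation matches numerical gradients", {
  cfg <- tcn_config(filters = 3L, n_dilations = 3L, kernel = 2L,
                    residual_blocks = 2L)
  m <- build_tcn(cfg, in_channels = 2L, seed = 5)
  T_len <- 12L
  N <- 3L
  withr::with_seed(42, {
    x <- matrix(rnorm(T_len * N * 2), T_len * N, 2)
    y <- rnorm(N)
  })
  skel <- m$params
  pvec <- unlist(skel, use.names = FALSE)
  lossfn <- function(p) {
    mm <- m
    mm$params <- utils::relist(p, skel)
    mean((rmpee:::tcn_forward(mm, x, T_len)$pred - y)^2)
  }
  fw <- rmpee:::tcn_forward(m, x, T_len, cache = TRUE)
  ga <- unlist(rmpee:::tcn_backward(m, fw, 2 * (fw$pred - y) / N, T_len),
               use.names = FALSE)
  h <- 1e-6
  gn <- vapply(seq_along(pvec), function(i) {
    up <- pvec; up[i] <- up[i] + h
    dn <- pvec; dn[i] <- dn[i] - h
    (lossfn(up) - lossfn(dn)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ga - gn)) / max(abs(gn)), 1e-6)
})

test_that("zeroed weights reduce the network to its head bias", {
  cfg <- tiny_tcn_config()
  m <- build_tcn(cfg, in_channels = 4L, seed = 1)
  skel <- m$params
  p0 <- rep(0, length(unlist(skel, use.names = FALSE)))
  m$params <- utils::relist(p0, skel)
  m$params$head$b <- 2.5
  T_len <- 75L
  withr::with_seed(7, x <- matrix(rnorm(T_len * 2 * 4), T_len * 2, 4))
  expect_equal(rmpee:::tcn_forward(m, x, T_len)$pred, c(2.5, 2.5))
})

test_that("weight initialization and training are seed-deterministic", {
  expect_identical(build_tcn(tiny_tcn_config(), seed = 9),
                   build_tcn(tiny_tcn_config(), seed = 9))
  ws <- make_amplitude_windows(n = 30, seed = 2)
  tc <- train_config(epochs = 2L, batch = 16L, seed = 13)
  f1 <- train_tcn(build_tcn(tiny_tcn_config(), seed = 3), ws, config = tc)
  f2 <- train_tcn(build_tcn(tiny_tcn_config(), seed = 3), ws, config = tc)
  expect_identical(f1$history$train_loss[1], f2$history$train_loss[1])
  expect_identical(f1$model$params, f2$model$params)
})
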