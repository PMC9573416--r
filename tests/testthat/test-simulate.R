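test_that("zero-variance profiles reproduce the group means exactly", {
  p <- simulate_subject("P", seed = 99, sd_scale = 0)
  expect_equal(p$age, 11.67)
  expect_equal(p$height, 152.10)
  expect_equal(p$body_mass, 41.65)
  expect_equal(p$vo2max, 1.99)
  expect_equal(p$bmi, p$body_mass / (p$height / 100)^2, tolerance = 1e-12)
})

test_that("profiles are physiological, group-consistent and seed-deterministic", {
  expect_error(simulate_subject("X", 1), "unknown group")
  a <- simulate_subject("A", seed = 5)
  expect_gt(a$age, 18)
  expect_gt(a$vo2max, 0)
  expect_equal(abs(a$bmi - a$body_mass / (a$height / 100)^2), 0,
               tolerance = 0.1)
  p <- simulate_subject("P", seed = 5)
  expect_lte(p$age, 12)
  pp <- simulate_subject("PP", seed = 5)
  expect_true(pp$age >= 13 && pp$age <= 17)
  expect_identical(simulate_subject("A", seed = 7),
                   simulate_subject("A", seed = 7))
})

test_that("adult draws recover the generator mean (Monte Carlo)", {
  ages <- vapply(1:1000, function(s) simulate_subject("A", seed = s)$age,
                 numeric(1))
  se <- 2.93 / sqrt(1000)
  expect_lt(abs(mean(ages) - 28.11), 3 * se)
})

test_that("protocol phases follow the age-dependent ramp rules", {
  p <- simulate_subject("P", seed = 1, sd_scale = 0)     # age 11.67
  pp <- simulate_subject("PP", seed = 1, sd_scale = 0)   # age 14.75
  ph_p <- simulate_protocol(p, "sitting")
  ph_pp <- simulate_protocol(pp, "standing")
  expect_equal(ph_p$ramp_rate[ph_p$label == "ramp"], 20)
  expect_equal(ph_pp$ramp_rate[ph_pp$label == "ramp"], 30)
  expect_equal(ph_p$end[1] - ph_p$start[1], 360)          # posture phase
  expect_equal(ph_pp$label[1], "standing")
  expect_equal(ph_p$start[-1], ph_p$end[-3])              # contiguous
  # ramp reaches VO2max: linear rise from rest at 10.3 mL/min/W x 20 W/min
  t_max <- attr(ph_p, "t_vo2max")
  expect_equal(3.5 * p$body_mass + 10.3 * 20 / 60 * (t_max - 480),
               p$vo2max * 1000, tolerance = 1e-6)
})

test_that("energy expenditure derives exactly from oxygen uptake", {
  expect_equal(ee_from_vo2(1000), 4.825)
  expect_equal(ee_from_vo2(0), 0)
  ws <- quick_subject()
  b <- attr(ws, "breaths")
  expect_equal(b$ee, b$vo2 / 1000 * 4.825, tolerance = 1e-12)
  expect_equal(b$rer, b$vco2 / b$vo2, tolerance = 1e-12)
  expect_true(all(b$duration >= 1 & b$duration <= 10))
  expect_true(all(b[c("vo2", "vco2", "ve", "ee")] >= 0))
})

test_that("noiseless resting EE matches one-MET expectation", {
  p <- simulate_subject("A", seed = 1, sd_scale = 0)      # 70.66 kg
  cfg <- simulator_config(noise_sd_gas = 0, noise_sd_distance = 0)
  ph <- simulate_protocol(p, "sitting", cfg)
  b <- simulate_gas_exchange(p, ph, cfg)
  sit <- b$ee[b$t <= 360]
  # 3.5 mL/min/kg x 70.66 kg = 0.2473 L/min -> x 4.825 = 1.193 kcal/min
  expect_equal(mean(sit), 1.193, tolerance = 0.01)
})

test_that("gas-exchange simulation is deterministic and rejects bad configs", {
  p <- simulate_subject("PP", seed = 3)
  ph <- simulate_protocol(p, "sitting")
  b1 <- simulate_gas_exchange(p, ph, seed = 11)
  b2 <- simulate_gas_exchange(p, ph, seed = 11)
  expect_identical(b1, b2)
  expect_error(simulator_config(th1_frac = 0.8, th2_frac = 0.5),
               "th1_frac < th2_frac")
})

test_that("trace sampling covers the protocol at exactly 15 Hz", {
  p <- simulate_subject("A", seed = 2, sd_scale = 0)
  cfg <- simulator_config(noise_sd_gas = 0, noise_sd_distance = 0)
  # 100 breaths of 3 s tile exactly 300 s
  b <- data.frame(t = (1:100) * 3, duration = 3, vo2 = 300, vco2 = 250,
                  ve = 9, ee = ee_from_vo2(300), rer = 250 / 300)
  tr <- simulate_rmp(structure(b, class = c("breath_samples", "data.frame")),
                     p, cfg, seed = 1)
  expect_equal(length(tr$t), 4500)
  expect_equal(tr$fs, 15)
  expect_true(all(tr$channels > 0))
})

test_that("gain-weighted channel excursions invert to tidal volume", {
  p <- simulate_subject("A", seed = 2, sd_scale = 0)
  cfg <- simulator_config(noise_sd_gas = 0, noise_sd_distance = 0)
  # single 4 s breath: raised-cosine peak falls on the 15 Hz grid
  b1 <- data.frame(t = 4, duration = 4, vo2 = 300, vco2 = 250, ve = 9,
                   ee = ee_from_vo2(300), rer = 250 / 300)
  class(b1) <- c("breath_samples", "data.frame")
  tr <- simulate_rmp(b1, p, cfg, seed = 1)
  exc <- apply(tr$channels, 2, function(x) max(x) - min(x))
  vt_rec <- sum(cfg$compartment_gains[colnames(tr$channels)] * exc)
  expect_equal(vt_rec, 9 * 4 / 60, tolerance = 1e-6)
  # doubling VE doubles every excursion
  b2 <- b1
  b2$ve <- 18
  tr2 <- simulate_rmp(b2, p, cfg, seed = 1)
  exc2 <- apply(tr2$channels, 2, function(x) max(x) - min(x))
  expect_equal(exc2, 2 * exc, tolerance = 1e-9)
})

test_that("per-breath volume conservation holds across a whole recording", {
  p <- simulate_subject("P", seed = 5, sd_scale = 0)
  cfg <- simulator_config(noise_sd_gas = 0, noise_sd_distance = 0)
  ph <- simulate_protocol(p, "sitting", cfg)
  b <- simulate_gas_exchange(p, ph, cfg)
  tr <- simulate_rmp(b, p, cfg, seed = 1)
  gains <- cfg$compartment_gains[colnames(tr$channels)]
  starts <- b$t - b$duration
  idx <- findInterval(tr$t, starts)
  err <- vapply(seq_len(nrow(b)), function(i) {
    sel <- idx == i
    if (sum(sel) < 5) return(0)
    exc <- apply(tr$channels[sel, , drop = FALSE], 2,
                 function(x) max(x) - min(x))
    vt <- b$ve[i] * b$duration[i] / 60
    abs(sum(gains * exc) - vt) / vt
  }, numeric(1))
  # grid quantization bounds the raised-cosine peak error; the bound grows
  # as breaths shorten toward ~19 samples at peak exercise
  expect_lt(max(err), 0.05)
})

test_that("non-contiguous or reversed breath times are rejected", {
  p <- simulate_subject("A", seed = 2)
  b <- data.frame(t = c(4, 3), duration = c(4, 3), vo2 = 300, vco2 = 250,
                  ve = 9, ee = 1.4, rer = 0.83)
  class(b) <- c("breath_samples", "data.frame")
  expect_error(simulate_rmp(b, p, seed = 1), "strictly increasing")
})
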