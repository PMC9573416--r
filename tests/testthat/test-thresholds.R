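noiseless_ramp <- function(group = "PP", seed = 1) {
  p <- simulate_subject(group, seed = seed)
  cfg <- simulator_config(noise_sd_gas = 0, noise_sd_distance = 0)
  ph <- simulate_protocol(p, "sitting", cfg)
  b <- simulate_gas_exchange(p, ph, cfg)
  list(profile = p, phases = ph, breaths = b)
}

test_that("respiratory equivalents are computed and validated", {
  b <- data.frame(t = 1:3, duration = 1, vo2 = 1200, vco2 = 1200, ve = 30,
                  ee = ee_from_vo2(1200), rer = 1)
  eq <- compute_equivalents(b, smooth = 1)
  expect_equal(eq$eq_o2, rep(25, 3))
  expect_equal(eq$eq_o2, eq$eq_co2)   # RER = 1 makes both equivalents equal
  b$vo2[2] <- 0
  expect_error(compute_equivalents(b), "index 2")
})

test_that("the oxygen equivalent is non-decreasing after its minimum on a ramp", {
  sim <- noiseless_ramp()
  eq <- compute_equivalents(sim$breaths)
  ramp <- eq[eq$t >= 480, ]
  i_min <- which.min(ramp$eq_o2)
  after <- ramp$eq_o2[i_min:nrow(ramp)]
  expect_true(all(diff(after) >= -1e-9))
})

test_that("thresholds are recovered on a noiseless ramp within 15 s", {
  sim <- noiseless_ramp()
  eq <- compute_equivalents(sim$breaths)
  part <- detect_thresholds(eq, sim$phases)
  expect_lt(abs(part$t_th1 - attr(sim$breaths, "t_th1_true")), 15)
  expect_lt(abs(part$t_th2 - attr(sim$breaths, "t_th2_true")), 15)
  expect_lt(part$t_th1, part$t_th2)
  ramp <- sim$phases[sim$phases$label == "ramp", ]
  expect_true(part$t_th1 > ramp$start && part$t_th2 < ramp$end)
})

test_that("threshold recovery error stays small across subjects", {
  # noiseless: median error within 15 s; default noise: within 30 s
  err <- function(noise, n = 10) {
    vapply(seq_len(n), function(s) {
      p <- simulate_subject("A", seed = 200 + s)
      cfg <- simulator_config(noise_sd_gas = noise,
                              noise_sd_distance = 0)
      ph <- simulate_protocol(p, "sitting", cfg)
      b <- simulate_gas_exchange(p, ph, cfg, seed = s)
      part <- detect_thresholds(compute_equivalents(b), ph)
      max(abs(part$t_th1 - attr(b, "t_th1_true")),
          abs(part$t_th2 - attr(b, "t_th2_true")))
    }, numeric(1))
  }
  expect_lte(median(err(0)), 15)
  expect_lte(median(err(0.03)), 30)
})

test_that("flat equivalents are reported as indeterminate", {
  sim <- noiseless_ramp()
  eq <- compute_equivalents(sim$breaths)
  flat <- eq
  flat$eq_o2 <- 25
  flat$eq_co2 <- 28
  expect_error(detect_thresholds(flat, sim$phases), "indeterminate")
  expect_error(detect_thresholds(eq[1:10, ], sim$phases), "at least")
})

test_that("window labeling partitions by phase and threshold, left-closed", {
  sim <- noiseless_ramp()
  eq <- compute_equivalents(sim$breaths)
  part <- detect_thresholds(eq, sim$phases)
  n <- 30
  sig <- array(1, dim = c(4, 75, n))
  starts <- c(100, 400, seq(500, by = 30, length.out = n - 3),
              part$t_th1 - 2.5)   # last midpoint falls exactly on t_th1
  meta <- data.frame(subject_id = "s", start = starts, target_ee = 1,
                     target_vo2 = 1, label = NA_character_)
  ws <- rmpee:::new_window_set(sig, meta)
  lb <- label_windows(ws, part, sim$phases)
  lab <- lb$meta$label
  expect_equal(lab[1], "sitting")
  expect_equal(lab[2], "rest_to_th1")
  expect_equal(lab[n], "th1_to_th2")       # boundary goes to the higher range
  mids <- starts + 2.5
  expect_equal(lab[mids >= part$t_th2 & mids < max(sim$phases$end)][1],
               "th2_to_vo2max")
  # totals: every in-phase window gets exactly one label
  expect_equal(sum(table(lab)), n)
  # labeling is invariant to window order
  perm <- sample(n)
  lb2 <- label_windows(ws[perm], part, sim$phases)
  expect_equal(lb2$meta$label, lab[perm])
})

test_that("VO2max criteria follow the attainment rules", {
  flat <- data.frame(t = seq(5, 300, by = 5), duration = 5, vo2 = 500,
                     vco2 = 425, ve = 12, ee = ee_from_vo2(500), rer = 0.85)
  crit <- check_vo2max(flat, age = 28, body_mass = 70)
  expect_equal(crit$hr_max_pred, 192)
  expect_false(crit$rer_gt_1_1)
  expect_false(crit$attained)

  sim <- noiseless_ramp()
  ramp <- sim$breaths[sim$breaths$t >= 480, ]
  crit2 <- check_vo2max(ramp, sim$profile$age, sim$profile$body_mass)
  expect_true(crit2$rer_gt_1_1)
  expect_true(crit2$vo2_plateau)
  expect_false(crit2$attained)            # only two flags without HR
  hr <- data.frame(t = ramp$t,
                   hr = seq(120, 220 - sim$profile$age,
                            length.out = nrow(ramp)))
  crit3 <- check_vo2max(ramp, sim$profile$age, sim$profile$body_mass,
                        hr = hr)
  expect_true(crit3$hr_steady_near_max)
  expect_true(crit3$attained)
})
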