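test_that("population curves hit their configured peaks exactly", {
  cfg <- isok_config()
  for (a in c("extension", "flexion")) for (m in c("concentric", "eccentric")) {
    cp <- cfg$curves[[a]][[m]]
    expect_equal(population_curve(cp$peak_angle, a, m, cfg), cp$peak)
  }
  expect_error(population_curve(95, "flexion", "concentric"), "\\[0, 90\\]")
})

test_that("default curves are positive with the documented peak locations", {
  cfg <- isok_config()
  fine <- seq(0, 90, by = 0.1)
  for (a in c("extension", "flexion")) for (m in c("concentric", "eccentric")) {
    expect_true(all(population_curve(fine, a, m, cfg) > 0))
  }
  ecc_flex <- population_curve(fine, "flexion", "eccentric", cfg)
  expect_equal(fine[which.max(ecc_flex)], 55)
})

test_that("planted ratio features sit where the generator promises", {
  sim <- small_sim(seed = 1)
  expect_equal(sim$truth$ext_crossing_progress_deg, 40, tolerance = 1e-3)
  expect_equal(length(sim$truth$ext_crossing_flexion_deg), 1)
  peaks <- sim$truth$flex_extrema$angle[sim$truth$flex_extrema$kind == "maximum"]
  expect_equal(peaks, c(20, 80), tolerance = 0.05)  # relative tolerance
  expect_true(all(sim$truth$ratios$flexion < 1))
})

test_that("a noise-free study reproduces the population curve exactly", {
  cfg <- isok_config(n_athletes = 2, sd_intercept = 0, sd_smooth_dev = 0,
                     sd_repetition = 0, sd_noise = 0)
  sim <- simulate_isokinetic(cfg, seed = 1)
  series <- sim$samples |> filter_isokinetic() |> select_best_repetition()
  one <- dplyr::filter(series, action == "extension", mode == "concentric",
                       athlete_id == "ath01")
  expect_equal(one$torque_nm,
               population_curve(one$angle_deg, "extension", "concentric", cfg))
})

test_that("row counts and velocity phases follow the configuration exactly", {
  cfg <- isok_config(n_athletes = 3)
  sim <- simulate_isokinetic(cfg, seed = 11)
  pts <- length(seq(0, 90, by = cfg$angle_step))
  expect_equal(nrow(sim$samples), 3 * 4 * 5 * pts)
  frac_const <- mean(abs(sim$samples$velocity_dps) == cfg$target_velocity)
  expect_equal(frac_const, sim$truth$constant_velocity_fraction)
  # extension moves toward full extension: negative velocity
  expect_true(all(sim$samples$velocity_dps[sim$samples$action == "extension"] <= 0))
})

test_that("simulation is bit-reproducible and seeds matter", {
  s1 <- small_sim(seed = 11)
  s2 <- small_sim(seed = 11)
  s3 <- small_sim(seed = 12)
  expect_identical(s1$samples, s2$samples)
  expect_false(identical(s1$samples$torque_nm, s3$samples$torque_nm))
})

test_that("the truth record scores best repetitions and variance components", {
  sim <- small_sim(seed = 2)
  expect_equal(sim$truth$sd_noise, 6)
  expect_equal(sim$truth$sd_intercept, 8)
  expect_gt(sim$truth$tau_ind, 0)
  # best repetition truth = largest (zero) offset per group
  off <- sim$truth$repetition_offsets
  best <- sim$truth$best_repetition
  merged <- dplyr::inner_join(off, best,
                              by = c("athlete_id", "action", "mode"))
  at_best <- merged[merged$repetition == merged$best_repetition, ]
  expect_true(all(at_best$offset == 0))
  expect_true(all(off$offset <= 0))
})

test_that("deviation curves have the requested amplitude on average", {
  cfg <- isok_config(n_athletes = 40, sd_noise = 0, sd_intercept = 0,
                     sd_repetition = 0)
  sim <- simulate_isokinetic(cfg, seed = 6)
  one_mode <- sim$samples |>
    dplyr::filter(action == "flexion", mode == "concentric",
                  repetition == 1, abs(velocity_dps) == 60)
  dev <- one_mode$torque_nm -
    population_curve(one_mode$angle_deg, "flexion", "concentric", cfg)
  # RMS amplitude of the smooth deviations ~ sd_smooth_dev (6 N·m)
  expect_gt(sqrt(mean(dev^2)), 3)
  expect_lt(sqrt(mean(dev^2)), 9)
})

test_that("the misspecified fourier deviation family is available", {
  sim <- simulate_isokinetic(isok_config(n_athletes = 3,
                                         dev_family = "fourier"), seed = 3)
  expect_equal(nrow(sim$samples), 3 * 4 * 5 * 91)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(isok_config(sd_noise = -1), "sd_noise")
  expect_error(isok_config(ramp_fraction = 0.6), "ramp_fraction")
  expect_error(isok_config(n_athletes = 0), "n_athletes")
})
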