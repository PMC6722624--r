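test_that("valid rows pass through read_trials unchanged", {
  path <- write_trials_csv(toy_trials())
  out <- read_trials(path, quiet = TRUE)
  expect_equal(nrow(out), 6)
  expect_equal(out$torque_nm, toy_trials()$torque_nm)
  expect_equal(nrow(attr(out, "rejections")), 0)
})

test_that("rows violating the schema are rejected and counted", {
  df <- toy_trials()
  df$angle_deg[2] <- 95
  out <- suppressMessages(read_trials(write_trials_csv(df)))
  expect_equal(nrow(out), 5)
  rej <- attr(out, "rejections")
  expect_equal(rej$n[rej$reason == "angle_out_of_range"], 1L)

  df2 <- toy_trials()
  df2$torque_nm[1] <- "not-a-number"
  out2 <- suppressMessages(read_trials(write_trials_csv(df2)))
  expect_equal(nrow(out2), 5)
  expect_true("unparseable_numeric" %in% attr(out2, "rejections")$reason)
})

test_that("a missing required column is a hard error naming it", {
  df <- toy_trials()
  df$velocity_dps <- NULL
  expect_error(read_trials(write_trials_csv(df)), "velocity_dps")
})

test_that("column remapping finds renamed columns", {
  df <- dplyr::rename(toy_trials(), moment = torque_nm)
  out <- read_trials(write_trials_csv(df),
                     col_map = c(torque_nm = "moment"), quiet = TRUE)
  expect_equal(out$torque_nm, toy_trials()$torque_nm)
})

test_that("velocity filtering keeps exactly the in-band samples", {
  df <- toy_trials()[1:4, ]
  df$velocity_dps <- c(60, 58, 30, -59.5)
  kept <- filter_isokinetic(df, 60, 3)
  expect_equal(kept$velocity_dps, c(60, 58, -59.5))
  # vacuous filter
  expect_equal(nrow(filter_isokinetic(df, 60, Inf)), 4)
  # order preserved
  expect_equal(kept$angle_deg, df$angle_deg[c(1, 2, 4)])
  expect_error(filter_isokinetic(df, 60, 0), "tolerance")
})

test_that("filtering warns when a group is emptied", {
  df <- toy_trials()
  df$velocity_dps[df$action == "flexion"] <- 10
  expect_warning(filter_isokinetic(df, 60, 3), "a1/flexion/concentric")
})

test_that("filtered fraction matches the generator's constant-velocity phase", {
  sim <- small_sim(seed = 1)
  one_rep <- dplyr::filter(sim$samples, athlete_id == "ath01",
                           action == "flexion", mode == "concentric",
                           repetition == 1)
  kept <- filter_isokinetic(one_rep, 60, 6)
  # oracle: count the constant-velocity samples directly
  n_const <- sum(abs(one_rep$velocity_dps) == 60)
  expect_lte(abs(nrow(kept) - n_const), 1)
  expect_equal(n_const / nrow(one_rep),
               sim$truth$constant_velocity_fraction)
})

test_that("best repetition maximizes peak torque with lowest-rep tie-break", {
  df <- tibble::tibble(
    athlete_id = "a1", action = "extension", mode = "concentric",
    repetition = rep(c(1L, 2L), each = 3),
    angle_deg = rep(c(10, 20, 30), 2),
    velocity_dps = -60,
    torque_nm = c(80, 100, 90, 85, 120, 95)
  )
  best <- select_best_repetition(df)
  expect_equal(unique(best$repetition), 2L)
  expect_equal(unique(best$axis), "flexion_angle")

  tie <- df
  tie$repetition <- rep(c(1L, 3L), each = 3)
  tie$torque_nm <- c(80, 100, 90, 85, 100, 95)
  expect_equal(unique(select_best_repetition(tie)$repetition), 1L)
})

test_that("selection agrees with a brute-force scan on simulated repetitions", {
  sim <- small_sim(seed = 2)
  filtered <- filter_isokinetic(sim$samples)
  best <- select_best_repetition(filtered)
  chosen <- best |>
    dplyr::distinct(athlete_id, action, mode, repetition)
  for (i in seq_len(nrow(chosen))) {
    grp <- dplyr::filter(filtered,
                         athlete_id == chosen$athlete_id[i],
                         action == chosen$action[i], mode == chosen$mode[i])
    peaks <- vapply(split(grp$torque_nm, grp$repetition), max, numeric(1))
    expect_equal(chosen$repetition[i],
                 as.integer(names(peaks)[which.max(peaks)]))
  }
})

test_that("filtering and selection commute when selection is restricted", {
  sim <- small_sim(seed = 3)
  a <- sim$samples |> filter_isokinetic() |> select_best_repetition()
  # selecting on filtered data then re-filtering changes nothing
  b <- sim$samples |> filter_isokinetic() |> select_best_repetition() |>
    filter_isokinetic()
  expect_equal(a, b)
})

test_that("rows are conserved: kept plus rejected equals input", {
  df <- toy_trials()
  df$angle_deg[1] <- -5
  df$torque_nm[4] <- "x"
  out <- suppressMessages(read_trials(write_trials_csv(df)))
  expect_equal(nrow(out) + sum(attr(out, "rejections")$n), nrow(df))

  sim <- small_sim(seed = 4)
  kept <- filter_isokinetic(sim$samples)
  removed <- dplyr::anti_join(
    sim$samples, kept,
    by = c("athlete_id", "action", "mode", "repetition", "angle_deg"))
  expect_equal(nrow(kept) + nrow(removed), nrow(sim$samples))
})

test_that("extension-angle rescaling is the 90-degree mirror involution", {
  expect_equal(rescale_extension_angle(90), 0)
  expect_equal(rescale_extension_angle(0), 90)
  for (x in c(0, 17.5, 90)) {
    expect_equal(rescale_extension_angle(rescale_extension_angle(x)), x)
  }
  expect_error(rescale_extension_angle(95), "\\[0, 90\\]")
  expect_error(rescale_extension_angle(-1), "\\[0, 90\\]")
})
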