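# Shared helpers: tiny in-code fixtures for the test suite.

# Write a trials CSV from a data frame and return its path.
write_trials_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# A minimal valid 6-row trial table (one athlete, mixed actions).
toy_trials <- function() {
  tibble::tibble(
    athlete_id = "a1",
    action = rep(c("extension", "flexion"), each = 3),
    mode = "concentric",
    repetition = 1L,
    angle_deg = c(10, 20, 30, 10, 20, 30),
    velocity_dps = c(-60, -60, -60, 60, 60, 60),
    torque_nm = c(100, 120, 130, 70, 80, 85)
  )
}

# Small, fast simulated study for integration-style tests.
small_sim <- function(seed = 1, ...) {
  simulate_isokinetic(isok_config(n_athletes = 6, ...), seed = seed)
}

# Random-intercept data with a known sinusoidal population curve.
sine_data <- function(n_athletes = 12, n_per = 80, sigma = 3, sigma_b = 5,
                      seed = 7) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_athletes), function(i) {
      x <- sort(runif(n_per, 0, 90))
      b0 <- rnorm(1, 0, sigma_b)
      tibble::tibble(
        athlete_id = sprintf("a%02d", i),
        angle_deg = x,
        torque_nm = 50 * sin(pi * x / 90) + b0 + rnorm(n_per, 0, sigma)
      )
    })
  })
}
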