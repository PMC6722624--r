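test_that("design blocks have the dimensions implied by the bases", {
  dat <- tibble::tibble(
    athlete_id = rep(c("a", "b"), each = 5),
    angle_deg = rep(seq(10, 80, length.out = 5), 2),
    torque_nm = rnorm(10, 100, 5)
  )
  expect_warning(
    des <- hgam_design(dat,
                       basis = smooth_basis(c(0, 90), n_basis = 4),
                       basis_ind = smooth_basis(c(0, 90), n_basis = 4)),
    "weakly identified")
  expect_equal(length(des$idx_fixed), 1 + 2)          # intercept + null space
  expect_equal(length(des$idx_zpop), 4 - 2)
  expect_equal(length(des$idx_b0), 2)
  expect_equal(length(des$idx_zind), 2 * (4 - 2))
  expect_equal(ncol(des$C),
               3 + 2 + 2 + 4)

  des0 <- hgam_design(dat, basis = smooth_basis(c(0, 90), n_basis = 4),
                      individual_smooths = FALSE)
  expect_equal(length(des0$idx_zind), 0)
})

test_that("a single athlete falls back to population terms with a warning", {
  dat <- tibble::tibble(athlete_id = "solo",
                        angle_deg = seq(5, 85, length.out = 30),
                        torque_nm = rnorm(30, 100, 5))
  expect_warning(des <- hgam_design(dat), "fewer than 2 athletes")
  expect_equal(length(des$idx_b0), 0)
  expect_equal(length(des$idx_zind), 0)
})

test_that("intercept-only posterior mean matches the sample mean", {
  withr::with_seed(31, y <- rnorm(200, 5, 1))
  des <- structure(list(
    y = y, C = matrix(1, 200, 1), n = 200,
    idx_fixed = 1L, idx_zpop = integer(0), idx_b0 = integer(0),
    idx_zind = integer(0), athletes = "a", athlete_index = rep(1L, 200),
    angle = rep(45, 200), basis = smooth_basis(), basis_ind = NULL,
    individual_smooths = FALSE
  ), class = "hgam_design")
  fit <- hgam_gibbs(des, n_iter = 1500, n_warmup = 500, chains = 1, seed = 5,
                    priors = list(a = 0.001, b = 0.001, fixed_var = 1e8))
  draws <- fit$theta[, 1]
  mcse <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mean(y)), 2 * mcse + 1e-8)
})

test_that("conditional coefficient mean equals the generalized-ridge oracle", {
  sim <- small_sim(seed = 5)
  dat <- sim$samples |> filter_isokinetic() |> select_best_repetition() |>
    dplyr::filter(action == "flexion", mode == "concentric")
  des <- hgam_design(dat, basis = smooth_basis(n_basis = 8),
                     basis_ind = smooth_basis(n_basis = 5))
  sigma2 <- 36; tau2_pop <- 50; sigma2_b <- 64; tau2_ind <- 4
  prec <- numeric(ncol(des$C))
  prec[des$idx_fixed] <- 1e-6
  prec[des$idx_zpop] <- 1 / tau2_pop
  prec[des$idx_b0] <- 1 / sigma2_b
  prec[des$idx_zind] <- 1 / tau2_ind
  cm <- hqgamm:::coef_conditional(crossprod(des$C), crossprod(des$C, des$y),
                                  sigma2, prec)
  oracle <- solve(crossprod(des$C) / sigma2 + diag(prec),
                  crossprod(des$C, des$y) / sigma2)
  expect_equal(cm$mean, oracle, tolerance = 1e-8)
})

test_that("the sampler recovers a planted sinusoidal population curve", {
  dat <- sine_data(seed = 7)
  fit <- hgam_fit(dat, n_iter = 600, n_warmup = 300, chains = 1, seed = 7)
  grid <- 0:90
  est <- colMeans(posterior_curve(fit, grid)$draws)
  truth <- 50 * sin(pi * grid / 90)
  expect_lt(sqrt(mean((est - truth)^2)), 2)
  sb <- mean(sqrt(fit$variances[, "sigma2_b"]))
  expect_gte(sb, 3)
  expect_lte(sb, 8)
})

test_that("gibbs draws are bit-identical under the same seed", {
  dat <- sine_data(n_athletes = 4, n_per = 25)
  f1 <- hgam_fit(dat, n_iter = 100, n_warmup = 50, chains = 2, seed = 99)
  f2 <- hgam_fit(dat, n_iter = 100, n_warmup = 50, chains = 2, seed = 99)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$variances, f2$variances)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("row order of the input does not change the posterior curve", {
  dat <- sine_data(n_athletes = 6, n_per = 40, seed = 12)
  perm <- withr::with_seed(1, sample(nrow(dat)))
  f1 <- hgam_fit(dat, n_iter = 400, n_warmup = 200, chains = 1, seed = 3)
  f2 <- hgam_fit(dat[perm, ], n_iter = 400, n_warmup = 200, chains = 1,
                 seed = 3)
  g <- seq(0, 90, 5)
  m1 <- colMeans(posterior_curve(f1, g)$draws)
  m2 <- colMeans(posterior_curve(f2, g)$draws)
  expect_lt(max(abs(m1 - m2)), 1.5)  # Monte-Carlo tolerance
})

test_that("smooth variance is bounded away from zero on nonlinear data", {
  dat <- sine_data(seed = 8)
  fit <- hgam_fit(dat, n_iter = 400, n_warmup = 200, chains = 1, seed = 8)
  # a straight line within noise would need tau2_pop near zero
  expect_gt(quantile(fit$variances[, "tau2_pop"], 0.025), 1)
})

test_that("intercept variance concentrates near zero when absent", {
  dat <- sine_data(sigma_b = 0, sigma = 3, seed = 9)
  fit <- hgam_fit(dat, n_iter = 500, n_warmup = 250, chains = 1, seed = 9)
  s2 <- median(fit$variances[, "sigma2"])
  expect_lt(median(fit$variances[, "sigma2_b"]), s2 / 10)
})

test_that("invalid iteration settings and non-finite inputs error", {
  dat <- sine_data(n_athletes = 3, n_per = 15)
  des <- hgam_design(dat, basis = smooth_basis(n_basis = 5),
                     basis_ind = smooth_basis(n_basis = 4))
  expect_error(hgam_gibbs(des, n_iter = 10, n_warmup = 10), "n_iter")
})
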