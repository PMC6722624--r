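# A fast fit reused across posterior tests.
sine_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      fit <<- hgam_fit(sine_data(seed = 7), n_iter = 400, n_warmup = 200,
                       chains = 1, seed = 7)
    }
    fit
  }
})

test_that("posterior curves have the contracted shape and domain guard", {
  fit <- sine_fit()
  pc <- posterior_curve(fit, grid = 45)
  expect_equal(dim(pc$draws), c(nrow(fit$theta), 1))
  expect_error(posterior_curve(fit, seq(-5, 90, 5)), "domain")
  expect_error(posterior_curve(fit, c(10, 10, 20)), "strictly increasing")
})

test_that("zeroed smooth coefficients give constant curves at the intercept", {
  fit <- sine_fit()
  fit0 <- fit
  fit0$theta[, c(fit$design$idx_fixed[-1], fit$design$idx_zpop)] <- 0
  d <- posterior_curve(fit0, seq(0, 90, 10))$draws
  expect_equal(d, matrix(fit0$theta[, 1], nrow(d), ncol(d)),
               tolerance = 1e-12)
})

test_that("the posterior-mean curve peaks where the planted curve peaks", {
  fit <- sine_fit()
  grid <- 0:90
  m <- colMeans(posterior_curve(fit, grid)$draws)
  expect_lte(abs(grid[which.max(m)] - 45), 3)
})

test_that("self-ratio is exactly one and scalar factors pass through", {
  fit <- sine_fit()
  pc <- posterior_curve(fit, seq(10, 80, 2))
  r <- functional_ratio(pc, pc)
  expect_true(all(abs(r$draws - 1) < 1e-12))
  expect_equal(r$upper95 - r$lower95, rep(0, length(r$grid)))
  pc2 <- pc
  pc2$draws <- 2 * pc$draws
  r2 <- functional_ratio(pc2, pc)
  expect_equal(r2$mean, rep(2, length(r2$grid)))
})

test_that("scaling the numerator scales the ratio summaries exactly", {
  fit <- sine_fit()
  num <- posterior_curve(fit, seq(10, 80, 5))
  den <- num
  den$draws <- den$draws + 20
  r1 <- functional_ratio(num, den)
  num_scaled <- num
  num_scaled$draws <- 3 * num$draws
  r3 <- functional_ratio(num_scaled, den)
  expect_equal(r3$mean, 3 * r1$mean)
  expect_equal(r3$lower95, 3 * r1$lower95)
  expect_equal(r3$upper95, 3 * r1$upper95)
})

test_that("credible band endpoints bracket the median everywhere", {
  fit <- sine_fit()
  pc <- posterior_curve(fit, seq(5, 85, 1))
  td <- tidy(pc)
  med <- apply(pc$draws, 2, median)
  expect_true(all(td$lower <= med & med <= td$upper))
})

test_that("weak denominators are masked and reported", {
  fit <- sine_fit()
  num <- posterior_curve(fit, seq(10, 80, 10))
  den <- num
  den$draws <- matrix(0.1, nrow(num$draws), ncol(num$draws))
  expect_warning(r <- functional_ratio(num, den), "masked")
  expect_true(all(r$masked))
  expect_true(all(is.na(r$mean)))
})

test_that("mismatched grids error and unequal draw counts are resampled", {
  fit <- sine_fit()
  a <- posterior_curve(fit, seq(10, 80, 10))
  b <- posterior_curve(fit, seq(10, 80, 5))
  expect_error(functional_ratio(a, b), "grids differ")
  a2 <- a
  a2$draws <- a$draws[1:50, ]
  r <- functional_ratio(a2, a)
  expect_equal(nrow(r$draws), 50)
})

test_that("level crossings interpolate linearly and handle absences", {
  g <- seq(0, 90, 1)
  lin <- 1.5 - g / 90
  expect_equal(find_level_crossings(g, lin, 1), 45)
  expect_equal(find_level_crossings(g, rep(0.8, 91), 1), numeric(0))
  cosy <- 1 + 0.3 * cos(2 * pi * g / 90)
  cr <- find_level_crossings(g, cosy, 1)
  expect_equal(length(cr), 2)
  expect_lt(max(abs(cr - c(22.5, 67.5))), 0.5)
  # exact grid hits reported once
  expect_equal(find_level_crossings(c(0, 1, 2), c(0.5, 1, 1.5), 1), 1)
})

test_that("crossing detector agrees with brute-force bracketing", {
  g <- seq(5, 85, 1)
  vals <- 1 + 0.4 * sin(3 * pi * g / 90) - 0.004 * g
  detected <- find_level_crossings(g, vals, 1)
  fine <- seq(5, 85, 0.01)
  vf <- 1 + 0.4 * sin(3 * pi * fine / 90) - 0.004 * fine
  brute <- fine[which(diff(sign(vf - 1)) != 0)]
  expect_equal(length(detected), length(brute))
  expect_lt(max(abs(detected - brute)), 1)  # within one grid step
})

test_that("extrema detection finds peaks, troughs and plateau midpoints", {
  g <- 0:90
  expect_equal(nrow(find_extrema(g, g / 3)), 0)              # monotone
  par <- -(g - 55)^2
  ex <- find_extrema(g, par)
  expect_equal(ex$angle, 55)
  expect_equal(ex$kind, "maximum")
  plateau <- c(0:10, rep(10, 5), 10:0)
  gp <- seq_along(plateau)
  run <- range(gp[plateau == 10])       # the flat top spans indices 11..17
  exp_found <- find_extrema(gp, plateau)
  expect_equal(exp_found$angle, mean(run))
  expect_equal(exp_found$kind, "maximum")
  # endpoints never reported
  expect_equal(nrow(find_extrema(g, sqrt(g))), 0)
})

test_that("planted bimodal flexion ratio features are present in the truth", {
  sim <- small_sim(seed = 1)
  ex <- sim$truth$flex_extrema
  peaks <- ex[ex$kind == "maximum", ]
  expect_equal(nrow(peaks), 2)
  expect_lt(abs(peaks$angle[1] - 20), 1)
  expect_lt(abs(peaks$angle[2] - 80), 1)
  trough <- ex[ex$kind == "minimum", ]
  expect_equal(trough$value, 0.54, tolerance = 0.01)
})
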