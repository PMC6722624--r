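#' Posterior draws of the population torque-angle curve
#'
#' Evaluates, for every retained posterior iteration, the population-level
#' mean curve `beta0 + f(angle)` on a common angle grid; athlete-level
#' random effects are marginalized at their zero mean. Optionally the
#' athlete-level variance (random intercept plus smooth deviation) can be
#' added to the draws to widen the band to individual-level prediction.
#'
#' @param fit An `"hgam_fit"` object.
#' @param grid Ordered angle grid (degrees) within the fitted basis domain;
#'   no extrapolation. Default `seq(0, 90, by = 1)`.
#' @param include_individual If `TRUE`, adds a zero-mean Gaussian athlete
#'   effect (new-athlete intercept and smooth deviation) to each draw.
#'   Default `FALSE` (population-level band).
#' @param axis Axis label recorded for display, `"flexion_angle"` or
#'   `"extension_progress"`. The grid itself always lives on the anatomical
#'   flexion axis; use [rescale_extension_angle()] only for display.
#' @return An object of class `"curve_draws"`: list with `grid`, `draws`
#'   (iterations by grid points), `axis`, `action`, `mode`.
#' @export
posterior_curve <- function(fit, grid = seq(0, 90, by = 1),
                            include_individual = FALSE,
                            axis = "flexion_angle") {
  stopifnot(inherits(fit, "hgam_fit"))
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("grid must be strictly increasing")
  }
  design <- fit$design
  dom <- design$basis$domain
  if (any(grid < dom[1] | grid > dom[2])) {
    abort("grid outside the fitted basis domain; no extrapolation")
  }
  pop <- basis_design(design$basis, grid)
  Xg <- cbind(1, pop$X0, pop$Z)
  idx <- c(design$idx_fixed, design$idx_zpop)
  draws <- fit$theta[, idx, drop = FALSE] %*% t(Xg)
  if (include_individual) {
    S <- nrow(draws)
    if (length(design$idx_b0)) {
      draws <- draws + rnorm(S, 0, sqrt(fit$variances[, "sigma2_b"]))
    }
    if (length(design$idx_zind)) {
      Zi <- basis_design(design$basis_ind, grid)$Z
      q <- ncol(Zi)
      u <- matrix(rnorm(S * q), S, q) *
        sqrt(fit$variances[, "tau2_ind"])
      draws <- draws + u %*% t(Zi)
    }
  }
  structure(list(grid = grid, draws = draws, axis = axis,
                 action = fit$action, mode = fit$mode),
            class = "curve_draws")
}

#' @export
print.curve_draws <- function(x, ...) {
  cat("Posterior curve draws",
      if (!is.null(x$action)) paste0("(", x$action, "/", x$mode, ")"),
      ":", nrow(x$draws), "draws on", length(x$grid), "grid points,",
      "axis =", x$axis, "\n")
  invisible(x)
}

#' Functional H:Q ratio curve from two sets of posterior curve draws
#'
#' Divides numerator by denominator torque draws pointwise on a common angle
#' grid, pairing posterior iterations one-to-one. The two curves come from
#' independently fitted models (one per muscle action), so iteration-wise
#' pairing of the two independent posteriors is a valid Monte-Carlo
#' representation of the ratio posterior. For knee extension the ratio is
#' eccentric hamstrings over concentric quadriceps; for knee flexion,
#' concentric hamstrings over eccentric quadriceps.
#'
#' Grid points where the denominator's posterior-mean torque falls below
#' `eps_torque` are masked (ratio set to `NA`) to prevent blow-up near the
#' ends of the range of motion, and reported.
#'
#' @param numerator,denominator `"curve_draws"` objects on identical grids.
#'   If their draw counts differ, the larger set is resampled down to the
#'   smaller with a fixed seed.
#' @param eps_torque Mask threshold for the denominator posterior mean, N·m.
#'   Default 1.
#' @param level Reference level whose crossings are located on the
#'   posterior-mean ratio. Default 1 (the point of equality).
#' @param resample_seed Seed used only if draw counts differ. Default 1.
#' @return An object of class `"ratio_curve"`: `grid`, `draws`, pointwise
#'   `mean`, `lower95`, `upper95`, logical `masked`, `crossings` (angles
#'   where the posterior-mean ratio crosses `level`), and `extrema`
#'   (tibble from [find_extrema()]).
#' @export
functional_ratio <- function(numerator, denominator, eps_torque = 1,
                             level = 1, resample_seed = 1) {
  stopifnot(inherits(numerator, "curve_draws"),
            inherits(denominator, "curve_draws"))
  if (length(numerator$grid) != length(denominator$grid) ||
      any(numerator$grid != denominator$grid)) {
    abort("numerator and denominator grids differ")
  }
  num <- numerator$draws
  den <- denominator$draws
  if (nrow(num) != nrow(den)) {
    S <- min(nrow(num), nrow(den))
    withr::with_seed(resample_seed, {
      if (nrow(num) > S) num <- num[sample(nrow(num), S), , drop = FALSE]
      if (nrow(den) > S) den <- den[sample(nrow(den), S), , drop = FALSE]
    })
  }
  masked <- colMeans(den) < eps_torque
  ratio <- num / den
  ratio[, masked] <- NA_real_
  if (mean(masked) > 0.2) {
    warn(paste0(round(100 * mean(masked)), "% of grid points masked ",
                "(denominator mean below ", eps_torque, " N·m)"))
  }
  mean_r <- colMeans(ratio)
  lo <- apply(ratio, 2, quantile, probs = 0.025, na.rm = TRUE, names = FALSE)
  hi <- apply(ratio, 2, quantile, probs = 0.975, na.rm = TRUE, names = FALSE)
  lo[masked] <- NA_real_
  hi[masked] <- NA_real_
  grid <- numerator$grid
  ok <- !masked
  no_extrema <- tibble::tibble(angle = numeric(0), value = numeric(0),
                               kind = character(0))
  structure(list(
    grid = grid, draws = ratio, mean = mean_r, lower95 = lo, upper95 = hi,
    masked = masked, level = level,
    crossings = if (sum(ok) >= 2) {
      find_level_crossings(grid[ok], mean_r[ok], level)
    } else numeric(0),
    extrema = if (sum(ok) >= 3) find_extrema(grid[ok], mean_r[ok])
              else no_extrema,
    axis = numerator$axis,
    numerator = c(numerator$action, numerator$mode),
    denominator = c(denominator$action, denominator$mode)
  ), class = "ratio_curve")
}

#' @export
print.ratio_curve <- function(x, ...) {
  cat("Functional ratio curve on", length(x$grid), "grid points\n")
  cat("  crossings of level", x$level, "at:",
      if (length(x$crossings)) paste(round(x$crossings, 2), collapse = ", ")
      else "none", "\n")
  if (nrow(x$extrema)) {
    cat("  extrema:\n")
    print(x$extrema)
  }
  invisible(x)
}

#' Locate level crossings of a curve sampled on a grid
#'
#' For each adjacent grid pair straddling the level, returns the
#' linear-interpolation crossing angle. Exact grid-point hits are reported
#' once. Crossings are returned in ascending order; an empty result is
#' valid.
#'
#' @param grid Ordered numeric grid (at least 2 points).
#' @param values Curve values on the grid (e.g. a posterior-mean ratio).
#' @param level Reference level. Default 1.
#' @return Numeric vector of crossing locations.
#' @export
find_level_crossings <- function(grid, values, level = 1) {
  stopifnot(length(grid) == length(values))
  if (length(grid) < 2) abort("grid must have at least 2 points")
  d <- values - level
  out <- grid[which(d == 0)]
  for (i in seq_len(length(grid) - 1)) {
    if (is.na(d[i]) || is.na(d[i + 1])) next
    if (d[i] * d[i + 1] < 0) {
      out <- c(out, grid[i] + (grid[i + 1] - grid[i]) * d[i] / (d[i] - d[i + 1]))
    }
  }
  sort(unique(out))
}

#' Locate interior extrema of a curve sampled on a grid
#'
#' Finds interior local maxima and minima by sign changes of the first
#' differences. Plateaus (runs of equal values flanked by opposite-signed
#' slopes) report their midpoint. Endpoints are excluded.
#'
#' @param grid Ordered numeric grid (at least 3 points).
#' @param values Curve values on the grid.
#' @return A tibble with columns `angle`, `value`, `kind`
#'   (`"maximum"`/`"minimum"`), possibly empty.
#' @export
find_extrema <- function(grid, values) {
  stopifnot(length(grid) == length(values))
  if (length(grid) < 3) abort("grid must have at least 3 points")
  keep <- !is.na(values)
  grid <- grid[keep]
  values <- values[keep]
  d <- diff(values)
  s <- sign(d)
  # collapse zero-slope runs: remember segment start for plateau midpoints
  nz <- which(s != 0)
  out <- tibble::tibble(angle = numeric(0), value = numeric(0),
                        kind = character(0))
  if (length(nz) < 2) return(out)
  for (k in seq_len(length(nz) - 1)) {
    i <- nz[k]; j <- nz[k + 1]
    if (s[i] != s[j]) {
      # extremum spans grid[i+1] .. grid[j] (a plateau if j > i + 1)
      ang <- (grid[i + 1] + grid[j]) / 2
      out <- dplyr::bind_rows(out, tibble::tibble(
        angle = ang, value = values[i + 1],
        kind = if (s[i] > 0) "maximum" else "minimum"
      ))
    }
  }
  out
}
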