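#' Tidy a hierarchical GAM fit
#'
#' One row per scalar parameter with posterior mean, SD and equal-tailed
#' 95% credible interval. Variance components are reported on the SD scale
#' as well.
#'
#' @param x An `"hgam_fit"` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.hgam_fit <- function(x, ...) {
  draws <- cbind(x$theta, x$variances)
  colnames(draws) <- c(theta_names(x$design), colnames(x$variances))
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    term = colnames(draws),
    estimate = colMeans(draws),
    std.error = apply(draws, 2, sd),
    conf.low = qs[1, ],
    conf.high = qs[2, ]
  )
}

#' Fit-level summary of a hierarchical GAM
#'
#' @param x An `"hgam_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: observations, athletes, draw count, posterior
#'   mean residual SD, and (when the log-likelihood was stored) WAIC, elpd
#'   and the effective number of parameters.
#' @export
glance.hgam_fit <- function(x, ...) {
  out <- tibble::tibble(
    nobs = x$design$n,
    n_athletes = length(x$design$athletes),
    n_draws = nrow(x$theta),
    sigma = mean(sqrt(x$variances[, "sigma2"]))
  )
  if (!is.null(x$loglik)) {
    w <- compute_waic(x)
    out$waic <- w$waic
    out$elpd <- w$elpd
    out$p_waic <- w$p_waic
  }
  out
}

#' Tidy posterior curve draws
#'
#' @param x A `"curve_draws"` object from [posterior_curve()].
#' @param level Credible level of the equal-tailed band. Default 0.95.
#' @param ... Unused.
#' @return A tibble with `angle`, `mean`, `lower`, `upper`.
#' @export
tidy.curve_draws <- function(x, level = 0.95, ...) {
  al <- (1 - level) / 2
  tibble::tibble(
    angle = x$grid,
    mean = colMeans(x$draws),
    lower = apply(x$draws, 2, quantile, probs = al, names = FALSE),
    upper = apply(x$draws, 2, quantile, probs = 1 - al, names = FALSE)
  )
}

#' Tidy a functional ratio curve
#'
#' @param x A `"ratio_curve"` object from [functional_ratio()].
#' @param ... Unused.
#' @return A tibble with `angle`, `mean`, `lower`, `upper`, `masked`.
#' @export
tidy.ratio_curve <- function(x, ...) {
  tibble::tibble(
    angle = x$grid,
    mean = x$mean,
    lower = x$lower95,
    upper = x$upper95,
    masked = x$masked
  )
}

#' One-row summary of a functional ratio curve
#'
#' @param x A `"ratio_curve"` object.
#' @param ... Unused.
#' @return A one-row tibble: number of equality crossings, the first
#'   crossing angle (NA if none), count of interior extrema, and the
#'   fraction of masked grid points.
#' @export
glance.ratio_curve <- function(x, ...) {
  tibble::tibble(
    n_crossings = length(x$crossings),
    first_crossing = if (length(x$crossings)) x$crossings[1] else NA_real_,
    n_extrema = nrow(x$extrema),
    masked_fraction = mean(x$masked)
  )
}
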