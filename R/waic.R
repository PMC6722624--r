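#' Widely applicable information criterion (WAIC)
#'
#' Computes WAIC from a pointwise log-likelihood matrix (posterior draws by
#' observations):
#' `lppd = sum_i log mean_s exp(ll[s, i])` (evaluated log-sum-exp safely),
#' `p_waic = sum_i var_s(ll[s, i])` (sample variance over draws), and
#' `waic = -2 * (lppd - p_waic)`. Lower WAIC indicates better expected
#' predictive performance.
#'
#' @param x An `"hgam_fit"` object with a stored log-likelihood matrix, or
#'   such a matrix directly (draws in rows, observations in columns; at
#'   least 2 draws).
#' @param ... Unused.
#' @return An object of class `"hqgamm_waic"`: list with `waic`, `elpd`
#'   (`lppd - p_waic`), `lppd`, `p_waic`, `n_obs`, `n_draws`, and a
#'   `pointwise` tibble (`lppd`, `p_waic`, `elpd` per observation).
#' @export
compute_waic <- function(x, ...) UseMethod("compute_waic")

#' @rdname compute_waic
#' @export
compute_waic.hgam_fit <- function(x, ...) {
  if (is.null(x$loglik)) {
    abort("fit has no stored log-likelihood matrix (store_loglik = FALSE)")
  }
  compute_waic(x$loglik)
}

#' @rdname compute_waic
#' @export
compute_waic.matrix <- function(x, ...) {
  if (nrow(x) < 2) abort("WAIC needs at least 2 posterior draws")
  # log mean exp per observation, guarded against underflow
  mx <- apply(x, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(x, 2, mx))))
  p_i <- apply(x, 2, var)
  pointwise <- tibble::tibble(lppd = lppd_i, p_waic = p_i,
                              elpd = lppd_i - p_i)
  structure(list(
    waic = -2 * sum(pointwise$elpd),
    elpd = sum(pointwise$elpd),
    lppd = sum(lppd_i),
    p_waic = sum(p_i),
    n_obs = ncol(x),
    n_draws = nrow(x),
    pointwise = pointwise
  ), class = "hqgamm_waic")
}

#' @export
print.hqgamm_waic <- function(x, ...) {
  cat("WAIC:", round(x$waic, 2), " (lppd =", round(x$lppd, 2),
      ", p_waic =", round(x$p_waic, 2), ",", x$n_obs, "obs,",
      x$n_draws, "draws)\n")
  invisible(x)
}

#' Compare two models by WAIC
#'
#' Reports each model's WAIC plus the difference in expected log predictive
#' density (elpd) and its standard error, computed from the pointwise elpd
#' contributions: `se = sqrt(n * var(elpd1_i - elpd2_i))`. Both models must
#' have been fitted to the same observations in the same order.
#'
#' @param x,y `"hqgamm_waic"` objects (or fits, coerced via
#'   [compute_waic()]) on the same data.
#' @param labels Length-2 character labels for the comparison table.
#' @return A tibble with one row per model (`model`, `waic`, `elpd`,
#'   `p_waic`) ordered best first, with attributes `elpd_diff`
#'   (elpd of `x` minus elpd of `y`) and `se_diff`.
#' @export
compare_waic <- function(x, y, labels = c("model1", "model2")) {
  if (inherits(x, "hgam_fit")) x <- compute_waic(x)
  if (inherits(y, "hgam_fit")) y <- compute_waic(y)
  stopifnot(inherits(x, "hqgamm_waic"), inherits(y, "hqgamm_waic"))
  if (x$n_obs != y$n_obs) abort("models were fitted to different numbers of observations")
  di <- x$pointwise$elpd - y$pointwise$elpd
  out <- tibble::tibble(
    model = labels,
    waic = c(x$waic, y$waic),
    elpd = c(x$elpd, y$elpd),
    p_waic = c(x$p_waic, y$p_waic)
  )
  out <- out[order(out$waic), , drop = FALSE]
  attr(out, "elpd_diff") <- x$elpd - y$elpd
  attr(out, "se_diff") <- sqrt(x$n_obs * var(di))
  out
}
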