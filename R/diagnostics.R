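#' Split R-hat of a set of chains
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also inflates the statistic. Values near 1
#' indicate the chains agree; values above about 1.01 are flagged by
#' [check_convergence()].
#'
#' @param x A draws-by-chains numeric matrix (one column per chain).
#' @return The split-R-hat value.
#' @export
mcmc_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  split <- cbind(x[seq_len(half), , drop = FALSE],
                 x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  nn <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size of a single chain
#'
#' Estimates `n / (1 + 2 * sum(rho_t))` with the autocorrelation sum
#' truncated by Geyer's initial positive-sequence rule (pairs of adjacent
#' autocorrelations are accumulated while their sum stays positive).
#'
#' @param x Numeric vector (or draws-by-chains matrix, pooled after
#'   centering each chain) of MCMC draws.
#' @return Estimated effective sample size.
#' @export
mcmc_ess <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) return(NA_real_)
  # chain-wise autocovariances, averaged
  max_lag <- n - 2
  acov <- matrix(0, max_lag + 1, m)
  for (j in seq_len(m)) {
    xc <- x[, j] - mean(x[, j])
    ac <- stats::acf(xc, lag.max = max_lag, type = "covariance",
                     plot = FALSE, demean = FALSE)$acf[, 1, 1]
    acov[, j] <- ac
  }
  g <- rowMeans(acov)
  if (g[1] == 0) return(n * m)
  rho <- g / g[1]
  # Geyer initial positive sequence on paired sums
  tau <- 1
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t + 1] + rho[t + 2]
    if (is.na(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  (n * m) / tau
}

#' Convergence diagnostics for a hierarchical GAM fit
#'
#' Computes split-R-hat (when at least two chains were run) and the bulk
#' effective sample size for every scalar parameter of the fit: the global
#' intercept, each smooth coefficient, each random effect, and the variance
#' components. Parameters with R-hat above the threshold are flagged.
#'
#' @param fit An `"hgam_fit"` object.
#' @param rhat_threshold Flag threshold for split-R-hat. Default 1.01.
#' @return A tibble with columns `parameter`, `rhat`, `ess_bulk`, `flagged`.
#'   With a single chain, `rhat` is `NA` and a warning notes that
#'   diagnostics are limited to the effective sample size.
#' @export
check_convergence <- function(fit, rhat_threshold = 1.01) {
  stopifnot(inherits(fit, "hgam_fit"))
  draws <- cbind(fit$theta, fit$variances)
  pn <- c(theta_names(fit$design), colnames(fit$variances))
  colnames(draws) <- pn
  chains <- sort(unique(fit$chain))
  single <- length(chains) < 2
  if (single) {
    warn("single chain: R-hat unavailable, diagnostics limited to ESS")
  }
  per_param <- function(j) {
    mat <- vapply(chains, function(ch) draws[fit$chain == ch, j],
                  numeric(sum(fit$chain == chains[1])))
    tibble::tibble(
      parameter = pn[j],
      rhat = if (single) NA_real_ else mcmc_rhat(mat),
      ess_bulk = mcmc_ess(mat)
    )
  }
  out <- purrr::map_dfr(seq_len(ncol(draws)), per_param)
  out$flagged <- !is.na(out$rhat) & out$rhat > rhat_threshold
  out
}

theta_names <- function(design) {
  d <- design$basis$penalty_order
  nm <- c("beta0", paste0("pop_null", seq_len(d)),
          paste0("pop_pen", seq_along(design$idx_zpop)))
  if (length(design$idx_b0)) {
    nm <- c(nm, paste0("b0[", design$athletes, "]"))
  }
  if (length(design$idx_zind)) {
    q <- length(design$idx_zind) / length(design$athletes)
    nm <- c(nm, paste0("ind[", rep(design$athletes, each = q), ",",
                       rep(seq_len(q), length(design$athletes)), "]"))
  }
  nm
}
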