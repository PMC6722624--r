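#' Assemble the two-level GAM design for one action-mode dataset
#'
#' Stacks the response and builds the blocked mixed-model design for the
#' model
#' \deqn{y_{ij} = \beta_0 + f(x_{ij}) + b_{0i} + f_i(x_{ij}) + \varepsilon_{ij},}
#' where `f` is the common population smoother shared by all athletes,
#' `b_0i` a per-athlete random intercept, and `f_i` a per-athlete smooth
#' deviation around the common shape whose penalized coefficients share one
#' variance across athletes. Columns are, in order: the global intercept,
#' the population smooth's polynomial null-space columns, its penalized
#' columns (variance `tau_pop^2`), per-athlete intercept indicators
#' (`sigma_b^2`), and per-athlete penalized deviation blocks
#' (shared `tau_ind^2`).
#'
#' @param data A tibble with columns `athlete_id`, `angle_deg`, `torque_nm`
#'   (one action-mode, typically one best repetition per athlete).
#' @param basis Population smoother basis, a [smooth_basis()] object.
#' @param basis_ind Basis for the per-athlete smooth deviations; usually
#'   smaller than `basis`. Default `smooth_basis(n_basis = 6)` on the same
#'   domain.
#' @param individual_smooths If `FALSE`, the per-athlete deviation blocks are
#'   omitted (random-intercept-only variant, used for model comparison).
#' @return A list of class `"hgam_design"` with the response `y`, the dense
#'   design matrix `C`, column-block indices (`idx_fixed`, `idx_zpop`,
#'   `idx_b0`, `idx_zind`), athlete bookkeeping, and the bases.
#' @export
hgam_design <- function(data, basis = smooth_basis(),
                        basis_ind = smooth_basis(domain = basis$domain,
                                                 n_basis = 6),
                        individual_smooths = TRUE) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("athlete_id", "angle_deg", "torque_nm") %in% names(data)))
  athletes <- unique(data$athlete_id)
  m <- length(athletes)
  single_athlete <- m < 2
  if (single_athlete) {
    warn("fewer than 2 athletes: fitting population terms only (no random effects)")
  }
  y <- data$torque_nm
  n <- length(y)
  pop <- basis_design(basis, data$angle_deg)
  d <- basis$penalty_order
  X <- cbind(1, pop$X0)
  Zpop <- pop$Z
  blocks <- list(X, Zpop)
  if (!single_athlete) {
    A <- matrix(0, n, m)
    A[cbind(seq_len(n), match(data$athlete_id, athletes))] <- 1
    blocks <- c(blocks, list(A))
  }
  q_ind <- 0L
  if (individual_smooths && !single_athlete) {
    ind <- basis_design(basis_ind, data$angle_deg)
    q_ind <- ncol(ind$Z)
    low <- table(factor(data$athlete_id, levels = athletes))
    weak <- names(low)[low < basis_ind$n_basis + 2]
    if (length(weak)) {
      warn(paste0("athlete(s) with fewer than K_ind + 2 observations; ",
                  "smooth deviation weakly identified: ",
                  paste(weak, collapse = ", ")))
    }
    Zind <- matrix(0, n, m * q_ind)
    ai <- match(data$athlete_id, athletes)
    for (j in seq_len(q_ind)) {
      Zind[cbind(seq_len(n), (ai - 1L) * q_ind + j)] <- ind$Z[, j]
    }
    blocks <- c(blocks, list(Zind))
  }
  C <- do.call(cbind, blocks)
  p_fixed <- 1L + d
  q_pop <- ncol(Zpop)
  idx_fixed <- seq_len(p_fixed)
  idx_zpop <- p_fixed + seq_len(q_pop)
  off <- p_fixed + q_pop
  idx_b0 <- if (!single_athlete) off + seq_len(m) else integer(0)
  off <- off + length(idx_b0)
  idx_zind <- if (q_ind > 0) off + seq_len(m * q_ind) else integer(0)
  structure(list(
    y = y, C = C, n = n,
    idx_fixed = idx_fixed, idx_zpop = idx_zpop,
    idx_b0 = idx_b0, idx_zind = idx_zind,
    athletes = athletes, athlete_index = match(data$athlete_id, athletes),
    angle = data$angle_deg,
    basis = basis, basis_ind = if (individual_smooths) basis_ind else NULL,
    individual_smooths = individual_smooths && !single_athlete
  ), class = "hgam_design")
}

# Conditional posterior moments of the coefficient vector given the variance
# components: the generalized-ridge solution of the penalized normal
# equations. Returns the Cholesky factor of the precision and the mean.
coef_conditional <- function(CtC, Cty, sigma2, prec) {
  M <- CtC / sigma2
  diag(M) <- diag(M) + prec
  R <- chol(M)
  mean <- backsolve(R, backsolve(R, Cty / sigma2, transpose = TRUE))
  list(R = R, mean = mean)
}

# One variance-component draw from its inverse-gamma full conditional.
draw_inv_gamma <- function(a, b) 1 / rgamma(1, shape = a, rate = b)

#' Fit the hierarchical GAM by blocked Gibbs sampling
#'
#' Runs a conjugate blocked Gibbs sampler for the Gaussian two-level GAM
#' assembled by [hgam_design()]: (i) a joint multivariate-normal update of
#' all coefficients given the variance components, via the penalized normal
#' equations; (ii) inverse-gamma updates of each variance component given
#' its coefficients; (iii) an inverse-gamma update of the residual variance.
#' Because the Gaussian-response model is fully conjugate, every update is
#' exact (acceptance probability 1) and the sampler is reproducible bit for
#' bit given the seed.
#'
#' Priors are weakly informative by default: inverse-gamma(0.001, 0.001) on
#' every variance component and Normal(0, 1e6) on the unpenalized fixed
#' coefficients.
#'
#' @param design An `"hgam_design"` bundle.
#' @param n_iter Total iterations per chain. Default 2000.
#' @param n_warmup Warmup iterations discarded per chain. Default 1000.
#' @param chains Number of chains (run sequentially, seeds `seed + 0:...`).
#'   Default 4.
#' @param seed Integer seed; required for reproducibility. Default 1.
#' @param priors List with elements `a`, `b` (inverse-gamma shape and rate)
#'   and `fixed_var` (prior variance of unpenalized fixed coefficients).
#' @param store_loglik If `TRUE` (default), keep the draws-by-observations
#'   matrix of pointwise Gaussian log-likelihoods needed for WAIC.
#' @param fix_variances Optional named list
#'   (`sigma2`, `tau2_pop`, `sigma2_b`, `tau2_ind`) freezing variance
#'   components at given values instead of sampling them (used for
#'   validation against the generalized-ridge oracle).
#' @return An object of class `"hgam_fit"`: coefficient draws (`theta`,
#'   post-warmup draws by parameters), variance draws (`variances`), the
#'   pointwise log-likelihood matrix (`loglik`), chain bookkeeping and the
#'   design.
#' @seealso [hgam_fit()] for the data-frame interface,
#'   [posterior_curve()], [compute_waic()], [check_convergence()]
#' @export
hgam_gibbs <- function(design, n_iter = 2000, n_warmup = 1000, chains = 4,
                       seed = 1,
                       priors = list(a = 0.001, b = 0.001, fixed_var = 1e6),
                       store_loglik = TRUE, fix_variances = NULL) {
  stopifnot(inherits(design, "hgam_design"))
  if (!(n_iter > n_warmup && n_warmup >= 0)) {
    abort("need n_iter > n_warmup >= 0")
  }
  y <- design$y
  C <- design$C
  n <- design$n
  p <- ncol(C)
  CtC <- crossprod(C)
  Cty <- crossprod(C, y)
  a0 <- priors$a %||% 0.001
  b0 <- priors$b %||% 0.001
  fixed_prec <- 1 / (priors$fixed_var %||% 1e6)
  has_b0 <- length(design$idx_b0) > 0
  has_ind <- length(design$idx_zind) > 0
  S_keep <- n_iter - n_warmup
  var_names <- c("sigma2", "tau2_pop",
                 if (has_b0) "sigma2_b", if (has_ind) "tau2_ind")
  fixed_vals <- fix_variances %||% list()

  run_chain <- function(chain_seed) {
    withr::with_seed(chain_seed, {
      sigma2 <- fixed_vals$sigma2 %||% 1
      tau2_pop <- fixed_vals$tau2_pop %||% 1
      sigma2_b <- fixed_vals$sigma2_b %||% 1
      tau2_ind <- fixed_vals$tau2_ind %||% 1
      theta_keep <- matrix(NA_real_, S_keep, p)
      var_keep <- matrix(NA_real_, S_keep, length(var_names),
                         dimnames = list(NULL, var_names))
      ll_keep <- if (store_loglik) matrix(NA_real_, S_keep, n) else NULL
      for (s in seq_len(n_iter)) {
        prec <- numeric(p)
        prec[design$idx_fixed] <- fixed_prec
        prec[design$idx_zpop] <- 1 / tau2_pop
        if (has_b0) prec[design$idx_b0] <- 1 / sigma2_b
        if (has_ind) prec[design$idx_zind] <- 1 / tau2_ind
        cm <- tryCatch(coef_conditional(CtC, Cty, sigma2, prec),
                       error = function(e) abort(paste0(
                         "singular coefficient system at iteration ", s,
                         "; consider a larger ridge/prior scale")))
        theta <- cm$mean + backsolve(cm$R, rnorm(p))
        if (any(!is.finite(theta))) {
          abort(paste0("non-finite coefficient draw at iteration ", s))
        }
        mu <- drop(C %*% theta)
        resid <- y - mu
        if (is.null(fixed_vals$sigma2)) {
          sigma2 <- draw_inv_gamma(a0 + n / 2, b0 + sum(resid^2) / 2)
        }
        u <- theta[design$idx_zpop]
        if (is.null(fixed_vals$tau2_pop)) {
          tau2_pop <- draw_inv_gamma(a0 + length(u) / 2, b0 + sum(u^2) / 2)
        }
        if (has_b0 && is.null(fixed_vals$sigma2_b)) {
          b <- theta[design$idx_b0]
          sigma2_b <- draw_inv_gamma(a0 + length(b) / 2, b0 + sum(b^2) / 2)
        }
        if (has_ind && is.null(fixed_vals$tau2_ind)) {
          v <- theta[design$idx_zind]
          tau2_ind <- draw_inv_gamma(a0 + length(v) / 2, b0 + sum(v^2) / 2)
        }
        if (s > n_warmup) {
          k <- s - n_warmup
          theta_keep[k, ] <- theta
          var_keep[k, "sigma2"] <- sigma2
          var_keep[k, "tau2_pop"] <- tau2_pop
          if (has_b0) var_keep[k, "sigma2_b"] <- sigma2_b
          if (has_ind) var_keep[k, "tau2_ind"] <- tau2_ind
          if (store_loglik) {
            ll_keep[k, ] <- dnorm(y, mu, sqrt(sigma2), log = TRUE)
          }
        }
      }
      list(theta = theta_keep, variances = var_keep, loglik = ll_keep)
    })
  }

  res <- lapply(seq_len(chains) - 1L, function(k) run_chain(seed + k))
  structure(list(
    theta = do.call(rbind, lapply(res, `[[`, "theta")),
    variances = do.call(rbind, lapply(res, `[[`, "variances")),
    loglik = if (store_loglik) do.call(rbind, lapply(res, `[[`, "loglik")),
    chain = rep(seq_len(chains), each = S_keep),
    design = design,
    n_iter = n_iter, n_warmup = n_warmup, chains = chains, seed = seed,
    priors = list(a = a0, b = b0, fixed_var = 1 / fixed_prec),
    acceptance = 1
  ), class = "hgam_fit")
}

#' Fit the hierarchical torque-angle model to one action-mode dataset
#'
#' Data-frame-first wrapper around [hgam_design()] and [hgam_gibbs()]:
#' builds the design for one (action, mode) dataset and runs the Gibbs
#' sampler. Each action-mode is fitted independently.
#'
#' @param data A tibble with `athlete_id`, `angle_deg`, `torque_nm`;
#'   optionally pre-filter with `action`/`mode`.
#' @param action,mode Optional values to subset `data` on its `action` and
#'   `mode` columns before fitting.
#' @param n_basis,n_basis_ind Population / individual-deviation basis sizes.
#'   Defaults 12 and 6.
#' @param penalty_order Difference-penalty order for both bases. Default 2.
#' @param individual_smooths Include per-athlete smooth deviations
#'   (default `TRUE`).
#' @param domain Angle domain of the smoothers. Default `c(0, 90)`.
#' @inheritParams hgam_gibbs
#' @param ... Passed on to [hgam_gibbs()].
#' @return An `"hgam_fit"` object; see [hgam_gibbs()].
#' @examples
#' sim <- simulate_isokinetic(isok_config(n_athletes = 4, sd_noise = 3))
#' dat <- sim$samples |>
#'   filter_isokinetic() |>
#'   select_best_repetition()
#' fit <- hgam_fit(dat, action = "flexion", mode = "concentric",
#'                 n_iter = 200, n_warmup = 100, chains = 1, seed = 1)
#' fit
#' @export
hgam_fit <- function(data, action = NULL, mode = NULL,
                     n_basis = 12, n_basis_ind = 6, penalty_order = 2,
                     individual_smooths = TRUE, domain = c(0, 90),
                     n_iter = 2000, n_warmup = 1000, chains = 4, seed = 1,
                     ...) {
  data <- tibble::as_tibble(data)
  if (!is.null(action)) data <- data[data$action == action, , drop = FALSE]
  if (!is.null(mode)) data <- data[data$mode == mode, , drop = FALSE]
  if (!nrow(data)) abort("no rows left after action/mode subsetting")
  design <- hgam_design(
    data,
    basis = smooth_basis(domain, n_basis, penalty_order = penalty_order),
    basis_ind = smooth_basis(domain, n_basis_ind,
                             penalty_order = penalty_order),
    individual_smooths = individual_smooths
  )
  fit <- hgam_gibbs(design, n_iter = n_iter, n_warmup = n_warmup,
                    chains = chains, seed = seed, ...)
  fit$action <- action
  fit$mode <- mode
  fit
}

#' @export
print.hgam_fit <- function(x, ...) {
  cat("Hierarchical GAM fit",
      if (!is.null(x$action)) paste0("(", x$action, "/", x$mode, ")"), "\n")
  cat("  observations:", x$design$n,
      " athletes:", length(x$design$athletes), "\n")
  cat("  draws:", nrow(x$theta), "(", x$chains, "chain(s) x",
      x$n_iter - x$n_warmup, ")\n")
  cat("  residual SD (posterior mean):",
      round(mean(sqrt(x$variances[, "sigma2"])), 3), "N·m\n")
  invisible(x)
}
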