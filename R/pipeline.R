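#' Assemble a reproducible run configuration
#'
#' Bundles every knob of the simulate -> fit -> report pipeline into one
#' serializable list. An archived run configuration plus its inputs
#' reproduces all outputs bit-exactly, since every source of randomness is
#' seeded from `seed`.
#'
#' @param seed Master seed for the whole run. Default 1.
#' @param input Optional path to an existing trials CSV; when `NULL` the
#'   synthetic generator supplies the data.
#' @param simulate Named list of [isok_config()] overrides.
#' @param tolerance_dps Truly-isokinetic velocity tolerance, deg/s.
#'   Default 6.
#' @param target_velocity_dps Target velocity, deg/s. Default 60.
#' @param n_basis,n_basis_ind,penalty_order Smoother settings
#'   (see [hgam_fit()]).
#' @param chains,n_iter,n_warmup Sampler settings (see [hgam_gibbs()]).
#' @param grid_step Angle grid step for reported curves, degrees. Default 1.
#' @param level Credible level for reported bands. Default 0.95.
#' @param eps_torque Ratio mask threshold, N·m. Default 1.
#' @param compare_models Also fit the intercept-only variant of each
#'   action-mode model and report the WAIC comparison. Default `TRUE`.
#' @param plots Write figure files in [run_report()]. Default `TRUE`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1, input = NULL, simulate = list(),
                       tolerance_dps = 6, target_velocity_dps = 60,
                       n_basis = 12, n_basis_ind = 6, penalty_order = 2,
                       chains = 4, n_iter = 2000, n_warmup = 1000,
                       grid_step = 1, level = 0.95, eps_torque = 1,
                       compare_models = TRUE, plots = TRUE) {
  structure(list(
    seed = seed, input = input, simulate = simulate,
    tolerance_dps = tolerance_dps,
    target_velocity_dps = target_velocity_dps,
    n_basis = n_basis, n_basis_ind = n_basis_ind,
    penalty_order = penalty_order,
    chains = chains, n_iter = n_iter, n_warmup = n_warmup,
    grid_step = grid_step, level = level, eps_torque = eps_torque,
    compare_models = compare_models, plots = plots
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `"run_config"` object;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `"run_config"` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

resolve_isok_config <- function(config) {
  args <- config$simulate %||% list()
  if (is.null(args$seed)) args$seed <- config$seed
  do.call(isok_config, args)
}

#' Simulate a dataset and write it to disk
#'
#' Runs [simulate_isokinetic()] under the run configuration and writes
#' `trials.csv` (canonical long format), `truth.json` (the ground-truth
#' record) and `run_config.yaml` (the resolved configuration, for
#' provenance) into `outdir`, creating it if needed.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @return Invisibly, the `"isok_sim"` object.
#' @export
run_simulate <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_isokinetic(resolve_isok_config(config))
  readr::write_csv(sim$samples, file.path(outdir, "trials.csv"))
  truth <- sim$truth
  truth$flex_extrema <- as.data.frame(truth$flex_extrema)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  write_run_config(config, file.path(outdir, "run_config.yaml"))
  invisible(sim)
}

action_modes <- function() {
  tidyr::expand_grid(action = c("extension", "flexion"),
                     mode = c("concentric", "eccentric"))
}

preprocess_trials <- function(trials, config) {
  trials |>
    filter_isokinetic(target_velocity_dps = config$target_velocity_dps,
                      tolerance_dps = config$tolerance_dps) |>
    select_best_repetition()
}

#' Fit the four action-mode models
#'
#' Reads the trials CSV (from `config$input` or `outdir/trials.csv`),
#' preprocesses it (truly-isokinetic filtering, best-repetition selection)
#' and fits one hierarchical GAM per (action, mode), each with its own
#' seed derived from the master seed. Draw matrices and metadata sidecars
#' are written per fit via [write_hgam_fit()], the cleaned model-ready data
#' to `model_data.csv`, and split-R-hat / effective-sample-size diagnostics
#' for all fits to `convergence.csv`. With `compare_models = TRUE` the
#' intercept-only variant (no per-athlete smooth deviations) is fitted as
#' well, under the same seed, for WAIC comparison.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of `"hgam_fit"` objects; comparison
#'   variants are suffixed `"_intercept_only"`.
#' @export
run_fit <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  input <- config$input %||% file.path(outdir, "trials.csv")
  trials <- read_trials(input, quiet = TRUE)
  dat <- preprocess_trials(trials, config)
  readr::write_csv(dat, file.path(outdir, "model_data.csv"))
  am <- action_modes()
  fits <- list()
  diag_rows <- list()
  for (k in seq_len(nrow(am))) {
    a <- am$action[k]; m <- am$mode[k]
    key <- paste(a, m, sep = "_")
    fit <- hgam_fit(dat, action = a, mode = m,
                    n_basis = config$n_basis,
                    n_basis_ind = config$n_basis_ind,
                    penalty_order = config$penalty_order,
                    chains = config$chains, n_iter = config$n_iter,
                    n_warmup = config$n_warmup, seed = config$seed + k)
    fits[[key]] <- fit
    write_hgam_fit(fit, file.path(outdir, paste0("fit_", key)))
    dg <- suppressWarnings(check_convergence(fit))
    dg$fit <- key
    diag_rows[[key]] <- dg
    if (isTRUE(config$compare_models)) {
      fit0 <- hgam_fit(dat, action = a, mode = m,
                       n_basis = config$n_basis,
                       n_basis_ind = config$n_basis_ind,
                       penalty_order = config$penalty_order,
                       individual_smooths = FALSE,
                       chains = config$chains, n_iter = config$n_iter,
                       n_warmup = config$n_warmup, seed = config$seed + k)
      fits[[paste0(key, "_intercept_only")]] <- fit0
      write_hgam_fit(fit0, file.path(outdir,
                                     paste0("fit_", key, "_intercept_only")))
    }
  }
  readr::write_csv(dplyr::bind_rows(diag_rows),
                   file.path(outdir, "convergence.csv"))
  invisible(fits)
}

#' Produce curves, ratio inference, WAIC tables and figures
#'
#' Turns the fitted models into the pipeline's outputs: per-action-mode
#' posterior curve summaries (`curve_*.csv`: `angle,mean,lower95,upper95`),
#' the two functional H:Q ratio curves (`ratio_extension.csv`,
#' `ratio_flexion.csv`), a JSON report of equality crossings and extrema
#' (`ratio_report.json`; extension results on both the anatomical and the
#' rescaled extension-progress axis), a WAIC comparison table
#' (`waic_comparison.csv`, one row per compared model per action-mode) and,
#' unless disabled, figure files analogous to per-action torque curves and
#' ratio curves.
#'
#' @param config A [run_config()].
#' @param outdir Output directory holding the fit artifacts.
#' @param fits Optional named fit list from [run_fit()]; when `NULL` the
#'   fits are reloaded from `outdir`.
#' @return Invisibly, a list with the curve tibbles, ratio curves and the
#'   WAIC table.
#' @export
run_report <- function(config, outdir, fits = NULL) {
  am <- action_modes()
  keys <- paste(am$action, am$mode, sep = "_")
  if (is.null(fits)) {
    fits <- list()
    for (key in keys) {
      fits[[key]] <- read_hgam_fit(file.path(outdir, paste0("fit_", key)))
      p0 <- file.path(outdir, paste0("fit_", key, "_intercept_only"))
      if (file.exists(paste0(p0, "_draws.csv"))) {
        fits[[paste0(key, "_intercept_only")]] <- read_hgam_fit(p0)
      }
    }
  }
  # report on the angle range actually observed after truly-isokinetic
  # filtering: the smoothers do not extrapolate beyond the data
  rng <- range(unlist(lapply(fits[keys], function(f) f$design$angle)))
  grid <- seq(ceiling(rng[1]), floor(rng[2]), by = config$grid_step)
  curves <- list()
  for (key in keys) {
    cd <- posterior_curve(fits[[key]], grid)
    td <- tidy(cd, level = config$level)
    names(td) <- c("angle", "mean", "lower95", "upper95")
    readr::write_csv(td, file.path(outdir, paste0("curve_", key, ".csv")))
    curves[[key]] <- cd
  }
  ratio_ext <- functional_ratio(curves$extension_eccentric,
                                curves$extension_concentric,
                                eps_torque = config$eps_torque)
  ratio_flex <- functional_ratio(curves$flexion_concentric,
                                 curves$flexion_eccentric,
                                 eps_torque = config$eps_torque)
  for (nm in c("extension", "flexion")) {
    rc <- if (nm == "extension") ratio_ext else ratio_flex
    readr::write_csv(tidy(rc), file.path(outdir, paste0("ratio_", nm, ".csv")))
  }
  report <- list(
    extension = list(
      crossings_flexion_deg = ratio_ext$crossings,
      crossings_progress_deg = rescale_extension_angle(ratio_ext$crossings),
      extrema = as.data.frame(ratio_ext$extrema)
    ),
    flexion = list(
      crossings_flexion_deg = ratio_flex$crossings,
      extrema = as.data.frame(ratio_flex$extrema)
    )
  )
  jsonlite::write_json(report, file.path(outdir, "ratio_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  waic_tbl <- NULL
  if (any(grepl("_intercept_only$", names(fits)))) {
    rows <- list()
    for (key in keys) {
      k0 <- paste0(key, "_intercept_only")
      if (is.null(fits[[k0]])) next
      cmp <- compare_waic(fits[[key]], fits[[k0]],
                          labels = c("intercept_plus_smooth_deviations",
                                     "intercept_only"))
      cmp$action_mode <- key
      cmp$elpd_diff <- attr(cmp, "elpd_diff")
      cmp$se_diff <- attr(cmp, "se_diff")
      rows[[key]] <- cmp
    }
    waic_tbl <- dplyr::bind_rows(rows)
    readr::write_csv(waic_tbl, file.path(outdir, "waic_comparison.csv"))
  }
  if (isTRUE(config$plots)) {
    for (key in keys) {
      p <- autoplot(curves[[key]], level = config$level,
                    rescale = grepl("^extension", key))
      ggplot2::ggsave(file.path(outdir, paste0("curve_", key, ".png")), p,
                      width = 6, height = 4, dpi = 120)
    }
    ggplot2::ggsave(file.path(outdir, "ratio_extension.png"),
                    autoplot(ratio_ext, rescale = TRUE),
                    width = 6, height = 4, dpi = 120)
    ggplot2::ggsave(file.path(outdir, "ratio_flexion.png"),
                    autoplot(ratio_flex),
                    width = 6, height = 4, dpi = 120)
  }
  invisible(list(curves = curves, ratio_extension = ratio_ext,
                 ratio_flexion = ratio_flex, waic = waic_tbl))
}

#' Run the full pipeline
#'
#' [run_simulate()] (skipped when `config$input` points at existing data),
#' then [run_fit()], then [run_report()], all inside `outdir`. Two runs
#' with the same configuration produce identical numeric outputs.
#'
#' @inheritParams run_fit
#' @return Invisibly, the [run_report()] result.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.null(config$input)) run_simulate(config, outdir)
  fits <- run_fit(config, outdir)
  run_report(config, outdir, fits = fits)
}

#' Serialize a fit to CSV draws plus a JSON sidecar
#'
#' Writes `<prefix>_draws.csv` (one row per retained iteration: chain index
#' followed by every coefficient and variance draw, labelled) and
#' `<prefix>_meta.json` (sampler settings, priors, bases, athlete order and
#' the model-ready data). [read_hgam_fit()] rebuilds the fit bit-exactly:
#' the CSV writer emits shortest round-trip representations and the sidecar
#' stores numbers at full precision, so the reconstructed draws, design and
#' pointwise log-likelihood equal the originals.
#'
#' @param fit An `"hgam_fit"` object.
#' @param prefix Path prefix for the two files.
#' @return Invisibly, `prefix`.
#' @export
write_hgam_fit <- function(fit, prefix) {
  draws <- tibble::as_tibble(cbind(chain = fit$chain, fit$theta,
                                   fit$variances), .name_repair = "minimal")
  names(draws) <- c("chain", theta_names(fit$design),
                    colnames(fit$variances))
  # print doubles with 17 significant digits so reloading is bit-exact
  draws <- dplyr::mutate(draws, dplyr::across(
    dplyr::where(is.double), function(x) sprintf("%.17g", x)))
  readr::write_csv(draws, paste0(prefix, "_draws.csv"))
  design <- fit$design
  meta <- list(
    action = fit$action, mode = fit$mode,
    n_iter = fit$n_iter, n_warmup = fit$n_warmup, chains = fit$chains,
    seed = fit$seed, priors = fit$priors,
    basis = list(domain = design$basis$domain,
                 n_basis = design$basis$n_basis,
                 degree = design$basis$degree,
                 penalty_order = design$basis$penalty_order),
    basis_ind = if (!is.null(design$basis_ind)) {
      list(domain = design$basis_ind$domain,
           n_basis = design$basis_ind$n_basis,
           degree = design$basis_ind$degree,
           penalty_order = design$basis_ind$penalty_order)
    },
    individual_smooths = design$individual_smooths,
    # numbers as %.17g strings: JSON writers round doubles, strings don't
    data = list(athlete_id = design$athletes[design$athlete_index],
                angle_deg = sprintf("%.17g", design$angle),
                torque_nm = sprintf("%.17g", design$y))
  )
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_hgam_fit
#' @export
read_hgam_fit <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  dat <- tibble::tibble(athlete_id = meta$data$athlete_id,
                        angle_deg = as.numeric(meta$data$angle_deg),
                        torque_nm = as.numeric(meta$data$torque_nm))
  basis <- smooth_basis(meta$basis$domain, meta$basis$n_basis,
                        meta$basis$degree, meta$basis$penalty_order)
  basis_ind <- if (!is.null(meta$basis_ind)) {
    smooth_basis(meta$basis_ind$domain, meta$basis_ind$n_basis,
                 meta$basis_ind$degree, meta$basis_ind$penalty_order)
  } else {
    smooth_basis(meta$basis$domain, n_basis = 6)
  }
  design <- hgam_design(dat, basis = basis, basis_ind = basis_ind,
                        individual_smooths = isTRUE(meta$individual_smooths))
  # base read.csv parses doubles via strtod (correctly rounded), which the
  # bit-exact round-trip contract relies on
  draws <- utils::read.csv(paste0(prefix, "_draws.csv"),
                           check.names = FALSE)
  chain <- as.integer(draws$chain)
  draws <- as.matrix(draws[, -1, drop = FALSE])
  p <- ncol(design$C)
  theta <- draws[, seq_len(p), drop = FALSE]
  variances <- draws[, (p + 1):ncol(draws), drop = FALSE]
  # recompute the pointwise log-likelihood with the same matrix-vector
  # product the sampler used, so the reload is bit-exact
  loglik <- t(vapply(seq_len(nrow(theta)), function(s) {
    dnorm(design$y, drop(design$C %*% theta[s, ]),
          sqrt(variances[s, "sigma2"]), log = TRUE)
  }, numeric(design$n)))
  structure(list(
    theta = unname(theta), variances = variances, loglik = loglik,
    chain = chain, design = design,
    n_iter = meta$n_iter, n_warmup = meta$n_warmup, chains = meta$chains,
    seed = meta$seed, priors = meta$priors, acceptance = 1,
    action = meta$action, mode = meta$mode
  ), class = "hgam_fit")
}
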