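# Skewed Gaussian bump with a baseline floor: value equals `peak` exactly at
# `peak_angle`; width differs left/right of the peak; tails level off at
# `base` so torques stay physiological at the range-of-motion ends.
skew_bump <- function(angle, base, peak, peak_angle, width_left, width_right) {
  w <- ifelse(angle < peak_angle, width_left, width_right)
  base + (peak - base) * exp(-0.5 * ((angle - peak_angle) / w)^2)
}

#' Configuration of the synthetic isokinetic study
#'
#' Bundles every knob of the synthetic-data generator, with defaults
#' emulating the study design the package targets: 30 athletes performing
#' five continuous maximal reciprocal knee extension/flexion repetitions at
#' a 60 deg/s target velocity over a 0--90 degree range of motion, with
#' smooth nonlinear population torque-angle curves, per-athlete intercept
#' and smooth-shape deviations, repetition-level offsets, and Gaussian
#' measurement noise.
#'
#' The default population curves are skewed Gaussian bumps with a baseline
#' floor, calibrated so that (i) the implied true functional H:Q ratio for
#' knee extension (eccentric hamstrings over concentric quadriceps) crosses
#' the point of equality exactly at 40 degrees of extension progress
#' (knee flexion 50 degrees), (ii) the true flexion ratio (concentric
#' hamstrings over eccentric quadriceps) is bimodal with peaks near 20 and
#' 80 degrees and a trough of about 0.54 near 55 degrees, never reaching
#' 1.0, and (iii) the eccentric-flexion torque curve has its marked peak at
#' exactly 55 degrees.
#'
#' @param n_athletes Number of athletes. Default 30.
#' @param n_repetitions Continuous maximal repetitions per action-mode.
#'   Default 5.
#' @param angle_step Angle sampling step in degrees. Default 1.
#' @param target_velocity Isokinetic target velocity, deg/s. Default 60.
#' @param ramp_fraction Fraction of the range of motion spent accelerating
#'   (and, symmetrically, decelerating); the limb is at target velocity in
#'   between. At 60 deg/s the acceleration and cushioning phases of a
#'   dynamometer are short, a few degrees of the arc, so the default is
#'   0.05 (truly isokinetic data over roughly 5--85 degrees).
#' @param curves Nested list `curves[[action]][[mode]]` of bump parameters
#'   (`base`, `peak`, `peak_angle`, `width_left`, `width_right`).
#' @param sd_intercept Between-athlete intercept SD `sigma_b`, N·m.
#'   Default 8.
#' @param sd_smooth_dev Root-mean-square amplitude over the range of motion
#'   of a per-athlete smooth shape deviation, N·m. Default 6.
#' @param sd_repetition Scale of the per-repetition scalar effort
#'   shortfall, N·m: within each athlete-action-mode group, offsets are
#'   `sd_repetition * (u - max(u))` with `u` standard normal, so every
#'   repetition but the best falls short of the athlete's capacity.
#'   Default 4.
#' @param sd_noise Residual measurement noise SD `sigma`, N·m. Default 6.
#' @param dev_n_basis Basis size of the per-athlete deviation smooths.
#'   Default 6 (matches the model's default individual basis).
#' @param dev_family `"bspline"` draws athlete deviations from the same
#'   P-spline family the model fits (well-specified case); `"fourier"` uses
#'   low-order sine waves instead (misspecified variant for robustness
#'   checks).
#' @param seed Default seed used by [simulate_isokinetic()]. Default 1.
#' @return A list of class `"isok_config"`.
#' @export
isok_config <- function(n_athletes = 30, n_repetitions = 5, angle_step = 1,
                        target_velocity = 60, ramp_fraction = 0.05,
                        curves = default_population_curves(),
                        sd_intercept = 8, sd_smooth_dev = 6,
                        sd_repetition = 4, sd_noise = 6,
                        dev_n_basis = 6, dev_family = c("bspline", "fourier"),
                        seed = 1) {
  dev_family <- match.arg(dev_family)
  cfg <- list(n_athletes = n_athletes, n_repetitions = n_repetitions,
              angle_step = angle_step, target_velocity = target_velocity,
              ramp_fraction = ramp_fraction, curves = curves,
              sd_intercept = sd_intercept, sd_smooth_dev = sd_smooth_dev,
              sd_repetition = sd_repetition, sd_noise = sd_noise,
              dev_n_basis = dev_n_basis, dev_family = dev_family, seed = seed)
  validate_isok_config(cfg)
  structure(cfg, class = "isok_config")
}

#' Default population torque-angle curves
#'
#' @return The nested curve-parameter list used by [isok_config()]; see
#'   that help page for the calibration the defaults satisfy.
#' @export
default_population_curves <- function() {
  list(
    extension = list(
      # quadriceps acting concentrically during knee extension
      concentric = list(base = 29, peak = 190, peak_angle = 60,
                        width_left = 36, width_right = 31),
      # hamstrings braking eccentrically during knee extension; peak height
      # solved so the true extension ratio crosses 1.0 at knee flexion 50
      eccentric = list(base = 63, peak = 211.0426, peak_angle = 64,
                       width_left = 22, width_right = 33)
    ),
    flexion = list(
      # hamstrings acting concentrically: broad plateau around 105-113 N·m
      concentric = list(base = 61, peak = 114, peak_angle = 53,
                        width_left = 35, width_right = 30),
      # quadriceps braking eccentrically: marked narrow peak at 55 degrees
      eccentric = list(base = 103, peak = 210, peak_angle = 55,
                       width_left = 15, width_right = 10)
    )
  )
}

validate_isok_config <- function(cfg) {
  pos_int <- function(x, nm) {
    if (!is.numeric(cfg[[x]]) || cfg[[x]] < 1) {
      abort(paste0("config field '", x, "' must be a positive integer"))
    }
  }
  pos_int("n_athletes"); pos_int("n_repetitions")
  for (nm in c("sd_intercept", "sd_smooth_dev", "sd_repetition", "sd_noise")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || is.na(cfg[[nm]]) ||
        cfg[[nm]] < 0) {
      abort(paste0("config field '", nm, "' must be a single SD >= 0"))
    }
  }
  if (!(cfg$ramp_fraction >= 0 && cfg$ramp_fraction < 0.5)) {
    abort("config field 'ramp_fraction' must lie in [0, 0.5)")
  }
  if (!(cfg$angle_step > 0)) abort("config field 'angle_step' must be > 0")
  if (!(cfg$target_velocity > 0)) {
    abort("config field 'target_velocity' must be > 0")
  }
  for (a in c("extension", "flexion")) for (m in c("concentric", "eccentric")) {
    cp <- cfg$curves[[a]][[m]]
    need <- c("base", "peak", "peak_angle", "width_left", "width_right")
    if (!all(need %in% names(cp))) {
      abort(paste0("curve parameters for ", a, "/", m, " must include: ",
                   paste(need, collapse = ", ")))
    }
    if (!(cp$peak_angle > 0 && cp$peak_angle < 90)) {
      abort(paste0("config field 'peak_angle' for ", a, "/", m,
                   " must lie in (0, 90)"))
    }
  }
  invisible(cfg)
}

#' True population torque-angle curve
#'
#' Deterministic smooth population torque at the given knee flexion angles
#' for one muscle action and contraction mode, under a generator
#' configuration.
#'
#' @param angle Knee flexion angles in `[0, 90]` degrees.
#' @param action `"extension"` or `"flexion"`.
#' @param mode `"concentric"` or `"eccentric"`.
#' @param config An [isok_config()] object.
#' @return Torque in N·m; at the configured peak angle the value equals the
#'   configured peak torque exactly.
#' @export
population_curve <- function(angle, action = c("extension", "flexion"),
                             mode = c("concentric", "eccentric"),
                             config = isok_config()) {
  action <- match.arg(action)
  mode <- match.arg(mode)
  if (any(angle < 0 | angle > 90)) abort("angle must lie in [0, 90]")
  cp <- config$curves[[action]][[mode]]
  skew_bump(angle, cp$base, cp$peak, cp$peak_angle,
            cp$width_left, cp$width_right)
}

# Trapezoidal velocity profile over the range of motion, as a function of
# movement progress fraction in [0, 1]. Unsigned magnitude.
velocity_profile <- function(frac, target, ramp) {
  v <- rep(target, length(frac))
  if (ramp > 0) {
    up <- frac < ramp
    down <- frac > 1 - ramp
    v[up] <- target * frac[up] / ramp
    v[down] <- target * (1 - frac[down]) / ramp
  }
  v
}

# Coefficient-scale SD giving athlete deviation curves the requested RMS
# amplitude over the domain: E dev(x)^2 = tau^2 * ||Z(x)||^2.
dev_coef_sd <- function(Z, sd_amplitude) {
  if (sd_amplitude == 0) return(0)
  sd_amplitude / sqrt(mean(rowSums(Z^2)))
}

#' Simulate a synthetic isokinetic study with known ground truth
#'
#' Generates long-format dynamometer samples with the statistical structure
#' the hierarchical GAM assumes: for every athlete, action, mode and
#' repetition, torque is the population curve plus a per-athlete intercept,
#' a per-athlete smooth shape deviation, a per-repetition scalar effort
#' shortfall, and
#' i.i.d. Gaussian noise. The velocity profile is a trapezoid (ramp-up,
#' constant target velocity, ramp-down) over the range of motion; during the
#' ramps the systematic torque is attenuated in proportion to the velocity
#' shortfall, so acceleration-phase samples are biased unless filtered out.
#' Repetition offsets are scalar, so the best repetition (greatest peak
#' torque) has a well-defined truth: the repetition with the largest offset.
#'
#' @param config An [isok_config()]; its defaults are the study conditions.
#' @param seed Integer seed; defaults to `config$seed`. The output is
#'   bit-reproducible given the seed.
#' @return A list of class `"isok_sim"` with elements
#' \describe{
#'   \item{samples}{tibble of trial rows in the canonical schema of
#'     [read_trials()].}
#'   \item{truth}{ground-truth record sufficient to score every downstream
#'     estimate: population curves on a 0.1-degree grid, true ratio curves
#'     with their equality crossings and extrema, the variance components
#'     (including the coefficient-scale deviation SD), per-athlete effects,
#'     per-repetition offsets, and the true best repetition per group.}
#'   \item{config}{the configuration used.}
#' }
#' @export
simulate_isokinetic <- function(config = isok_config(), seed = config$seed) {
  validate_isok_config(config)
  actions <- c("extension", "flexion")
  modes <- c("concentric", "eccentric")
  angles <- seq(0, 90, by = config$angle_step)
  npts <- length(angles)
  ids <- sprintf("ath%02d", seq_len(config$n_athletes))

  dev_basis <- smooth_basis(c(0, 90), n_basis = config$dev_n_basis,
                            penalty_order = 2)
  fine <- seq(0, 90, by = 0.1)
  if (config$dev_family == "bspline") {
    Zs <- basis_design(dev_basis, angles)$Z
    Zfine <- basis_design(dev_basis, fine)$Z
  } else {
    fourier <- function(x) sapply(1:4, function(k) sin(k * pi * x / 90))
    Zs <- fourier(angles)
    Zfine <- fourier(fine)
  }
  tau_ind <- dev_coef_sd(Zfine, config$sd_smooth_dev)

  withr::with_seed(seed, {
    grid_tbl <- tidyr::expand_grid(athlete_id = ids, action = actions,
                                   mode = modes)
    effects <- grid_tbl |>
      dplyr::mutate(
        b0 = rnorm(dplyr::n(), 0, config$sd_intercept),
        dev_coef = purrr::map(seq_len(dplyr::n()), function(i) {
          rnorm(ncol(Zs), 0, tau_ind)
        })
      )
    # repetition effects are nonpositive effort shortfalls from the
    # athlete's maximal capacity: the best repetition (largest offset)
    # attains the population curve exactly, so "best repetition" has an
    # unbiased, well-defined truth
    rep_offsets <- tidyr::expand_grid(
      athlete_id = ids, action = actions, mode = modes,
      repetition = seq_len(config$n_repetitions)
    ) |>
      dplyr::group_by(.data$athlete_id, .data$action, .data$mode) |>
      dplyr::mutate(offset = {
        u <- rnorm(dplyr::n())
        config$sd_repetition * (u - max(u))
      }) |>
      dplyr::ungroup()

    one_rep <- function(athlete_id, action, mode, repetition, b0, dev_coef,
                        offset) {
      # extension runs from deep flexion (90) to full extension (0)
      ang <- if (action == "extension") rev(angles) else angles
      frac <- if (action == "extension") (90 - ang) / 90 else ang / 90
      vmag <- velocity_profile(frac, config$target_velocity,
                               config$ramp_fraction)
      vsign <- if (action == "extension") -1 else 1
      ord <- match(ang, angles)
      systematic <- population_curve(ang, action, mode, config) + b0 +
        drop(Zs[ord, , drop = FALSE] %*% dev_coef) + offset
      atten <- 0.7 + 0.3 * vmag / config$target_velocity
      torque <- systematic * atten + rnorm(npts, 0, config$sd_noise)
      tibble::tibble(athlete_id = athlete_id, action = action, mode = mode,
                     repetition = as.integer(repetition), angle_deg = ang,
                     velocity_dps = vsign * vmag, torque_nm = torque)
    }

    samples <- rep_offsets |>
      dplyr::left_join(effects, by = c("athlete_id", "action", "mode")) |>
      purrr::pmap(one_rep) |>
      dplyr::bind_rows()
  })

  curves_fine <- tidyr::expand_grid(action = actions, mode = modes) |>
    dplyr::mutate(curve = purrr::map2(.data$action, .data$mode, function(a, m) {
      tibble::tibble(angle_deg = fine,
                     torque_nm = population_curve(fine, a, m, config))
    })) |>
    tidyr::unnest("curve")
  curve_of <- function(a, m) {
    curves_fine$torque_nm[curves_fine$action == a & curves_fine$mode == m]
  }
  ext_ratio <- curve_of("extension", "eccentric") /
    curve_of("extension", "concentric")
  flex_ratio <- curve_of("flexion", "concentric") /
    curve_of("flexion", "eccentric")
  ext_cross_flexion <- find_level_crossings(fine, ext_ratio, 1)
  flex_extrema <- find_extrema(fine, flex_ratio)
  best_rep <- rep_offsets |>
    dplyr::group_by(.data$athlete_id, .data$action, .data$mode) |>
    dplyr::slice_max(.data$offset, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("athlete_id", "action", "mode", best_repetition = "repetition")

  truth <- list(
    curves = curves_fine,
    ratios = tibble::tibble(angle_deg = fine, extension = ext_ratio,
                            flexion = flex_ratio),
    ext_crossing_flexion_deg = ext_cross_flexion,
    ext_crossing_progress_deg = rescale_extension_angle(ext_cross_flexion),
    flex_extrema = flex_extrema,
    ecc_flexion_peak_angle = fine[which.max(curve_of("flexion", "eccentric"))],
    sd_intercept = config$sd_intercept,
    sd_smooth_dev = config$sd_smooth_dev,
    tau_ind = tau_ind,
    sd_repetition = config$sd_repetition,
    sd_noise = config$sd_noise,
    athlete_effects = effects |>
      dplyr::mutate(dev_coef = purrr::map(.data$dev_coef, identity)),
    repetition_offsets = rep_offsets,
    best_repetition = best_rep,
    constant_velocity_fraction = mean(
      velocity_profile(angles / 90, config$target_velocity,
                       config$ramp_fraction) == config$target_velocity),
    seed = seed
  )
  structure(list(samples = samples, truth = truth, config = config),
            class = "isok_sim")
}

#' @export
print.isok_sim <- function(x, ...) {
  cat("Synthetic isokinetic study:", x$config$n_athletes, "athletes x",
      "4 action-modes x", x$config$n_repetitions, "repetitions,",
      nrow(x$samples), "rows (seed", x$truth$seed, ")\n")
  invisible(x)
}
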