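#' Read long-format isokinetic trial data
#'
#' Reads a comma-separated dynamometer export with one row per sampled
#' instant and validates it against the canonical trial schema:
#' `athlete_id`, `action` (`extension`/`flexion`), `mode`
#' (`concentric`/`eccentric`), `repetition` (integer, from 1), `angle_deg`
#' (knee flexion angle, 0 = full extension, 90 = deep flexion),
#' `velocity_dps` (signed angular velocity, deg/s) and `torque_nm`
#' (gravity-corrected moment of force, N·m).
#'
#' Rows failing validation (unparseable numbers, angles outside 0--90,
#' repetition < 1, non-finite torque, unknown action/mode labels) are dropped
#' and counted by reason; the counts are attached as the `"rejections"`
#' attribute and reported via a message. A missing required column is a hard
#' error naming the canonical column.
#'
#' @param path Path to a CSV file with a single header row.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(torque_nm = "moment")`. Unmapped
#'   canonical names are looked up directly.
#' @param quiet If `TRUE`, suppress the rejection-count message.
#'
#' @return A tibble of validated trial samples with the canonical columns,
#'   `repetition` as integer, and a `"rejections"` attribute (tibble with
#'   columns `reason`, `n`).
#' @seealso [filter_isokinetic()], [select_best_repetition()]
#' @export
read_trials <- function(path, col_map = NULL, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  canonical <- c("athlete_id", "action", "mode", "repetition",
                 "angle_deg", "velocity_dps", "torque_nm")
  map <- setNames(canonical, canonical)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), canonical)
    if (length(bad)) abort(paste0("unknown canonical column(s) in col_map: ",
                                  paste(bad, collapse = ", ")))
    map[names(col_map)] <- unname(col_map)
  }
  missing <- canonical[!map %in% names(raw)]
  if (length(missing)) {
    abort(paste0("required column(s) missing from ", path, ": ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    athlete_id = as.character(raw[[map["athlete_id"]]]),
    action     = tolower(trimws(raw[[map["action"]]])),
    mode       = tolower(trimws(raw[[map["mode"]]])),
    repetition = suppressWarnings(as.numeric(raw[[map["repetition"]]])),
    angle_deg  = suppressWarnings(as.numeric(raw[[map["angle_deg"]]])),
    velocity_dps = suppressWarnings(as.numeric(raw[[map["velocity_dps"]]])),
    torque_nm  = suppressWarnings(as.numeric(raw[[map["torque_nm"]]]))
  )
  validate_trials(out, quiet = quiet)
}

#' Validate trial samples against the canonical schema
#'
#' Applies the row-level invariants of the trial schema (see
#' [read_trials()]) to an in-memory data frame, dropping and counting
#' offending rows.
#'
#' @param data A data frame with the canonical trial columns.
#' @param quiet If `TRUE`, suppress the rejection-count message.
#' @return A validated tibble with a `"rejections"` attribute.
#' @export
validate_trials <- function(data, quiet = FALSE) {
  data <- tibble::as_tibble(data)
  unparseable <- is.na(data$repetition) | is.na(data$angle_deg) |
    is.na(data$velocity_dps) | is.na(data$torque_nm)
  reasons <- list(
    unparseable_numeric = unparseable,
    angle_out_of_range  = !unparseable &
      (data$angle_deg < 0 | data$angle_deg > 90),
    repetition_invalid  = !unparseable & data$repetition < 1,
    torque_not_finite   = !unparseable & !is.finite(data$torque_nm),
    unknown_action      = !data$action %in% c("extension", "flexion"),
    unknown_mode        = !data$mode %in% c("concentric", "eccentric")
  )
  reject <- Reduce(`|`, reasons)
  counts <- tibble::tibble(
    reason = names(reasons),
    n = unname(vapply(reasons, function(r) sum(r & reject, na.rm = TRUE),
                      integer(1)))
  )
  counts <- counts[counts$n > 0, , drop = FALSE]
  kept <- data[!reject, , drop = FALSE]
  kept$repetition <- as.integer(kept$repetition)
  if (!quiet && nrow(counts)) {
    inform(paste0("rejected ", sum(reject), " row(s): ",
                  paste0(counts$reason, "=", counts$n, collapse = ", ")))
  }
  attr(kept, "rejections") <- counts
  kept
}

#' Keep only truly isokinetic samples
#'
#' Retains the samples recorded while the limb actually moved at the target
#' angular velocity, i.e. those with `|abs(velocity_dps) - target| <=
#' tolerance`. The absolute value makes one band cover both movement
#' directions, whose raw velocities carry opposite signs. Acceleration and
#' deceleration phases at the ends of the range of motion are thereby
#' excluded. Row order is preserved.
#'
#' @param data A trial tibble (see [read_trials()]).
#' @param target_velocity_dps Target angular velocity, deg/s. Default 60.
#' @param tolerance_dps Half-width of the accepted velocity band, deg/s
#'   (must be > 0; `Inf` keeps everything). Default 6 (10% of 60 deg/s).
#' @return The filtered tibble. A warning names any (athlete, action, mode)
#'   group left empty.
#' @export
filter_isokinetic <- function(data, target_velocity_dps = 60, tolerance_dps = 6) {
  stopifnot(is.numeric(tolerance_dps), length(tolerance_dps) == 1)
  if (!(tolerance_dps > 0)) abort("tolerance_dps must be > 0")
  data <- tibble::as_tibble(data)
  keep <- abs(abs(data$velocity_dps) - target_velocity_dps) <= tolerance_dps
  out <- data[keep, , drop = FALSE]
  groups_in <- dplyr::distinct(data, .data$athlete_id, .data$action, .data$mode)
  groups_out <- dplyr::distinct(out, .data$athlete_id, .data$action, .data$mode)
  emptied <- dplyr::anti_join(groups_in, groups_out,
                              by = c("athlete_id", "action", "mode"))
  if (nrow(emptied)) {
    warn(paste0("no truly isokinetic samples left for group(s): ",
                paste(paste(emptied$athlete_id, emptied$action, emptied$mode,
                            sep = "/"), collapse = "; ")))
  }
  out
}

#' Select the best repetition per athlete, action and mode
#'
#' Within each (athlete, action, mode) group, picks the repetition attaining
#' the greatest peak torque; ties are broken by the lowest repetition number.
#' Exactly one repetition contributes per group afterwards. An `axis` column
#' records the angle convention in force (`"flexion_angle"`).
#'
#' @param data A trial tibble, typically after [filter_isokinetic()].
#' @return A tibble restricted to the best repetition of each group, in the
#'   original sample order, with an added `axis` column.
#' @export
select_best_repetition <- function(data) {
  data <- tibble::as_tibble(data)
  if (!nrow(data)) {
    warn("no samples supplied; returning empty selection")
    return(dplyr::mutate(data, axis = character(0)))
  }
  peaks <- data |>
    dplyr::group_by(.data$athlete_id, .data$action, .data$mode, .data$repetition) |>
    dplyr::summarise(peak = max(.data$torque_nm), .groups = "drop") |>
    dplyr::group_by(.data$athlete_id, .data$action, .data$mode) |>
    dplyr::arrange(dplyr::desc(.data$peak), .data$repetition,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("athlete_id", "action", "mode", "repetition")
  data |>
    dplyr::semi_join(peaks, by = c("athlete_id", "action", "mode", "repetition")) |>
    dplyr::mutate(axis = "flexion_angle")
}

#' Rescale knee-flexion angles to extension progress
#'
#' Knee extension starts from deep flexion (90 degrees) and ends at full
#' extension (0 degrees). For display, extension results are conventionally
#' shown on a rescaled axis with 0 at the start of the action, i.e.
#' `90 - angle`. The mapping is an involution: applying it twice returns the
#' input.
#'
#' @param angle_deg Numeric vector of knee flexion angles in `[0, 90]`.
#' @return `90 - angle_deg`, the extension-progress angle in degrees.
#' @export
rescale_extension_angle <- function(angle_deg) {
  if (!is.numeric(angle_deg)) abort("angle_deg must be numeric")
  if (any(!is.na(angle_deg) & (angle_deg < 0 | angle_deg > 90))) {
    abort("angle_deg must lie in [0, 90]")
  }
  90 - angle_deg
}
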