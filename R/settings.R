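#' Detection settings
#'
#' Parameters of the eye-openness blink classifier and of the pupil-size
#' comparison detector. Defaults are the recommended operating point for
#' 600 Hz recordings.
#'
#' @param gap_fill_ms Maximum duration (ms) of a data-loss gap that is
#'   repaired by linear interpolation before detection. Default 40.
#' @param filter_len_ms Length (ms) of the Savitzky-Golay smoothing and
#'   differentiation window. Default 25.
#' @param min_amplitude_frac Minimum blink amplitude as a fraction of the
#'   "fully open" eyelid level (the median of the eye-openness signal).
#'   Default 0.10.
#' @param onset_vel_mad_factor Velocity threshold for onset/offset expansion,
#'   in multiples of the MAD of the velocity signal. Default 3.
#' @param min_peak_vel_mad_factor Minimum peak closing/opening velocity a
#'   blink must reach (the lower of the two peaks is tested), in MAD
#'   multiples. Default 2.
#' @param min_duration_ms Minimum blink duration in ms. Default 30.
#' @param merge_ms Blinks separated by less than this many ms are merged.
#'   Default 100.
#' @param ps_exclude_nonpositive Exclude non-positive pupil-size values
#'   before PS detection. Default `FALSE`.
#' @param ps_min_diameter_mm,ps_max_diameter_mm Optional physiological
#'   plausibility bounds on pupil diameter (mm); `NULL` disables a bound.
#'   Typical values when enabled: 2 and 7.
#' @param ps_exclusion_margin_ms Margin (ms) invalidated on each side of a
#'   bound-violating run. Default 50.
#' @param deg_per_mm Conversion factor for reporting eyelid velocities in
#'   degrees per second; eyelid travel of about 12 mm spans roughly 60
#'   degrees of lid rotation. Default 5. Reporting only; detection operates
#'   in mm.
#'
#' @return An object of class `detection_settings` (a validated list).
#' @export
detection_settings <- function(gap_fill_ms = 40,
                               filter_len_ms = 25,
                               min_amplitude_frac = 0.10,
                               onset_vel_mad_factor = 3,
                               min_peak_vel_mad_factor = 2,
                               min_duration_ms = 30,
                               merge_ms = 100,
                               ps_exclude_nonpositive = FALSE,
                               ps_min_diameter_mm = NULL,
                               ps_max_diameter_mm = NULL,
                               ps_exclusion_margin_ms = 50,
                               deg_per_mm = 5.0) {
  s <- list(
    gap_fill_ms = gap_fill_ms,
    filter_len_ms = filter_len_ms,
    min_amplitude_frac = min_amplitude_frac,
    onset_vel_mad_factor = onset_vel_mad_factor,
    min_peak_vel_mad_factor = min_peak_vel_mad_factor,
    min_duration_ms = min_duration_ms,
    merge_ms = merge_ms,
    ps_exclude_nonpositive = isTRUE(ps_exclude_nonpositive),
    ps_min_diameter_mm = ps_min_diameter_mm,
    ps_max_diameter_mm = ps_max_diameter_mm,
    ps_exclusion_margin_ms = ps_exclusion_margin_ms,
    deg_per_mm = deg_per_mm
  )
  validate_settings(s)
  structure(s, class = "detection_settings")
}

validate_settings <- function(s) {
  durs <- c(s$gap_fill_ms, s$filter_len_ms, s$min_duration_ms, s$merge_ms,
            s$ps_exclusion_margin_ms)
  if (any(!is.finite(durs)) || any(durs < 0)) {
    stop("all durations must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(s$min_amplitude_frac) ||
      s$min_amplitude_frac <= 0 || s$min_amplitude_frac >= 1) {
    stop("`min_amplitude_frac` must lie in (0, 1)", call. = FALSE)
  }
  if (!(s$onset_vel_mad_factor >= s$min_peak_vel_mad_factor &&
        s$min_peak_vel_mad_factor > 0)) {
    stop("need onset_vel_mad_factor >= min_peak_vel_mad_factor > 0",
         call. = FALSE)
  }
  if (!is.null(s$ps_min_diameter_mm) && !is.null(s$ps_max_diameter_mm) &&
      s$ps_min_diameter_mm >= s$ps_max_diameter_mm) {
    stop("ps_min_diameter_mm must be < ps_max_diameter_mm", call. = FALSE)
  }
  if (!is.finite(s$deg_per_mm) || s$deg_per_mm <= 0) {
    stop("`deg_per_mm` must be > 0", call. = FALSE)
  }
  invisible(s)
}

#' @export
print.detection_settings <- function(x, ...) {
  cat("<detection_settings>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, if (is.null(v)) "off" else format(v)))
  }
  invisible(x)
}

#' Read detection settings from JSON
#'
#' The JSON object may contain any subset of the [detection_settings()]
#' fields; missing fields take their defaults. Unknown keys are an error.
#'
#' @param path Path to a JSON file.
#' @return A `detection_settings` object.
#' @export
read_settings <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(detection_settings))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown settings key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(detection_settings, x)
}

#' Write detection settings to JSON
#'
#' @param settings A [detection_settings()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_settings <- function(settings, path) {
  jsonlite::write_json(unclass(settings), path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pupil-size detector options
#'
#' Options for the pupil-size (data-loss) blink detector, including the
#' optional physiological exclusion criteria and optional event-duration
#' bounds. All options are disabled by default, matching the plain
#' three-step detector (interpolate short gaps, take remaining invalid runs
#' as blinks, merge close runs).
#'
#' @param exclude_nonpositive Mark non-positive pupil diameters invalid.
#' @param min_diameter_mm,max_diameter_mm Optional plausibility bounds (mm);
#'   `NULL` disables a bound. Typical values when enabled: 2 and 7.
#' @param exclusion_margin_ms Margin (ms) invalidated on each side of every
#'   bound-violating run. Default 50.
#' @param min_duration_ms,max_duration_ms Optional bounds on event duration
#'   (ms); events outside the bounds are dropped. `NULL` disables a bound.
#' @return An object of class `ps_options`.
#' @export
ps_options <- function(exclude_nonpositive = FALSE,
                       min_diameter_mm = NULL,
                       max_diameter_mm = NULL,
                       exclusion_margin_ms = 50,
                       min_duration_ms = NULL,
                       max_duration_ms = NULL) {
  if (!is.null(min_diameter_mm) && !is.null(max_diameter_mm) &&
      min_diameter_mm >= max_diameter_mm) {
    stop("min_diameter_mm must be < max_diameter_mm", call. = FALSE)
  }
  if (exclusion_margin_ms < 0) stop("margins must be >= 0", call. = FALSE)
  structure(
    list(exclude_nonpositive = isTRUE(exclude_nonpositive),
         min_diameter_mm = min_diameter_mm,
         max_diameter_mm = max_diameter_mm,
         exclusion_margin_ms = exclusion_margin_ms,
         min_duration_ms = min_duration_ms,
         max_duration_ms = max_duration_ms),
    class = "ps_options"
  )
}

#' Derive pupil-size options from detection settings
#'
#' Maps the `ps_*` fields of a [detection_settings()] object onto a
#' [ps_options()] object.
#'
#' @param settings A `detection_settings` object.
#' @return A `ps_options` object.
#' @export
ps_options_from_settings <- function(settings) {
  ps_options(
    exclude_nonpositive = settings$ps_exclude_nonpositive,
    min_diameter_mm = settings$ps_min_diameter_mm,
    max_diameter_mm = settings$ps_max_diameter_mm,
    exclusion_margin_ms = settings$ps_exclusion_margin_ms
  )
}
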