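#' Apply physiological exclusion criteria to a pupil-size series
#'
#' Marks samples invalid when their pupil diameter violates the enabled
#' plausibility bounds (non-positive values and/or values outside
#' `[min_diameter_mm, max_diameter_mm]`), and additionally invalidates all
#' samples within `exclusion_margin_ms` of each violating run. Exclusions
#' never re-validate a sample, so data loss is monotone non-decreasing
#' under this operation.
#'
#' @param ps A pupil-size [sample_series()].
#' @param opts A [ps_options()] object.
#' @return A new `sample_series`.
#' @export
apply_exclusions <- function(ps, opts) {
  enabled <- opts$exclude_nonpositive || !is.null(opts$min_diameter_mm) ||
    !is.null(opts$max_diameter_mm)
  if (!enabled) return(ps)
  bad <- rep(FALSE, length(ps$t))
  val <- ps$value
  ok <- ps$valid & !is.na(val)
  if (opts$exclude_nonpositive) bad <- bad | (ok & val <= 0)
  if (!is.null(opts$min_diameter_mm)) bad <- bad | (ok & val < opts$min_diameter_mm)
  if (!is.null(opts$max_diameter_mm)) bad <- bad | (ok & val > opts$max_diameter_mm)
  if (!any(bad)) return(ps)
  margin_n <- as.integer(round(opts$exclusion_margin_ms / 1000 * ps$fs))
  if (margin_n > 0) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    n <- length(bad)
    for (k in which(r$values)) {
      lo <- max(1L, starts[k] - margin_n)
      hi <- min(n, ends[k] + margin_n)
      bad[lo:hi] <- TRUE
    }
  }
  series_replace(ps, valid = ps$valid & !bad)
}

#' Detect blinks from data loss in a pupil-size signal
#'
#' The traditional comparison detector: blinks are the stretches where the
#' eye tracker reported no pupil. Three steps:
#' \enumerate{
#'   \item interpolate data-loss gaps shorter than `gap_fill_ms`;
#'   \item turn every remaining maximal invalid run into an event whose
#'     onset is the time of the first invalid sample and whose offset is
#'     the time of the first valid sample after the run;
#'   \item merge events separated by less than `merge_ms`.
#' }
#' Events are half-open intervals, so an interior gap of `k` samples at
#' sampling interval `1/fs` has duration exactly `k/fs`. A run reaching the
#' series end is closed one nominal interval after the last sample and
#' flagged `clipped`. Optional physiological exclusions are applied first
#' (see [apply_exclusions()]) and optional duration bounds last. Kinematic
#' fields are `NA`: the pupil-size signal carries no eyelid information.
#'
#' @param ps A pupil-size [sample_series()].
#' @param settings A [detection_settings()] object (`gap_fill_ms`,
#'   `merge_ms` are used).
#' @param opts A [ps_options()] object.
#' @return A `blink_events` table with `source = "ps"`.
#' @export
detect_ps_blinks <- function(ps, settings = detection_settings(),
                             opts = ps_options_from_settings(settings)) {
  if (!inherits(ps, "sample_series")) {
    stop("`ps` must be a sample_series", call. = FALSE)
  }
  ps_x <- apply_exclusions(ps, opts)
  ps_x <- interpolate_gaps(ps_x, settings$gap_fill_ms)
  runs <- find_invalid_runs(ps_x)
  n <- length(ps_x$t)
  dt <- 1 / ps_x$fs
  if (nrow(runs) == 0) return(empty_blink_events())
  onset_t <- ps_x$t[runs$start]
  at_end <- runs$end > n
  offset_t <- ifelse(at_end, ps_x$t[n] + dt, ps_x$t[pmin(runs$end, n)])
  ev <- data.frame(
    eye = ps_x$eye, source = "ps",
    onset_t = onset_t, offset_t = offset_t,
    duration = offset_t - onset_t,
    clipped = at_end | runs$start == 1L,
    stringsAsFactors = FALSE
  )
  # merge runs separated by less than merge_ms
  if (nrow(ev) > 1) {
    repeat {
      gaps <- ev$onset_t[-1] - ev$offset_t[-nrow(ev)]
      k <- which(gaps < settings$merge_ms / 1000)
      if (length(k) == 0) break
      k <- k[1]
      ev$offset_t[k] <- ev$offset_t[k + 1]
      ev$duration[k] <- ev$offset_t[k] - ev$onset_t[k]
      ev$clipped[k] <- ev$clipped[k] || ev$clipped[k + 1]
      ev <- ev[-(k + 1), , drop = FALSE]
    }
  }
  if (!is.null(opts$min_duration_ms)) {
    ev <- ev[ev$duration >= opts$min_duration_ms / 1000, , drop = FALSE]
  }
  if (!is.null(opts$max_duration_ms)) {
    ev <- ev[ev$duration <= opts$max_duration_ms / 1000, , drop = FALSE]
  }
  as_blink_events(ev)
}
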