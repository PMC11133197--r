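#' Match two event streams one-to-one
#'
#' Pairs events from a reference stream with events from a test stream. A
#' pair is admissible only when the two events overlap in time; among the
#' admissible partners of a reference event, the one with the largest
#' temporal overlap wins. Pairing is resolved greedily in reference onset
#' order, with ties broken in favor of the earlier test-event onset. Each
#' event appears in at most one pair. Matched pairs are true positives,
#' unmatched test events false positives and unmatched reference events
#' false negatives; the event-based F1 score is
#' `2*TP / (2*TP + FP + FN)`, defined as 1 when both streams are empty.
#'
#' @param ref,test `blink_events` tables, each sorted by onset and
#'   internally non-overlapping.
#' @return An object of class `match_result`: a list with `pairs` (data
#'   frame of `ref_idx`, `test_idx`, `overlap_s`), `unmatched_ref`,
#'   `unmatched_test` (index vectors), `tp`, `fp`, `fn`, `f1`, and copies
#'   of `ref` and `test`.
#' @export
match_events <- function(ref, test) {
  check_event_list(ref, require_sorted = TRUE, require_disjoint = TRUE)
  check_event_list(test, require_sorted = TRUE, require_disjoint = TRUE)
  nr <- nrow(ref)
  nt <- nrow(test)
  used <- rep(FALSE, nt)
  pairs <- data.frame(ref_idx = integer(), test_idx = integer(),
                      overlap_s = numeric())
  for (i in seq_len(nr)) {
    if (nt == 0) break
    ov <- pmin(ref$offset_t[i], test$offset_t) -
      pmax(ref$onset_t[i], test$onset_t)
    ov[used] <- -Inf
    if (all(ov <= 0)) next
    best <- max(ov)
    j <- which(ov == best)[1] # earliest test onset among ties (sorted order)
    used[j] <- TRUE
    pairs <- rbind(pairs, data.frame(ref_idx = i, test_idx = j,
                                     overlap_s = best))
  }
  tp <- nrow(pairs)
  fp <- nt - tp
  fn <- nr - tp
  f1 <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(
    list(pairs = pairs,
         unmatched_ref = setdiff(seq_len(nr), pairs$ref_idx),
         unmatched_test = setdiff(seq_len(nt), pairs$test_idx),
         tp = tp, fp = fp, fn = fn, f1 = f1,
         ref = ref, test = test),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP=%d FP=%d FN=%d F1=%.4f\n",
              x$tp, x$fp, x$fn, x$f1))
  invisible(x)
}

#' Onset and offset differences of matched events
#'
#' For every matched pair, computes `onset_ref - onset_test` and
#' `offset_ref - offset_test` (seconds; negative onset delta means the
#' reference event starts earlier) and summarizes them.
#'
#' @param match A [match_events()] result with at least one pair.
#' @return A list with `onset_mean`, `onset_sd`, `offset_mean`,
#'   `offset_sd` (seconds, sample SD), `n_pairs`, and the per-pair vectors
#'   `onset_delta`, `offset_delta`.
#' @export
onset_offset_deltas <- function(match) {
  if (!inherits(match, "match_result")) {
    stop("`match` must be a match_result", call. = FALSE)
  }
  if (nrow(match$pairs) == 0) stop("no matched pairs", call. = FALSE)
  i <- match$pairs$ref_idx
  j <- match$pairs$test_idx
  d_on <- match$ref$onset_t[i] - match$test$onset_t[j]
  d_off <- match$ref$offset_t[i] - match$test$offset_t[j]
  list(
    onset_mean = mean(d_on), onset_sd = if (length(d_on) > 1) sd(d_on) else 0,
    offset_mean = mean(d_off), offset_sd = if (length(d_off) > 1) sd(d_off) else 0,
    n_pairs = length(d_on), onset_delta = d_on, offset_delta = d_off
  )
}

#' Summarize an event stream
#'
#' Blink rate and moments of duration, phase amplitudes and peak speeds
#' over a recording. Kinematic summaries are `NA` when the corresponding
#' fields are absent (pupil-size events).
#'
#' @param events A `blink_events` table.
#' @param recording_duration_s Duration of the recording in seconds (`> 0`).
#' @return A list with `n`, `rate_hz`, `duration_mean`, `duration_sd`
#'   (seconds), `closing_amp_mean`, `opening_amp_mean` (mm),
#'   `peak_closing_vel_mean`, `peak_opening_vel_mean` (mm/s).
#' @export
summarize_events <- function(events, recording_duration_s) {
  if (!is.finite(recording_duration_s) || recording_duration_s <= 0) {
    stop("`recording_duration_s` must be > 0", call. = FALSE)
  }
  n <- nrow(events)
  m <- function(x) if (n == 0 || all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  s <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else sd(x)
  }
  list(
    n = n,
    rate_hz = n / recording_duration_s,
    duration_mean = m(events$duration), duration_sd = s(events$duration),
    closing_amp_mean = m(events$closing_amp),
    opening_amp_mean = m(events$opening_amp),
    peak_closing_vel_mean = m(events$peak_closing_vel),
    peak_opening_vel_mean = m(events$peak_opening_vel)
  )
}

#' Data-quality report for a series
#'
#' Data loss is the number of invalid samples divided by all samples in the
#' series. RMS-S2S precision is the root mean square of the differences
#' between consecutive samples, over pairs where both samples are valid; it
#' is `NA` when no such pair exists. The whole series enters the
#' computation, including blink periods, so eyelid motion contributes to
#' the RMS-S2S of an eye-openness signal.
#'
#' @param series A [sample_series()] with at least one sample (two for
#'   RMS-S2S).
#' @return A list of class `quality_report` with `n_samples`, `n_valid`,
#'   `data_loss_frac` and `rms_s2s` (signal units, mm).
#' @export
quality_report <- function(series) {
  n <- length(series$t)
  if (n == 0) stop("empty series", call. = FALSE)
  n_valid <- sum(series$valid)
  both <- series$valid[-1] & series$valid[-n]
  d <- diff(series$value)[both]
  structure(
    list(n_samples = n, n_valid = n_valid,
         data_loss_frac = 1 - n_valid / n,
         rms_s2s = if (length(d) == 0) NA_real_ else sqrt(mean(d^2))),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> n=%d, loss=%.2f%%, RMS-S2S=%s mm\n",
              x$n_samples, 100 * x$data_loss_frac,
              format(x$rms_s2s, digits = 4)))
  invisible(x)
}

#' Convert an eyelid velocity from mm/s to deg/s
#'
#' Reporting convenience: eyelid travel of about 12 mm corresponds to about
#' 60 degrees of lid rotation, i.e. 5 deg/mm; the mapping is approximately
#' linear over the range of typical blinks.
#'
#' @param v_mm_per_s Velocity in mm/s (vectorized).
#' @param deg_per_mm Conversion factor (`> 0`), default 5.
#' @return Velocity in deg/s.
#' @export
mm_to_deg <- function(v_mm_per_s, deg_per_mm = 5.0) {
  if (!is.finite(deg_per_mm) || deg_per_mm <= 0) {
    stop("`deg_per_mm` must be > 0", call. = FALSE)
  }
  v_mm_per_s * deg_per_mm
}
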