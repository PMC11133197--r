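# canonical column order of a blink-event table
EVENT_COLS <- c(
  "eye", "source", "onset_t", "offset_t", "duration", "t_min_openness",
  "eo_onset", "eo_offset", "eo_min", "closing_amp", "opening_amp",
  "peak_closing_vel", "t_peak_closing", "peak_opening_vel", "t_peak_opening",
  "clipped"
)

#' Empty blink-event table
#'
#' @return A zero-row data frame of class `blink_events` with the canonical
#'   column set: `eye`, `source`, `onset_t`, `offset_t`, `duration`,
#'   `t_min_openness`, `eo_onset`, `eo_offset`, `eo_min`, `closing_amp`,
#'   `opening_amp`, `peak_closing_vel`, `t_peak_closing`,
#'   `peak_opening_vel`, `t_peak_opening`, `clipped`. Kinematic columns are
#'   `NA` for events detected from the pupil-size signal.
#' @export
empty_blink_events <- function() {
  df <- data.frame(
    eye = character(), source = character(),
    onset_t = numeric(), offset_t = numeric(), duration = numeric(),
    t_min_openness = numeric(), eo_onset = numeric(), eo_offset = numeric(),
    eo_min = numeric(), closing_amp = numeric(), opening_amp = numeric(),
    peak_closing_vel = numeric(), t_peak_closing = numeric(),
    peak_opening_vel = numeric(), t_peak_opening = numeric(),
    clipped = logical(),
    stringsAsFactors = FALSE
  )
  class(df) <- c("blink_events", "data.frame")
  df
}

as_blink_events <- function(df) {
  missing <- setdiff(EVENT_COLS, names(df))
  for (nm in missing) df[[nm]] <- NA
  df <- df[, EVENT_COLS, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("blink_events", "data.frame")
  df
}

# sanity checks shared by writers and the matcher
check_event_list <- function(events, require_sorted = TRUE,
                             require_disjoint = FALSE) {
  if (!is.data.frame(events)) stop("expected a blink-event table", call. = FALSE)
  n <- nrow(events)
  if (n == 0) return(invisible(events))
  if (any(events$offset_t <= events$onset_t)) {
    stop("every event must have onset_t < offset_t", call. = FALSE)
  }
  if (require_sorted && n > 1 && is.unsorted(events$onset_t)) {
    stop("events must be sorted by onset_t", call. = FALSE)
  }
  if (require_disjoint && n > 1 &&
      any(events$onset_t[-1] < events$offset_t[-n])) {
    stop("events must not overlap", call. = FALSE)
  }
  invisible(events)
}
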