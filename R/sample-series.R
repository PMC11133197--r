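#' Construct a sample series
#'
#' One channel of an eye-tracking recording: timestamps, measurement values
#' and per-sample validity. Invalid samples carry `NA` as their value; a
#' valid sample is never `NA`.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param value Numeric vector of measurements in mm (eye openness or pupil
#'   diameter), same length as `t`. Values at invalid samples are replaced
#'   by `NA`.
#' @param valid Logical vector of per-sample validity. Defaults to samples
#'   whose value is a positive finite number.
#' @param fs Nominal sampling frequency in Hz.
#' @param channel Channel label, `"eo"` (eye openness) or `"ps"` (pupil size).
#' @param eye Eye label, `"left"` or `"right"`.
#'
#' @return An object of class `sample_series`: a list with elements `t`,
#'   `value`, `valid`, `fs`, `channel`, `eye`.
#'
#' @details A warning is issued when the median sample interval deviates by
#'   more than 20% from `1/fs`, which usually indicates a wrong `fs` or a
#'   wrong timestamp unit.
#' @export
sample_series <- function(t, value, valid = NULL, fs,
                          channel = c("eo", "ps"), eye = c("left", "right")) {
  channel <- match.arg(channel)
  eye <- match.arg(eye)
  t <- as.numeric(t)
  value <- as.numeric(value)
  if (length(t) != length(value)) {
    stop("`t` and `value` must have the same length", call. = FALSE)
  }
  if (is.null(valid)) {
    valid <- is.finite(value) & value > 0
  }
  valid <- as.logical(valid)
  if (length(valid) != length(t)) {
    stop("`valid` must have the same length as `t`", call. = FALSE)
  }
  valid[is.na(valid)] <- FALSE
  if (anyNA(t)) stop("timestamps must not contain NA", call. = FALSE)
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  value[!valid] <- NA_real_
  if (any(valid & !is.finite(value))) {
    # cannot happen after the NA assignment above, kept as a guard
    stop("valid samples must have finite values", call. = FALSE)
  }
  if (length(t) > 1) {
    med_dt <- median(diff(t))
    if (abs(med_dt - 1 / fs) > 0.2 / fs) {
      warning(sprintf(
        "median sample interval (%.6g s) deviates more than 20%% from 1/fs (%.6g s)",
        med_dt, 1 / fs
      ), call. = FALSE)
    }
  }
  structure(
    list(t = t, value = value, valid = valid, fs = fs,
         channel = channel, eye = eye),
    class = "sample_series"
  )
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf(
    "<sample_series> %s/%s: %d samples @ %g Hz, %.2f%% invalid, span %.3f s\n",
    x$channel, x$eye, length(x$t), x$fs,
    100 * mean(!x$valid), if (length(x$t)) diff(range(x$t)) else 0
  ))
  invisible(x)
}

#' @export
length.sample_series <- function(x) length(x$t)

#' Construct a recording
#'
#' A container for up to four sample series (eye openness and pupil size,
#' left and right eye) that share a common time base.
#'
#' @param series Named list of [sample_series()] objects. Names must be of
#'   the form `"eo_left"`, `"eo_right"`, `"ps_left"`, `"ps_right"`.
#' @param participant,condition Optional labels stored in `meta`.
#' @param notes Optional free-form notes (e.g. load warnings).
#'
#' @return An object of class `recording`: a list with elements `series` and
#'   `meta`.
#' @export
recording <- function(series, participant = NA_character_,
                      condition = NA_character_, notes = character()) {
  if (!is.list(series) || length(series) == 0) {
    stop("`series` must be a non-empty named list of sample_series", call. = FALSE)
  }
  allowed <- c("eo_left", "eo_right", "ps_left", "ps_right")
  nms <- names(series)
  if (is.null(nms) || !all(nms %in% allowed)) {
    stop("series names must be among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  ok <- vapply(series, inherits, logical(1), what = "sample_series")
  if (!all(ok)) stop("all elements of `series` must be sample_series", call. = FALSE)
  t0 <- series[[1]]$t
  for (s in series) {
    if (length(s$t) != length(t0) || any(s$t != t0)) {
      stop("all series in a recording must share identical timestamps",
           call. = FALSE)
    }
  }
  structure(
    list(series = series,
         meta = list(participant = participant, condition = condition,
                     notes = notes)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> participant=%s condition=%s\n",
              x$meta$participant, x$meta$condition))
  for (s in x$series) print(s)
  if (length(x$meta$notes)) cat("notes:", paste(x$meta$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Extract one series from a recording
#'
#' @param rec A [recording()].
#' @param channel `"eo"` or `"ps"`.
#' @param eye `"left"` or `"right"`.
#' @return The requested [sample_series()].
#' @export
get_series <- function(rec, channel = c("eo", "ps"), eye = c("left", "right")) {
  channel <- match.arg(channel)
  eye <- match.arg(eye)
  key <- paste(channel, eye, sep = "_")
  s <- rec$series[[key]]
  if (is.null(s)) stop("recording has no series `", key, "`", call. = FALSE)
  s
}

# internal: replace the value/valid vectors of a series, keeping metadata
series_replace <- function(series, value = series$value, valid = series$valid) {
  series$value <- value
  series$valid <- valid
  series$value[!series$valid] <- NA_real_
  series
}
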