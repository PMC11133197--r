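#' Find runs of invalid samples
#'
#' Locates maximal runs of `valid == FALSE` in a series. Index intervals are
#' half-open: `start` is the first invalid sample, `end` is one past the
#' last. The run duration counts the full lost span, i.e. the time covered
#' by the invalid samples plus one nominal sample interval.
#'
#' @param series A [sample_series()].
#' @return A data frame with columns `start`, `end` (integer indices,
#'   half-open) and `duration_ms`.
#' @export
find_invalid_runs <- function(series) {
  v <- series$valid
  n <- length(v)
  empty <- data.frame(start = integer(), end = integer(),
                      duration_ms = numeric())
  if (n == 0 || all(v)) return(empty)
  r <- rle(!v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]
  ends_incl <- ends[keep]
  dt_ms <- 1000 / series$fs
  data.frame(
    start = starts,
    end = ends_incl + 1L,
    duration_ms = (series$t[ends_incl] - series$t[starts]) * 1000 + dt_ms
  )
}

#' Interpolate short data-loss gaps
#'
#' Replaces invalid runs shorter than `max_gap_ms` by linear interpolation
#' between the flanking valid samples and marks them valid. Runs touching
#' either edge of the series have no flanking support and are left
#' untouched, as are runs of duration `>= max_gap_ms`. The input is not
#' modified; the operation is idempotent and never alters valid samples.
#'
#' @param series A [sample_series()].
#' @param max_gap_ms Gaps strictly shorter than this (ms) are repaired.
#' @return A new `sample_series`.
#' @export
interpolate_gaps <- function(series, max_gap_ms) {
  if (!is.finite(max_gap_ms) || max_gap_ms < 0) {
    stop("`max_gap_ms` must be >= 0", call. = FALSE)
  }
  runs <- find_invalid_runs(series)
  if (nrow(runs) == 0) return(series)
  n <- length(series$t)
  value <- series$value
  valid <- series$valid
  for (k in seq_len(nrow(runs))) {
    s <- runs$start[k]
    e <- runs$end[k] # one past last invalid
    if (runs$duration_ms[k] >= max_gap_ms) next
    if (s == 1L || e > n) next # edge-touching: no flank to interpolate from
    idx <- s:(e - 1L)
    value[idx] <- approx(
      x = series$t[c(s - 1L, e)], y = series$value[c(s - 1L, e)],
      xout = series$t[idx]
    )$y
    valid[idx] <- TRUE
  }
  series_replace(series, value = value, valid = valid)
}

# window length in samples for a Savitzky-Golay filter: round to the nearest
# sample count and force odd by incrementing
sg_window_samples <- function(window_ms, fs, order) {
  n <- as.integer(round(window_ms * fs / 1000))
  if (n %% 2L == 0L) n <- n + 1L
  if (n <= order) {
    stop(sprintf("filter window (%d samples) must exceed the polynomial order (%d)",
                 n, order), call. = FALSE)
  }
  n
}

# Apply a Savitzky-Golay coefficient matrix with validity-aware masking.
# m = 0 gives the smoothed value, m = 1 the first derivative per sample
# interval. Interior samples use the centered window; the first and last
# half-windows use the off-center rows of the coefficient matrix (i.e. the
# local polynomial fit of the first/last full window, evaluated off-center).
# Any output whose window overlaps an invalid (NA) sample is NA.
sg_apply <- function(x, n, order, m) {
  N <- length(x)
  if (N < n) stop("series shorter than the filter window", call. = FALSE)
  Fm <- signal::sgolay(p = order, n = n, m = m)
  h <- (n - 1L) %/% 2L
  out <- rep(NA_real_, N)
  # interior: windows x[(i-h):(i+h)]; embed() rows hold windows reversed
  cc <- rev(Fm[h + 1L, ])
  out[(h + 1L):(N - h)] <- as.vector(stats::embed(x, n) %*% cc)
  # edges: off-center fits of the first and last window
  head_ok <- !anyNA(x[1:n])
  tail_ok <- !anyNA(x[(N - n + 1L):N])
  if (head_ok) out[1:h] <- as.vector(Fm[1:h, , drop = FALSE] %*% x[1:n])
  if (tail_ok) {
    out[(N - h + 1L):N] <-
      as.vector(Fm[(h + 2L):n, , drop = FALSE] %*% x[(N - n + 1L):N])
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' Low-pass filters a series with a local least-squares polynomial fit: each
#' output sample is the polynomial of degree `order`, fitted to the window
#' centered on the sample, evaluated at the center. Samples whose window
#' overlaps invalid data become invalid. The window length is
#' `round(window_ms * fs / 1000)` samples, forced odd by incrementing.
#'
#' @param series A [sample_series()].
#' @param window_ms Filter window length in ms.
#' @param order Polynomial order (default 2).
#' @return A new `sample_series` with smoothed values.
#' @export
sg_smooth <- function(series, window_ms, order = 2L) {
  n <- sg_window_samples(window_ms, series$fs, order)
  out <- sg_apply(series$value, n, order, m = 0L)
  series_replace(series, value = out, valid = !is.na(out))
}

#' Savitzky-Golay velocity
#'
#' First derivative of a series via Savitzky-Golay differentiation: the
#' derivative of the local polynomial fit at the window center, scaled to
#' units per second. Applied to the unsmoothed signal; the fit itself
#' provides the noise suppression. Velocity is signed: eyelid closing is
#' negative, opening positive.
#'
#' @inheritParams sg_smooth
#' @return An object of class `velocity_series`: a list with `t`, `v`
#'   (mm/s), `valid` and `fs`, on the same time base as the input.
#' @export
sg_velocity <- function(series, window_ms, order = 2L) {
  n <- sg_window_samples(window_ms, series$fs, order)
  v <- sg_apply(series$value, n, order, m = 1L) * series$fs
  structure(
    list(t = series$t, v = v, valid = !is.na(v), fs = series$fs),
    class = "velocity_series"
  )
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("<velocity_series> %d samples @ %g Hz, %.2f%% invalid\n",
              length(x$t), x$fs, 100 * mean(!x$valid)))
  invisible(x)
}

#' Raw median absolute deviation
#'
#' `median(|x - median(x)|)` without any consistency scaling constant, the
#' robust dispersion estimate used for the adaptive velocity thresholds.
#' Non-finite values are dropped first.
#'
#' @param values Numeric vector.
#' @return A scalar.
#' @export
mad_raw <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) == 0) {
    stop("no finite values to compute the MAD from", call. = FALSE)
  }
  stats::mad(x, constant = 1)
}
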