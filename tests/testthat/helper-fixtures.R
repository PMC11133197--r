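# shared fixture builders (all data generated in code)

# sample_series on a regular time base
make_series <- function(value, fs = 600, valid = NULL, channel = "eo",
                        eye = "left") {
  n <- length(value)
  sample_series(t = (seq_len(n) - 1L) / fs, value = value, valid = valid,
                fs = fs, channel = channel, eye = eye)
}

# minimal blink-event table from onset/offset vectors
ev_table <- function(onsets, offsets, eye = "left", source = "eo") {
  stopifnot(length(onsets) == length(offsets))
  if (length(onsets) == 0) return(empty_blink_events())
  df <- data.frame(
    eye = eye, source = source, onset_t = onsets, offset_t = offsets,
    duration = offsets - onsets, clipped = FALSE,
    stringsAsFactors = FALSE
  )
  blinkeo:::as_blink_events(df)
}

# simulator ground truth as a blink-event table (for matching)
truth_to_events <- function(truth, eye = "left") {
  ev_table(truth$onset_t, truth$offset_t, eye = eye, source = "eo")
}

# noise-free trace with blinks at given onset times (s); returns the series
# and the per-blink onset/offset times actually sampled
make_blink_trace <- function(onsets_s, fs = 600, duration_s = NULL,
                             shape = blink_shape()) {
  wf <- blink_waveform(shape, fs)
  if (is.null(duration_s)) duration_s <- max(onsets_s) + length(wf) / fs + 0.5
  n <- as.integer(round(duration_s * fs))
  y <- rep(shape$baseline_before_mm, n)
  on_t <- off_t <- numeric(length(onsets_s))
  for (k in seq_along(onsets_s)) {
    i0 <- as.integer(round(onsets_s[k] * fs)) + 1L
    i1 <- i0 + length(wf) - 1L
    y[i0:i1] <- wf
    if (i1 < n) y[(i1 + 1L):n] <- shape$baseline_after_mm
    on_t[k] <- (i0 - 1L) / fs
    off_t[k] <- (i1 - 1L) / fs
  }
  list(series = make_series(y, fs = fs), onset_t = on_t, offset_t = off_t)
}

# independent per-window least-squares polynomial-fit oracle for the
# Savitzky-Golay operations: fits an order-2 polynomial to each window by
# solving the normal equations and evaluates value and derivative at the
# output sample (edge samples use the first/last full window, evaluated
# off-center)
sg_oracle <- function(x, window_n, fs) {
  N <- length(x)
  h <- (window_n - 1L) %/% 2L
  val <- der <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    lo <- min(max(1L, i - h), N - window_n + 1L)
    win <- lo:(lo + window_n - 1L)
    if (anyNA(x[win])) next
    tau <- win - i
    X <- cbind(1, tau, tau^2)
    b <- qr.solve(X, x[win])
    val[i] <- b[1]
    der[i] <- b[2] * fs
  }
  list(value = val, v = der)
}

# naive linear-scan oracle for candidate expansion on clean traces:
# walk from the trough, cross the sub-threshold closure bottom, then stop
# at the first sample below threshold after the fast phase
expand_oracle_side <- function(v, trough, T_vel, step) {
  i <- trough + step
  seen <- FALSE
  while (i >= 1 && i <= length(v)) {
    if (abs(v[i]) >= T_vel) seen <- TRUE
    else if (seen) return(i)
    i <- i + step
  }
  if (step < 0) 1L else length(v)
}
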