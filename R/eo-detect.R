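#' "Fully open" eyelid level
#'
#' The per-series reference eye openness against which relative blink
#' amplitudes are measured: the median over valid samples. Blinks occupy a
#' small minority of samples in a typical trial, so the median is a robust
#' estimate of the openness of the resting, fully open eyelids. Intended to
#' be computed on the gap-interpolated, unfiltered eye-openness series.
#'
#' @param eo A [sample_series()] with `channel == "eo"`.
#' @return The level in mm (scalar).
#' @export
fully_open_level <- function(eo) {
  x <- eo$value[eo$valid]
  if (length(x) == 0) stop("series has no valid samples", call. = FALSE)
  median(x)
}

# local minima of a smoothed eye-openness segment (indices into `y`),
# via sign changes of the first difference; flat extrema contribute the
# midpoint of the flat run
local_minima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  d <- diff(y)
  s <- sign(d)
  # carry the last non-zero sign across flat stretches
  nz <- s != 0
  if (!any(nz)) return(integer())
  s_f <- s
  idx <- cumsum(nz)
  s_f[idx > 0] <- s[nz][idx[idx > 0]]
  mins <- integer()
  for (i in which(s_f[-1] > 0 & s_f[-length(s_f)] < 0)) {
    # descending before position i+1, ascending after: minimum in between;
    # for a flat bottom take the midpoint of the flat run
    j <- i + 1L
    k <- j
    while (k > 1L && d[k - 1L] == 0) k <- k - 1L
    mins <- c(mins, as.integer(floor((k + j) / 2)))
  }
  mins
}

# topographic prominence of a local minimum within a segment: walk outward
# until the signal drops below the minimum (or the segment ends); the
# prominence is the minimum of the highest levels reached on the two sides,
# relative to the trough
trough_prominence <- function(y, i) {
  n <- length(y)
  left_top <- -Inf
  j <- i - 1L
  while (j >= 1L && y[j] >= y[i]) {
    if (y[j] > left_top) left_top <- y[j]
    j <- j - 1L
  }
  right_top <- -Inf
  j <- i + 1L
  while (j <= n && y[j] >= y[i]) {
    if (y[j] > right_top) right_top <- y[j]
    j <- j + 1L
  }
  # an edge-bounded side contributes the highest level seen up to the edge
  min(left_top, right_top) - y[i]
}

#' Find candidate blink closures
#'
#' Locates local minima of the smoothed eye-openness series whose
#' topographic prominence reaches the minimum blink amplitude
#' (`min_amplitude_frac * fully_open`) and which are separated by at least
#' the minimum blink duration. When two qualifying minima are closer than
#' the minimum separation, the deeper one is kept. These thresholds only
#' prune candidates early; final inclusion of a blink is decided by the
#' rejection rules on the unfiltered-signal kinematics.
#'
#' Invalid stretches of the smoothed series split it into segments; minima
#' are found per segment, so a closure bottom interrupted by unrepaired
#' data loss yields no candidate.
#'
#' @param eo_smoothed A smoothed [sample_series()] (see [sg_smooth()]).
#' @param settings A [detection_settings()] object.
#' @param fully_open Reference eyelid level in mm; defaults to the median of
#'   the valid smoothed samples, but the full detector passes the level of
#'   the unfiltered series.
#' @return Integer vector of trough indices, sorted ascending (possibly
#'   empty).
#' @export
find_closure_peaks <- function(eo_smoothed, settings,
                               fully_open = fully_open_level(eo_smoothed)) {
  prom_min <- settings$min_amplitude_frac * fully_open
  sep_min <- settings$min_duration_ms / 1000 * eo_smoothed$fs
  y <- eo_smoothed$value
  valid <- eo_smoothed$valid
  n <- length(y)
  cand <- integer()
  # segments of contiguous valid samples
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    seg <- y[starts[k]:ends[k]]
    mins <- local_minima(seg)
    for (i in mins) {
      if (trough_prominence(seg, i) >= prom_min) {
        cand <- c(cand, starts[k] + i - 1L)
      }
    }
  }
  if (length(cand) < 2) return(cand)
  # enforce minimum separation, deepest trough wins
  ord <- cand[order(y[cand])]
  kept <- integer()
  for (i in ord) {
    if (all(abs(kept - i) >= sep_min)) kept <- c(kept, i)
  }
  sort(kept)
}

# walk from the trough outward (step = -1 for onset, +1 for offset) until
# the speed |v| settles below T_vel behind the blink's fast phase.
#
# The closure bottom sits between the two fast phases, so the scan first
# crosses a sub-threshold stretch; it then traverses the supra-threshold
# run of the fast phase and stops at the first sample where |v| < T_vel
# again. To be robust against isolated noise excursions just above T_vel
# inside the closure bottom, a supra-threshold run only counts as the fast
# phase if it reaches 2 * T_vel; lesser runs are crossed. If the scan hits
# the series edge or an invalid velocity sample the boundary index is
# returned with clipped = TRUE; if that happens before any fast phase was
# seen, the trough itself is returned (the candidate collapses and is
# rejected later by the duration rule).
expand_side <- function(v, valid, trough_idx, T_vel, step) {
  major <- 2 * T_vel
  n <- length(v)
  i <- trough_idx + step
  in_run <- FALSE
  run_peak <- 0
  last_ok <- trough_idx
  while (i >= 1L && i <= n) {
    if (!valid[i]) {
      if (in_run && run_peak >= major) {
        return(list(idx = last_ok, clipped = TRUE))
      }
      return(list(idx = trough_idx, clipped = TRUE))
    }
    av <- abs(v[i])
    if (av >= T_vel) {
      in_run <- TRUE
      if (av > run_peak) run_peak <- av
    } else if (in_run) {
      if (run_peak >= major) return(list(idx = i, clipped = FALSE))
      in_run <- FALSE
      run_peak <- 0
    }
    last_ok <- i
    i <- i + step
  }
  # ran off the series edge
  if (in_run && run_peak >= major) {
    return(list(idx = last_ok, clipped = TRUE))
  }
  list(idx = trough_idx, clipped = TRUE)
}

#' Expand a closure candidate to onset and offset
#'
#' Starting from a candidate trough, scans backward and forward through the
#' velocity series until the eyelid speed settles below the velocity
#' threshold `T_vel` on the far side of the closing (respectively opening)
#' phase. The scan stops early -- and the candidate is flagged `clipped` --
#' at the series edges and at invalid velocity samples.
#'
#' @param v A `velocity_series` (see [sg_velocity()]).
#' @param trough_idx Sample index of the candidate's minimum openness.
#' @param T_vel Velocity threshold in mm/s (`> 0`); typically
#'   `onset_vel_mad_factor * mad_raw(v$v)`.
#' @return A list (class `blink_candidate`) with `onset_idx`, `trough_idx`,
#'   `offset_idx`, `T_vel` and `clipped`.
#' @export
expand_candidate <- function(v, trough_idx, T_vel) {
  if (!is.finite(T_vel) || T_vel <= 0) stop("`T_vel` must be > 0", call. = FALSE)
  if (trough_idx < 1L || trough_idx > length(v$v)) {
    stop("`trough_idx` out of range", call. = FALSE)
  }
  left <- expand_side(v$v, v$valid, trough_idx, T_vel, step = -1L)
  right <- expand_side(v$v, v$valid, trough_idx, T_vel, step = +1L)
  structure(
    list(onset_idx = left$idx, trough_idx = trough_idx,
         offset_idx = right$idx, T_vel = T_vel,
         clipped = left$clipped || right$clipped),
    class = "blink_candidate"
  )
}

#' Compute blink kinematics for a candidate
#'
#' Reads openness values and phase kinematics from the unfiltered
#' (gap-interpolated) eye-openness series and its velocity. The minimum
#' openness is located within the candidate interval on the unfiltered
#' series; the closing phase runs from onset to that minimum and the
#' opening phase from the minimum to offset. Peak speeds are the largest
#' `|v|` within each phase.
#'
#' @param eo The unfiltered (gap-interpolated) [sample_series()].
#' @param v The matching `velocity_series`.
#' @param cand A `blink_candidate` from [expand_candidate()].
#' @return A one-row `blink_events` table.
#' @export
extract_kinematics <- function(eo, v, cand) {
  on <- cand$onset_idx
  off <- cand$offset_idx
  idx <- on:off
  vals <- eo$value[idx]
  clipped <- isTRUE(cand$clipped)
  if (all(is.na(vals))) {
    trough <- cand$trough_idx
    clipped <- TRUE
  } else {
    trough <- idx[which.min(vals)]
  }
  phase_peak <- function(range_idx) {
    sp <- abs(v$v[range_idx])
    sp[!v$valid[range_idx]] <- NA
    if (all(is.na(sp))) return(list(vel = NA_real_, t = NA_real_))
    j <- which.max(sp)
    list(vel = sp[j], t = v$t[range_idx[j]])
  }
  closing <- phase_peak(on:trough)
  opening <- phase_peak(trough:off)
  if (is.na(closing$vel) || is.na(opening$vel)) clipped <- TRUE
  ev <- data.frame(
    eye = eo$eye, source = "eo",
    onset_t = eo$t[on], offset_t = eo$t[off],
    duration = eo$t[off] - eo$t[on],
    t_min_openness = eo$t[trough],
    eo_onset = eo$value[on], eo_offset = eo$value[off],
    eo_min = eo$value[trough],
    closing_amp = eo$value[on] - eo$value[trough],
    opening_amp = eo$value[off] - eo$value[trough],
    peak_closing_vel = closing$vel, t_peak_closing = closing$t,
    peak_opening_vel = opening$vel, t_peak_opening = opening$t,
    clipped = clipped,
    stringsAsFactors = FALSE
  )
  as_blink_events(ev)
}

#' Reject implausible blink candidates
#'
#' Keeps events that satisfy all three inclusion rules:
#' \itemize{
#'   \item amplitude: `max(closing_amp, opening_amp) >=
#'     min_amplitude_frac * fully_open` (the larger phase amplitude is
#'     tested so that a post-blink baseline shift does not reject a real
#'     blink);
#'   \item duration: `duration >= min_duration_ms`;
#'   \item peak velocity: `min(peak_closing_vel, peak_opening_vel) >=
#'     min_peak_vel_mad_factor * mad_v` (the lower of the two peaks must
#'     exceed the threshold).
#' }
#' Events with missing kinematics (fully clipped phases) fail the rules.
#'
#' @param events A `blink_events` table carrying kinematics.
#' @param settings A [detection_settings()] object.
#' @param fully_open Reference eyelid level in mm.
#' @param mad_v Raw MAD of the velocity series in mm/s.
#' @return The filtered `blink_events` table, order preserved.
#' @export
reject_candidates <- function(events, settings, fully_open, mad_v) {
  if (nrow(events) == 0) return(events)
  amp <- pmax(events$closing_amp, events$opening_amp)
  peak <- pmin(events$peak_closing_vel, events$peak_opening_vel)
  keep <- !is.na(amp) & amp >= settings$min_amplitude_frac * fully_open &
    events$duration >= settings$min_duration_ms / 1000 &
    !is.na(peak) & peak >= settings$min_peak_vel_mad_factor * mad_v
  as_blink_events(events[keep, , drop = FALSE])
}

#' Merge blinks that are close in time
#'
#' Repeatedly merges adjacent events whose separation
#' (`next onset - previous offset`) is less than `merge_ms`, replacing the
#' pair by a single event spanning both, with kinematics recomputed over
#' the union (the minimum openness is re-located within the merged span).
#' Iterates to a fixed point, so all output gaps are `>= merge_ms`.
#'
#' @param events A sorted, non-overlapping `blink_events` table from the
#'   eye-openness detector.
#' @param merge_ms Separation threshold in ms.
#' @param eo The unfiltered (gap-interpolated) [sample_series()] the events
#'   were detected in.
#' @param v The matching `velocity_series`.
#' @return A `blink_events` table.
#' @export
merge_events <- function(events, merge_ms, eo, v) {
  check_event_list(events, require_sorted = TRUE, require_disjoint = TRUE)
  if (nrow(events) < 2) return(events)
  repeat {
    gaps <- events$onset_t[-1] - events$offset_t[-nrow(events)]
    k <- which(gaps < merge_ms / 1000)
    if (length(k) == 0) break
    k <- k[1]
    on_idx <- which(eo$t == events$onset_t[k])
    off_idx <- which(eo$t == events$offset_t[k + 1])
    cand <- structure(
      list(onset_idx = on_idx, trough_idx = on_idx, offset_idx = off_idx,
           T_vel = NA_real_,
           clipped = events$clipped[k] || events$clipped[k + 1]),
      class = "blink_candidate"
    )
    merged <- extract_kinematics(eo, v, cand)
    events <- as_blink_events(rbind(
      events[seq_len(k - 1), , drop = FALSE],
      merged,
      events[seq(k + 2, length.out = nrow(events) - k - 1), , drop = FALSE]
    ))
  }
  events
}

#' Detect blinks in an eye-openness signal
#'
#' The full eye-openness blink classifier:
#' \enumerate{
#'   \item interpolate data-loss gaps shorter than `gap_fill_ms`;
#'   \item smooth the signal with a Savitzky-Golay filter (`filter_len_ms`,
#'     order 2) for closure-peak finding;
#'   \item compute eyelid velocity from the unsmoothed signal with a
#'     Savitzky-Golay differentiator of the same length;
#'   \item find prominent closure minima in the smoothed signal;
#'   \item expand each candidate backward/forward until the speed falls
#'     below `T_vel = onset_vel_mad_factor * MAD(v)`;
#'   \item read kinematics (openness at onset/offset/minimum, phase
#'     amplitudes, peak closing/opening speeds and their times) from the
#'     unfiltered signal;
#'   \item reject candidates that fail the amplitude, duration or
#'     peak-velocity rules;
#'   \item merge blinks separated by less than `merge_ms`.
#' }
#' Candidates whose expanded intervals overlap are collapsed to the deeper
#' trough before kinematics are computed. The result is deterministic for
#' fixed input and settings.
#'
#' @param x A [recording()] or an eye-openness [sample_series()].
#' @param eye `"left"` or `"right"`; used to pick the series when `x` is a
#'   recording.
#' @param settings A [detection_settings()] object.
#' @return A `blink_events` table, sorted by onset, `source = "eo"`.
#' @export
detect_eo_blinks <- function(x, eye = c("left", "right"),
                             settings = detection_settings()) {
  eye <- match.arg(eye)
  eo <- if (inherits(x, "recording")) get_series(x, "eo", eye) else x
  if (!inherits(eo, "sample_series") || eo$channel != "eo") {
    stop("`x` must be a recording or an eye-openness sample_series",
         call. = FALSE)
  }
  eo_i <- interpolate_gaps(eo, settings$gap_fill_ms)
  eo_s <- sg_smooth(eo_i, settings$filter_len_ms)
  v <- sg_velocity(eo_i, settings$filter_len_ms)
  fully_open <- fully_open_level(eo_i)
  mad_v <- mad_raw(v$v[v$valid])
  # essentially noise-free data can have MAD(v) ~ 0; a small floor relative
  # to the largest observed speed keeps the threshold meaningful
  T_vel <- max(settings$onset_vel_mad_factor * mad_v,
               0.01 * max(abs(v$v[v$valid]), 0))
  troughs <- find_closure_peaks(eo_s, settings, fully_open)
  if (length(troughs) == 0 || T_vel <= 0) return(empty_blink_events())
  cands <- lapply(troughs, function(i) expand_candidate(v, i, T_vel))
  # collapse candidates whose expansion windows overlap: deeper trough wins
  if (length(cands) > 1) {
    depth <- eo_s$value[troughs]
    kept <- list(cands[[1]])
    kept_depth <- depth[1]
    for (j in 2:length(cands)) {
      cur <- cands[[j]]
      prev <- kept[[length(kept)]]
      if (cur$onset_idx <= prev$offset_idx) {
        if (is.na(kept_depth[length(kept)]) ||
            (!is.na(depth[j]) && depth[j] < kept_depth[length(kept)])) {
          kept[[length(kept)]] <- cur
          kept_depth[length(kept)] <- depth[j]
        }
      } else {
        kept <- c(kept, list(cur))
        kept_depth <- c(kept_depth, depth[j])
      }
    }
    cands <- kept
  }
  events <- do.call(rbind, lapply(cands, function(cd) {
    extract_kinematics(eo_i, v, cd)
  }))
  events <- as_blink_events(events)
  events <- events[order(events$onset_t), , drop = FALSE]
  # candidates that collapsed to a point cannot form an interval
  events <- as_blink_events(
    events[events$offset_t > events$onset_t, , drop = FALSE]
  )
  events <- reject_candidates(events, settings, fully_open, mad_v)
  merge_events(events, settings$merge_ms, eo_i, v)
}
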