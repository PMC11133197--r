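test_that("fully_open_level is the median of valid samples", {
  expect_equal(fully_open_level(make_series(rep(9, 100))), 9)
  expect_equal(fully_open_level(make_series(rep(c(8, 9, 10), 30))), 9)
  expect_error(fully_open_level(make_series(rep(NA_real_, 5),
                                            valid = rep(FALSE, 5))),
               "no valid")
  # a long baseline with brief blinks keeps the median at the baseline
  tr <- make_blink_trace(c(1, 3, 5), duration_s = 60,
                         shape = blink_shape(baseline_after_mm = 8.75))
  expect_equal(fully_open_level(tr$series), 8.75, tolerance = 1e-6)
})

test_that("find_closure_peaks finds one trough per blink", {
  s <- detection_settings()
  flat <- sg_smooth(make_series(rep(9, 600)), 25)
  expect_length(find_closure_peaks(flat, s), 0)

  one <- make_blink_trace(0.5, duration_s = 2)
  sm <- sg_smooth(one$series, 25)
  pk <- find_closure_peaks(sm, s, fully_open = fully_open_level(one$series))
  expect_length(pk, 1)
  # at the global minimum of the noise-free trace (within the flat bottom)
  expect_equal(sm$value[pk], min(sm$value, na.rm = TRUE), tolerance = 1e-6)

  two <- make_blink_trace(c(0.5, 1.0), duration_s = 2.5)
  sm2 <- sg_smooth(two$series, 25)
  pk2 <- find_closure_peaks(sm2, s, fully_open = fully_open_level(two$series))
  expect_length(pk2, 2)
  expect_true(all(diff(pk2) > 0))
})

test_that("candidate expansion matches a linear-scan oracle on clean blinks", {
  tr <- make_blink_trace(0.5, duration_s = 2)
  v <- sg_velocity(tr$series, 25)
  # center of the closed plateau, as the peak finder would place it
  at_min <- which(tr$series$value == min(tr$series$value))
  trough <- as.integer(round(mean(at_min)))
  T_vel <- 10
  cand <- expand_candidate(v, trough, T_vel)
  expect_s3_class(cand, "blink_candidate")
  expect_equal(cand$onset_idx, expand_oracle_side(v$v, trough, T_vel, -1L))
  expect_equal(cand$offset_idx, expand_oracle_side(v$v, trough, T_vel, +1L))
  expect_true(cand$onset_idx <= cand$trough_idx)
  expect_true(cand$trough_idx <= cand$offset_idx)
  expect_false(cand$clipped)
})

test_that("candidate expansion clips at boundaries and collapses on flat velocity", {
  # trough at the first sample: nothing to scan through on the left
  tr <- make_blink_trace(0.5, duration_s = 2)
  v <- sg_velocity(tr$series, 25)
  cand <- expand_candidate(v, 1L, 10)
  expect_equal(cand$onset_idx, 1L)
  expect_true(cand$clipped)

  # velocity identically zero around the trough: candidate collapses to a
  # point (and would be removed later by the duration rule)
  vz <- v
  vz$v <- rep(0, length(vz$v))
  cz <- expand_candidate(vz, 600L, 10)
  expect_equal(cz$onset_idx, 600L)
  expect_equal(cz$offset_idx, 600L)

  expect_error(expand_candidate(v, 600L, -1), "T_vel")
})

test_that("kinematics are read from the unfiltered series", {
  # symmetric V-shaped blink: equal peak speeds, ordered phase times
  fs <- 600
  y <- c(rep(9, 200), 9 - (1:60) * 0.14, 9 - 0.14 * 60 + (1:60) * 0.14,
         rep(9, 200))
  s <- make_series(y, fs = fs)
  v <- sg_velocity(s, 25)
  trough <- which.min(y)
  cand <- expand_candidate(v, trough, 10)
  ev <- extract_kinematics(s, v, cand)
  expect_equal(ev$closing_amp, ev$eo_onset - ev$eo_min)
  expect_equal(ev$opening_amp, ev$eo_offset - ev$eo_min)
  expect_equal(ev$peak_closing_vel, ev$peak_opening_vel, tolerance = 1e-6)
  expect_true(ev$onset_t <= ev$t_peak_closing)
  expect_true(ev$t_peak_closing <= ev$t_min_openness)
  expect_true(ev$t_min_openness <= ev$t_peak_opening)
  expect_true(ev$t_peak_opening <= ev$offset_t)

  # asymmetric blink (fast closing, slow opening, equal amplitudes):
  # the faster phase has the larger peak speed
  sh <- blink_shape(closing_ms = 63, opening_ms = 138,
                    baseline_after_mm = 8.75)
  tr <- make_blink_trace(0.5, duration_s = 2, shape = sh)
  v2 <- sg_velocity(tr$series, 25)
  trough2 <- which.min(tr$series$value)
  ev2 <- extract_kinematics(tr$series, v2, expand_candidate(v2, trough2, 10))
  expect_gt(ev2$peak_closing_vel, ev2$peak_opening_vel)
})

test_that("rejection rules drop short, small and slow candidates", {
  s <- detection_settings()
  mad_v <- 4
  base <- data.frame(
    eye = "left", source = "eo",
    onset_t = 1, offset_t = 1.25, duration = 0.25, t_min_openness = 1.1,
    eo_onset = 9, eo_offset = 8.8, eo_min = 0.7,
    closing_amp = 8.3, opening_amp = 8.1,
    peak_closing_vel = 200, t_peak_closing = 1.05,
    peak_opening_vel = 90, t_peak_opening = 1.2, clipped = FALSE,
    stringsAsFactors = FALSE
  )
  ok <- blinkeo:::as_blink_events(base)
  expect_equal(nrow(reject_candidates(ok, s, 9, mad_v)), 1)

  short <- ok; short$duration <- 0.020
  expect_equal(nrow(reject_candidates(short, s, 9, mad_v)), 0)

  small <- ok; small$closing_amp <- 0.5; small$opening_amp <- 0.4
  expect_equal(nrow(reject_candidates(small, s, 9, mad_v)), 0)

  # the lower of the two peak speeds must exceed 2 * MAD(v)
  slow <- ok
  slow$peak_closing_vel <- 5 * mad_v
  slow$peak_opening_vel <- 1.5 * mad_v
  expect_equal(nrow(reject_candidates(slow, s, 9, mad_v)), 0)

  # amplitude rule uses the larger phase amplitude: a post-blink baseline
  # shift does not reject a real blink
  shifted <- ok; shifted$opening_amp <- 0.2
  expect_equal(nrow(reject_candidates(shifted, s, 9, mad_v)), 1)
})

test_that("merge_events joins close blinks iteratively", {
  fs <- 600
  tr <- make_blink_trace(c(0.5, 1.5, 2.5), duration_s = 4)
  eo <- tr$series
  v <- sg_velocity(eo, 25)
  mk <- function(i0, i1) {
    c(eo$t[as.integer(round(i0 * fs)) + 1L],
      eo$t[as.integer(round(i1 * fs)) + 1L])
  }
  # 50 ms gap -> merged
  a <- mk(0.5, 0.75); b <- mk(0.8, 1.0)
  ev <- ev_table(c(a[1], b[1]), c(a[2], b[2]))
  out <- merge_events(ev, 100, eo, v)
  expect_equal(nrow(out), 1)
  expect_equal(out$onset_t, a[1])
  expect_equal(out$offset_t, b[2])

  # 150 ms gap -> unchanged
  b2 <- mk(0.9, 1.1)
  ev2 <- ev_table(c(a[1], b2[1]), c(a[2], b2[2]))
  expect_equal(nrow(merge_events(ev2, 100, eo, v)), 2)

  # gaps of 80 and 90 ms collapse to one event at the fixed point
  e1 <- mk(0.5, 0.75); e2 <- mk(0.83, 1.0); e3 <- mk(1.09, 1.3)
  ev3 <- ev_table(c(e1[1], e2[1], e3[1]), c(e1[2], e2[2], e3[2]))
  out3 <- merge_events(ev3, 100, eo, v)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$onset_t, e1[1])
  expect_equal(out3$offset_t, e3[2])

  # overlapping input is rejected
  bad <- ev_table(c(0.5, 0.6), c(0.7, 0.9))
  expect_error(merge_events(bad, 100, eo, v), "overlap")
})

test_that("the full detector recovers every blink in a noise-free trial", {
  cfg <- sim_config(seed = 2, eo_noise_rms_mm = 0, ps_noise_rms_mm = 0,
                    jitter_ms = 0)
  sim <- simulate_recording(cfg)
  ev <- detect_eo_blinks(sim$recording, "left")
  expect_equal(nrow(ev), 60)
  m <- match_events(truth_to_events(sim$truth), ev)
  expect_equal(m$f1, 1.0)
  # determinism: identical input gives identical output
  ev2 <- detect_eo_blinks(sim$recording, "left")
  expect_identical(ev, ev2)
})

test_that("a blink-free noisy baseline yields no events", {
  sim <- simulate_recording(sim_config(seed = 4, blink_rate_hz = 0,
                                       duration_s = 30))
  ev <- detect_eo_blinks(sim$recording, "left")
  expect_equal(nrow(ev), 0)
})

test_that("detection is covariant under rescaling of the openness signal", {
  sim <- simulate_recording(sim_config(seed = 6, duration_s = 20))
  eo <- get_series(sim$recording, "eo", "left")
  ev <- detect_eo_blinks(eo)
  k <- 3.7
  eo_k <- sample_series(eo$t, eo$value * k, valid = eo$valid, fs = eo$fs,
                        channel = "eo", eye = "left")
  ev_k <- detect_eo_blinks(eo_k)
  expect_equal(ev_k$onset_t, ev$onset_t)
  expect_equal(ev_k$offset_t, ev$offset_t)
  expect_equal(ev_k$closing_amp, k * ev$closing_amp, tolerance = 1e-9)
})

test_that("emitted events satisfy the event invariants and separation", {
  s <- detection_settings()
  for (seed in c(21, 22)) {
    sim <- simulate_recording(sim_config(seed = seed, duration_s = 30))
    ev <- detect_eo_blinks(sim$recording, "left", s)
    expect_gt(nrow(ev), 0)
    expect_true(all(ev$onset_t < ev$offset_t))
    expect_equal(ev$duration, ev$offset_t - ev$onset_t)
    expect_true(all(ev$onset_t <= ev$t_peak_closing))
    expect_true(all(ev$t_peak_closing <= ev$t_min_openness))
    expect_true(all(ev$t_min_openness <= ev$t_peak_opening))
    expect_true(all(ev$t_peak_opening <= ev$offset_t))
    expect_true(all(ev$eo_min <= pmin(ev$eo_onset, ev$eo_offset)))
    expect_true(all(ev$closing_amp >= 0))
    expect_true(all(ev$opening_amp >= 0))
    if (nrow(ev) > 1) {
      expect_true(all(ev$onset_t[-1] - ev$offset_t[-nrow(ev)] >= 0.1))
    }
    # every emitted event passes the inclusion rules it was filtered by
    fo <- fully_open_level(interpolate_gaps(
      get_series(sim$recording, "eo", "left"), s$gap_fill_ms))
    expect_true(all(pmax(ev$closing_amp, ev$opening_amp) >=
                      s$min_amplitude_frac * fo))
    expect_true(all(ev$duration >= s$min_duration_ms / 1000))
  }
})
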