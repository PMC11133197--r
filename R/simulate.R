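#' Blink waveform shape
#'
#' Parameters of the synthetic eyelid trajectory of one blink: a
#' half-cosine descent from the pre-blink baseline to the minimum openness,
#' a closed plateau, and a half-cosine ascent to the post-blink baseline.
#' The half-cosine phases are C1-smooth at both ends and reproduce the
#' characteristic asymmetry of real blinks -- fast closing, slower
#' re-opening -- whose default phase durations (63 ms closing, 138 ms
#' opening, about 50 ms closed) and openness levels (8.75 mm before,
#' 8.16 mm after, 0.73 mm at minimum) follow typical values for prompted
#' blinks in adults. The waveform is a parameter-sparse stand-in, not a
#' physiological eyelid model.
#'
#' @param closing_ms,opening_ms,plateau_ms Phase durations in ms.
#' @param min_openness_mm Minimum eye openness during the blink (mm).
#' @param baseline_before_mm,baseline_after_mm Eye openness at blink onset
#'   and after completion (mm); the post-blink baseline may differ from the
#'   pre-blink one (eyelids often re-open slightly less).
#' @return An object of class `blink_shape`.
#' @export
blink_shape <- function(closing_ms = 63, opening_ms = 138, plateau_ms = 50,
                        min_openness_mm = 0.73,
                        baseline_before_mm = 8.75, baseline_after_mm = 8.16) {
  if (closing_ms <= 0 || opening_ms <= 0 || plateau_ms < 0) {
    stop("phase durations must be positive (plateau may be 0)", call. = FALSE)
  }
  if (min_openness_mm < 0 || min_openness_mm >= baseline_before_mm ||
      min_openness_mm >= baseline_after_mm) {
    stop("`min_openness_mm` must be >= 0 and below both baselines",
         call. = FALSE)
  }
  structure(
    list(closing_ms = closing_ms, opening_ms = opening_ms,
         plateau_ms = plateau_ms, min_openness_mm = min_openness_mm,
         baseline_before_mm = baseline_before_mm,
         baseline_after_mm = baseline_after_mm),
    class = "blink_shape"
  )
}

#' Sample one blink waveform
#'
#' Evaluates the eyelid trajectory of [blink_shape()] at sampling rate
#' `fs`: baseline_before, half-cosine descent, plateau at the minimum,
#' half-cosine ascent, baseline_after. The first sample is exactly the
#' pre-blink baseline and the last exactly the post-blink baseline.
#'
#' @param shape A [blink_shape()].
#' @param fs Sampling frequency in Hz.
#' @return Numeric vector of openness values in mm.
#' @export
blink_waveform <- function(shape, fs) {
  total_s <- (shape$closing_ms + shape$plateau_ms + shape$opening_ms) / 1000
  n <- as.integer(round(total_s * fs)) + 1L
  tt <- (seq_len(n) - 1L) / fs
  t1 <- shape$closing_ms / 1000
  t2 <- t1 + shape$plateau_ms / 1000
  t3 <- total_s
  y <- numeric(n)
  a_close <- shape$baseline_before_mm - shape$min_openness_mm
  a_open <- shape$baseline_after_mm - shape$min_openness_mm
  closing <- tt < t1
  plateau <- tt >= t1 & tt < t2
  opening <- tt >= t2
  y[closing] <- shape$min_openness_mm +
    a_close * (1 + cos(pi * tt[closing] / t1)) / 2
  y[plateau] <- shape$min_openness_mm
  y[opening] <- shape$min_openness_mm +
    a_open * (1 - cos(pi * (tt[opening] - t2) / (t3 - t2))) / 2
  y[n] <- shape$baseline_after_mm # exact endpoint regardless of rounding
  y
}

#' Simulation configuration
#'
#' Study conditions for a synthetic binocular recording: a 60 s trial at
#' 600 Hz with blinks prompted at 1 Hz, additive Gaussian noise whose
#' sample-to-sample RMS matches typical tracker precision (0.200 mm for
#' eye openness, 0.004 mm for pupil size), and pupil-size data loss driven
#' by eyelid occlusion (the pupil is unmeasurable while the aperture
#' between the eyelids is smaller than the pupil itself).
#'
#' @param fs Sampling frequency in Hz.
#' @param duration_s Trial duration in seconds.
#' @param blink_rate_hz Prompted blink rate (blinks per second).
#' @param jitter_ms Each blink onset is shifted by a uniform jitter in
#'   `[-jitter_ms, +jitter_ms]`, emulating variable prompt-following.
#' @param shape A [blink_shape()].
#' @param eo_noise_rms_mm,ps_noise_rms_mm Target RMS-S2S noise magnitudes;
#'   the per-sample noise SD is `rms / sqrt(2)` so that the measured
#'   RMS-S2S of a blink-free stretch matches the target in expectation.
#' @param pupil_diameter_mm Simulated pupil diameter.
#' @param occlusion_threshold Eye-openness level (mm) below which the pupil
#'   is unmeasurable; defaults to the pupil diameter (a sphere between the
#'   eyelids smaller than the pupil implies partial occlusion).
#' @param extra_ps_loss_frac,extra_eo_loss_frac Additional random data loss
#'   (fractions in `[0, 1)`) injected into the channels, emulating tracking
#'   difficulty unrelated to blinks.
#' @param seed Integer seed; the same seed reproduces the recording
#'   bit-identically.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs = 600, duration_s = 60, blink_rate_hz = 1.0,
                       jitter_ms = 50, shape = blink_shape(),
                       eo_noise_rms_mm = 0.200, ps_noise_rms_mm = 0.004,
                       pupil_diameter_mm = 4.0,
                       occlusion_threshold = pupil_diameter_mm,
                       extra_ps_loss_frac = 0, extra_eo_loss_frac = 0,
                       seed = 1L) {
  if (fs <= 0 || duration_s <= 0) stop("fs and duration must be > 0", call. = FALSE)
  if (blink_rate_hz < 0 || blink_rate_hz > 1) {
    stop("`blink_rate_hz` must lie in [0, 1]", call. = FALSE)
  }
  if (jitter_ms < 0) stop("`jitter_ms` must be >= 0", call. = FALSE)
  if (extra_ps_loss_frac < 0 || extra_ps_loss_frac >= 1 ||
      extra_eo_loss_frac < 0 || extra_eo_loss_frac >= 1) {
    stop("extra loss fractions must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(fs = fs, duration_s = duration_s, blink_rate_hz = blink_rate_hz,
         jitter_ms = jitter_ms, shape = shape,
         eo_noise_rms_mm = eo_noise_rms_mm, ps_noise_rms_mm = ps_noise_rms_mm,
         pupil_diameter_mm = pupil_diameter_mm,
         occlusion_threshold = occlusion_threshold,
         extra_ps_loss_frac = extra_ps_loss_frac,
         extra_eo_loss_frac = extra_eo_loss_frac,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# run a block of code with a locally seeded RNG, restoring caller state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a binocular recording with ground truth
#'
#' Generates eye-openness and pupil-size series for both eyes on a shared
#' time base. Blinks are placed at `1/blink_rate_hz` intervals with uniform
#' onset jitter; between a blink's end and the next blink's start the
#' baseline ramps slowly back to the pre-blink level. Gaussian noise is
#' added per channel and eye (independent draws). The pupil is valid only
#' where the noise-free eye openness is at or above the occlusion
#' threshold, so pupil-size data loss is concentrated inside true blinks;
#' optional extra loss is injected as random runs. The ground truth lists
#' every true blink with its onset, offset (where the waveform departs from
#' and returns to baseline), time of minimum openness and phase amplitudes.
#'
#' @param config A [sim_config()].
#' @return A list with elements `recording` (a [recording()]) and `truth`
#'   (a data frame with `onset_t`, `offset_t`, `t_min_openness`,
#'   `closing_amp`, `opening_amp`).
#' @export
simulate_recording <- function(config = sim_config()) {
  fs <- config$fs
  n <- as.integer(round(config$fs * config$duration_s))
  t <- (seq_len(n) - 1L) / fs
  shape <- config$shape
  wf <- blink_waveform(shape, fs)
  wf_len <- length(wf)
  n_blinks <- if (config$blink_rate_hz > 0) {
    as.integer(floor(config$duration_s * config$blink_rate_hz))
  } else 0L
  period <- if (n_blinks > 0) 1 / config$blink_rate_hz else Inf
  footprint_s <- (wf_len - 1L) / fs
  jitter_s <- config$jitter_ms / 1000
  # blinks are anchored a quarter period into each interval, so the jitter
  # must stay within that margin and the waveform within the remainder
  if (n_blinks > 0 &&
      (jitter_s > 0.25 * period ||
       footprint_s + jitter_s >= 0.75 * period)) {
    stop("blink footprint exceeds the inter-blink interval", call. = FALSE)
  }
  with_local_seed(config$seed, {
    # --- noise-free eyelid trajectory + truth ---------------------------
    eo_clean <- rep(shape$baseline_before_mm, n)
    truth <- data.frame(onset_t = numeric(), offset_t = numeric(),
                        t_min_openness = numeric(),
                        closing_amp = numeric(), opening_amp = numeric())
    if (n_blinks > 0) {
      jit <- runif(n_blinks, -config$jitter_ms, config$jitter_ms) / 1000
      onsets_s <- (seq_len(n_blinks) - 1L) * period + 0.25 * period + jit
      onset_idx <- as.integer(round(onsets_s * fs)) + 1L
      prev_end <- 1L
      for (k in seq_len(n_blinks)) {
        i0 <- onset_idx[k]
        i1 <- i0 + wf_len - 1L
        eo_clean[i0:i1] <- wf
        # slow ramp from the previous post-blink level back to baseline
        if (k > 1) {
          ramp <- prev_end:i0
          eo_clean[ramp] <- seq(shape$baseline_after_mm,
                                shape$baseline_before_mm,
                                length.out = length(ramp))
        }
        if (i1 < n) eo_clean[(i1 + 1L):n] <- shape$baseline_after_mm
        prev_end <- i1
        t_min <- t[i0] + (shape$closing_ms + shape$plateau_ms / 2) / 1000
        truth <- rbind(truth, data.frame(
          onset_t = t[i0], offset_t = t[i1], t_min_openness = t_min,
          closing_amp = shape$baseline_before_mm - shape$min_openness_mm,
          opening_amp = shape$baseline_after_mm - shape$min_openness_mm
        ))
      }
    }
    # --- channels (independent noise per eye) ---------------------------
    eo_sd <- config$eo_noise_rms_mm / sqrt(2)
    ps_sd <- config$ps_noise_rms_mm / sqrt(2)
    ps_valid <- eo_clean >= config$occlusion_threshold
    make_eye <- function(eye, loss_seed_offset) {
      eo_val <- eo_clean + rnorm(n, 0, eo_sd)
      eo <- sample_series(t, eo_val, valid = rep(TRUE, n), fs = fs,
                          channel = "eo", eye = eye)
      ps_val <- config$pupil_diameter_mm + rnorm(n, 0, ps_sd)
      ps <- sample_series(t, ps_val, valid = ps_valid, fs = fs,
                          channel = "ps", eye = eye)
      if (config$extra_eo_loss_frac > 0) {
        eo <- inject_data_loss(eo, config$extra_eo_loss_frac,
                               seed = config$seed * 8L + loss_seed_offset)
      }
      if (config$extra_ps_loss_frac > 0) {
        ps <- inject_data_loss(ps, config$extra_ps_loss_frac,
                               seed = config$seed * 8L + loss_seed_offset + 1L)
      }
      list(eo = eo, ps = ps)
    }
    left <- make_eye("left", 0L)
    right <- make_eye("right", 2L)
    rec <- recording(
      list(eo_left = left$eo, eo_right = right$eo,
           ps_left = left$ps, ps_right = right$ps),
      participant = "sim", condition = sprintf("seed%d", config$seed)
    )
    list(recording = rec, truth = truth)
  })
}

#' Inject random data loss into a series
#'
#' Invalidates runs of samples -- run lengths geometrically distributed
#' with the given mean, run starts uniform -- until the overall invalid
#' fraction of the series reaches `frac`. Never re-validates a sample;
#' deterministic for a fixed seed.
#'
#' @param series A [sample_series()].
#' @param frac Target invalid fraction in `[0, 1)`.
#' @param mean_run_ms Mean run length in ms. Default 100.
#' @param seed Integer seed.
#' @return A new `sample_series`.
#' @export
inject_data_loss <- function(series, frac, mean_run_ms = 100, seed = 1L) {
  if (!is.finite(frac) || frac < 0 || frac >= 1) {
    stop("`frac` must lie in [0, 1)", call. = FALSE)
  }
  if (frac == 0) return(series)
  n <- length(series$t)
  mean_run_n <- max(1, mean_run_ms / 1000 * series$fs)
  with_local_seed(seed, {
    valid <- series$valid
    while (sum(!valid) / n < frac) {
      start <- sample.int(n, 1L)
      len <- rgeom(1L, 1 / mean_run_n) + 1L
      valid[start:min(n, start + len - 1L)] <- FALSE
    }
    series_replace(series, valid = valid)
  })
}
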