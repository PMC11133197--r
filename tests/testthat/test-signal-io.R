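test_that("read_recording parses values, validity and time units", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ts,eo,eo_ok",
    "0,9.0,1",
    "1667,8.9,1",
    "3333,-1,1",
    "5000,8.8,0"
  ), f)
  cmap <- list(time = "ts", time_unit = "us",
               eo_left = c(value = "eo", valid = "eo_ok"))
  rec <- read_recording(f, cmap, fs = 600)
  s <- get_series(rec, "eo", "left")
  expect_equal(s$t, c(0, 1667, 3333, 5000) * 1e-6)
  expect_equal(s$value[1:2], c(9.0, 8.9))
  # negative value and zero validity flag both yield invalid + sentinel
  expect_equal(s$valid, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(s$value[3:4])))
})

test_that("read_recording rejects duplicated timestamps and missing columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,eo,ok", "0,9,1", "0,8.9,1"), f)
  cmap <- list(time = "t", eo_left = c(value = "eo", valid = "ok"))
  expect_error(read_recording(f, cmap, fs = 600), "strictly increasing")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,eo,ok", "0,9,1", "0.01,8.9,1"), f2)
  cmap2 <- list(time = "t", eo_left = c(value = "nope", valid = "ok"))
  expect_error(read_recording(f2, cmap2, fs = 100), "nope")
})

test_that("read_recording warns when the sample interval contradicts fs", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,eo,ok", "0,9,1", "0.5,9,1", "1.0,9,1"), f)
  cmap <- list(time = "t", eo_left = c(value = "eo", valid = "ok"))
  expect_warning(rec <- read_recording(f, cmap, fs = 600), "deviates")
  expect_true(length(rec$meta$notes) > 0)
})

test_that("read_recording never fabricates valid samples", {
  set.seed(42)
  n <- 200
  f <- withr::local_tempfile(fileext = ".csv")
  val <- round(rnorm(n, 8, 3), 3) # some negative
  flag <- sample(0:1, n, replace = TRUE)
  txt <- sprintf("%g,%s,%d", (0:(n - 1)) / 600, val, flag)
  writeLines(c("t,eo,ok", txt), f)
  cmap <- list(time = "t", eo_left = c(value = "eo", valid = "ok"))
  rec <- read_recording(f, cmap, fs = 600)
  s <- get_series(rec, "eo", "left")
  expect_equal(sum(s$valid), sum(flag == 1 & is.finite(val) & val > 0))
})

test_that("event tables round-trip through TSV losslessly", {
  sim <- simulate_recording(sim_config(duration_s = 6, seed = 3))
  eo <- detect_eo_blinks(sim$recording, "left")
  ps <- detect_ps_blinks(get_series(sim$recording, "ps", "left"))
  both <- blinkeo:::as_blink_events(rbind(eo, ps))
  both <- both[order(both$onset_t), , drop = FALSE]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events(both, f)
  back <- read_events(f)
  expect_identical(names(back), blinkeo:::EVENT_COLS)
  num <- setdiff(blinkeo:::EVENT_COLS, c("eye", "source", "clipped"))
  for (nm in num) {
    expect_equal(back[[nm]], both[[nm]], tolerance = 1e-9)
  }
  expect_identical(back$eye, both$eye)
  expect_identical(back$source, both$source)
  expect_identical(back$clipped, both$clipped)
  # pupil-size rows leave kinematic cells empty
  lines <- readLines(f)
  ps_line <- lines[grep("\tps\t", lines)[1]]
  expect_match(ps_line, "\t\t")
})

test_that("write_events refuses unsorted input", {
  ev <- ev_table(c(1, 0.2), c(1.5, 0.4))
  expect_error(write_events(ev, tempfile()), "sorted")
})

test_that("settings JSON round-trips and unknown keys error", {
  s <- detection_settings(min_amplitude_frac = 0.2, ps_min_diameter_mm = 2,
                          ps_max_diameter_mm = 7)
  f <- withr::local_tempfile(fileext = ".json")
  write_settings(s, f)
  s2 <- read_settings(f)
  expect_equal(unclass(s2), unclass(s))

  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"gap_fill_ms": 40, "bogus_key": 1}', f2)
  expect_error(read_settings(f2), "bogus_key")
})

test_that("recordings written by the package can be read back", {
  sim <- simulate_recording(sim_config(duration_s = 4, seed = 9))
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(sim$recording, f)
  cmap <- blinkeo:::default_column_map(names(sim$recording$series))
  rec <- read_recording(f, cmap, fs = 600)
  for (key in names(sim$recording$series)) {
    a <- sim$recording$series[[key]]
    b <- rec$series[[key]]
    expect_equal(b$valid, a$valid)
    expect_equal(b$value, a$value, tolerance = 1e-9)
  }
})

test_that("series and recording invariants are enforced", {
  expect_error(sample_series(c(0, 0.1), c(9, 8), fs = -1,
                             channel = "eo", eye = "left"),
               "fs")
  expect_error(sample_series(c(0, 0.1, 0.1), c(1, 2, 3), fs = 10,
                             channel = "eo", eye = "left"),
               "strictly increasing")
  s1 <- make_series(rep(9, 10))
  s2 <- make_series(rep(4, 11), channel = "ps")
  expect_error(recording(list(eo_left = s1, ps_left = s2)), "identical")
  expect_error(recording(list()), "non-empty")
})
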