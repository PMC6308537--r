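test_that("pulse_record validates its invariants", {
  expect_s3_class(pulse_record(1:10, fs = 100), "pulse_record")
  expect_error(pulse_record(numeric(0), fs = 100), "non-empty")
  expect_error(pulse_record(1:10, fs = 0), "positive")
  expect_error(pulse_record(1:10, fs = 100, ecg = 1:5), "same number")
  expect_error(pulse_record(c(1, NA, 3), fs = 100), "non-finite")
  expect_error(pulse_record(1:10, fs = 100, ref_sbp = 80, ref_dbp = 120),
               "exceed")
})

test_that("record I/O round-trips samples bit-exactly and metadata field-for-field", {
  g <- fixture_record(fs = 250, duration = 5)
  rec <- g$record
  rec$subject_id <- "S01"
  rec$session_time <- "day00_09.00h"
  dir <- withr::local_tempdir()
  sig <- file.path(dir, "rec0001.csv"); sc <- file.path(dir, "rec0001.json")
  write_record(rec, sig, sc)
  back <- read_record(sig, sc)
  expect_identical(back$ppw, rec$ppw)
  expect_identical(back$ecg, rec$ecg)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$subject_id, rec$subject_id)
  expect_identical(back$session_time, rec$session_time)
  expect_equal(back$ref_sbp, rec$ref_sbp)
  expect_equal(back$ref_dbp, rec$ref_dbp)
})

test_that("read_record rejects bad metadata and inconsistent time columns", {
  dir <- withr::local_tempdir()
  sig <- file.path(dir, "x.csv"); sc <- file.path(dir, "x.json")
  writeLines(c("ppw", "1", "2", "3"), sig)
  jsonlite::write_json(list(subject_id = "a"), sc, auto_unbox = TRUE)
  expect_error(read_record(sig, sc), "fs")
  jsonlite::write_json(list(fs = 0), sc, auto_unbox = TRUE)
  expect_error(read_record(sig, sc), "fs")
  jsonlite::write_json(list(fs = 100), sc, auto_unbox = TRUE)
  writeLines(c("time,ppw", "0,1", "0.02,2", "0.04,3"), sig)  # spacing for 50 Hz
  expect_error(read_record(sig, sc), "time")
  # ppw-only file is fine, ECG absent
  writeLines(c("ppw", "1", "2", "3"), sig)
  expect_null(read_record(sig, sc)$ecg)
})

test_that("low-pass filter preserves passband and kills stopband", {
  fs <- 2500
  t <- (0:(4 * fs - 1)) / fs
  expect_lt(max(abs(lowpass_filter(rep(3, fs), fs) - 3)), 1e-5)
  y5 <- lowpass_filter(sin(2 * pi * 5 * t), fs)
  expect_gt(fft_amp(y5, fs, 5), 0.99)
  y200 <- lowpass_filter(sin(2 * pi * 200 * t), fs)
  expect_lt(fft_amp(y200, fs, 200), 0.10)
  expect_error(lowpass_filter(1:10, fs = 90, cutoff_hz = 50), "cutoff")
})

test_that("preprocessing is idempotent within tolerance", {
  fs <- 2500
  g <- fixture_record(fs = fs, duration = 30, drift = 0.4, snr = 20)
  f1 <- lowpass_filter(g$record$ppw, fs)
  b1 <- remove_baseline(f1, fs)
  # baseline removal alone
  b2 <- remove_baseline(b1, fs)
  expect_lt(sqrt(mean((b2 - b1)^2)), 0.01 * sqrt(mean((b1 - f1)^2)))
  # the full chain: running it a second time changes under 1% of what the
  # first run changed
  p2 <- remove_baseline(lowpass_filter(b1, fs), fs)
  expect_lt(sqrt(mean((p2 - b1)^2)),
            0.01 * sqrt(mean((b1 - g$record$ppw)^2)))
})

test_that("baseline removal strips 0.2 Hz drift and zero-centres the record", {
  fs <- 500
  g <- fixture_record(fs = fs, duration = 60, seed = 3, hr_jitter = 0)
  filt <- lowpass_filter(g$record$ppw, fs)
  t <- (seq_along(filt) - 1) / fs
  drift <- 0.5 * sin(2 * pi * 0.2 * t + 1)
  before <- band_power(filt + drift, fs, 0, 0.3)
  after <- band_power(remove_baseline(filt + drift, fs), fs, 0, 0.3)
  expect_lt(after / before, 0.05)  # >= 95% of drift energy removed
  out <- remove_baseline(filt, fs)
  expect_lt(abs(mean(out)) / diff(range(out)), 0.01)
  expect_equal(remove_baseline(rep(0, 20 * fs), fs), rep(0, 20 * fs))
  expect_error(remove_baseline(1:8, fs), "short")
})

test_that("baseline removal leaves pulse morphology essentially untouched", {
  fs <- 500
  g <- fixture_record(fs = fs, duration = 60, seed = 3, hr_jitter = 0)
  filt <- lowpass_filter(g$record$ppw, fs)
  out <- remove_baseline(filt, fs)
  t <- (seq_along(filt) - 1) / fs
  idx <- findInterval(t, g$truth$feet)
  # interior complete beats (the record is cut mid-beat at both ends, so the
  # baseline estimate at the very boundary is inherently less certain)
  interior <- as.character(seq(2L, length(g$truth$feet) - 2L))
  p2p_a <- vapply(split(filt, idx)[interior], function(z) diff(range(z)), 1)
  p2p_b <- vapply(split(out, idx)[interior], function(z) diff(range(z)), 1)
  expect_lt(max(abs(p2p_b - p2p_a) / p2p_a), 0.02)
})

test_that("derivatives match closed forms", {
  fs <- 1000
  t <- (0:(2 * fs - 1)) / fs
  ramp <- 3.5 * t
  d <- derivatives(ramp, fs)
  i <- 50:(length(t) - 50)
  expect_equal(d$d1[i], rep(3.5, length(i)), tolerance = 1e-8)
  expect_equal(d$d2[i], rep(0, length(i)), tolerance = 1e-6)
  s <- sin(2 * pi * t)
  ds <- derivatives(s, fs)
  expect_lt(max(abs(ds$d1[i] - 2 * pi * cos(2 * pi * t[i]))), 0.01 * 2 * pi)
  dc <- derivatives(rep(2, 100), fs)
  expect_equal(dc$d1, rep(0, 100))
  expect_equal(dc$d2, rep(0, 100))
  expect_error(derivatives(1:4, fs), "short")
})

test_that("beat segmentation recovers the generated beat train", {
  fs <- 500
  g <- generate_record(120, 80, fs = fs, duration = 60, noise_snr_db = Inf,
                       drift_amp = 0, hr = 60, hr_jitter = 0.02, seed = 9)
  beats <- segment_beats(preprocess_record(g$record))
  expect_gte(length(beats), 58)
  expect_lte(length(beats), 60)
  # boundaries within +-20 ms of generator feet
  starts <- vapply(beats, function(b) (b$start - 1) / fs, 1)
  errs <- vapply(starts, function(s) min(abs(g$truth$feet - s)), 1)
  expect_lt(max(errs), 0.020)
  # flat signal: no beats, a warning, not an error
  flat <- pulse_record(rep(1, 10 * fs), fs = fs)
  expect_warning(b0 <- segment_beats(preprocess_record(flat)), "no beats")
  expect_length(b0, 0L)
})

test_that("corrupted beats are dropped by the duration/peak-count gates", {
  fs <- 500
  g <- generate_record(120, 80, fs = fs, duration = 30, noise_snr_db = Inf,
                       drift_amp = 0, seed = 4, hr_jitter = 0)
  rec <- g$record
  # inject a burst artifact in the middle of one beat
  mid <- round(length(rec$ppw) / 2)
  rec$ppw[mid:(mid + fs %/% 2)] <- rec$ppw[mid:(mid + fs %/% 2)] +
    2 * sin(2 * pi * 8 * seq(0, 0.5, length.out = fs %/% 2 + 1))
  beats <- segment_beats(preprocess_record(rec))
  expect_gt(attr(beats, "n_dropped"), 0)
  # every kept beat still has exactly one prominent peak and a sane duration
  durs <- vapply(beats, function(b) (b$end - b$start) / fs, 1)
  expect_true(all(durs >= 0.3 & durs <= 2))
})

test_that("R-peak detection recovers the generated R train", {
  fs <- 500
  g <- generate_record(120, 80, fs = fs, duration = 60, noise_snr_db = 30,
                       drift_amp = 0, hr = 75, seed = 21)
  r <- detect_r_peaks(g$record$ecg, fs)
  expect_true(all(diff(r) > 0))
  expect_gte(length(r), length(g$truth$r_times) - 1)
  expect_lte(length(r), length(g$truth$r_times) + 1)
  errs <- vapply((r - 1) / fs, function(s) min(abs(g$truth$r_times - s)), 1)
  expect_lt(max(errs), 0.010)
  expect_identical(detect_r_peaks(rep(0, 1000), fs), integer(0))
})
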