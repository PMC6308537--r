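# Shared fixtures built in code: small records and beats for unit tests.

fixture_record <- function(fs = 500, duration = 20, sbp = 120, dbp = 80,
                           snr = Inf, drift = 0, seed = 42, ...) {
  generate_record(sbp, dbp, fs = fs, duration = duration,
                  noise_snr_db = snr, drift_amp = drift, seed = seed, ...)
}

# one clean detected beat plus its fiducials
fixture_beat <- function(fs = 2500, sbp = 120, dbp = 80, seed = 5) {
  g <- generate_record(sbp, dbp, fs = fs, duration = 8, noise_snr_db = Inf,
                       drift_amp = 0, seed = seed, hr_jitter = 0,
                       with_ecg = FALSE)
  rec <- preprocess_record(g$record)
  beats <- segment_beats(rec)
  list(beat = beats[[3]], truth = g$truth, record = rec)
}

# FFT amplitude of a signal at a single frequency
fft_amp <- function(x, fs, f0) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  i <- which.min(abs(freqs - f0))
  2 * Mod(stats::fft(x)[i]) / n
}

band_power <- function(x, fs, lo, hi) {
  x <- x - mean(x)
  s <- stats::fft(x)
  f <- (seq_along(x) - 1) * fs / length(x)
  sum(Mod(s[f >= lo & f <= hi])^2)
}
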