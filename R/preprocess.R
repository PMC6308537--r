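#' Zero-phase low-pass filter
#'
#' Removes high-frequency interference with a 4th-order Butterworth low-pass
#' applied forward and backward (`signal::filtfilt`), so fiducial timing is
#' not distorted by filter phase. Default cutoff 50 Hz.
#'
#' @param samples Numeric signal vector.
#' @param fs Sampling rate in Hz; must exceed `2 * cutoff_hz`.
#' @param cutoff_hz Cutoff frequency in Hz (default 50).
#' @return Filtered signal, same length as input.
#' @export
lowpass_filter <- function(samples, fs, cutoff_hz = 50) {
  if (fs <= 2 * cutoff_hz) {
    stop("'fs' must exceed twice the cutoff frequency", call. = FALSE)
  }
  samples <- as.numeric(samples)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  # odd-mirror padding so the forward-backward pass settles outside the data
  n <- length(samples)
  pad <- min(n - 1L, max(8L, as.integer(ceiling(12 * fs / cutoff_hz))))
  ext <- c(2 * samples[1] - samples[(pad + 1L):2],
           samples,
           2 * samples[n] - samples[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, ext))
  y[(pad + 1L):(pad + n)]
}

# O(n) centred running mean with edge-value padding
.runmean <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n < 3L) return(x)
  half <- w %/% 2L
  pad <- c(rep(x[1], half), x, rep(x[n], w - half))
  cs <- cumsum(pad)
  (cs[(w + 1L):(w + n)] - cs[1:n]) / w
}

# db8 scaling (low-pass reconstruction) filter, standard published values.
.db8_scaling <- rev(c(
  -0.00011747678412477, 0.00067544940645057, -0.00039174037337695,
  -0.00487035299345157, 0.00874609404740578, 0.01398102791739828,
  -0.04408825393079475, -0.01736930100180755, 0.12874742662047847,
  0.00047248457391328, -0.28401554296154692, -0.01582910525634931,
  0.58535468365420671, 0.67563073629728980, 0.31287159091429995,
  0.05441584224310401
))

.dilated_conv <- function(x, h, step, center = ceiling(length(h) / 2),
                          decay = NULL) {
  n <- length(x)
  offs <- (seq_along(h) - center) * step
  pad <- max(abs(offs))
  # symmetric (even) reflection: bounded extrapolation; the price is a
  # conservative baseline estimate within one filter span of the edges
  xe <- c(x[pmin(n, pad:1 + 1L)], x, x[pmax(1L, n - seq_len(pad))])
  out <- numeric(n)
  for (k in seq_along(h)) {
    out <- out + h[k] * xe[(1:n) + pad + offs[k]]
  }
  out
}

# One stage of the a-trous (stationary wavelet) approximation: convolve with
# the db8 scaling filter dilated by 2^(level-1), DC-normalised. The filter is
# applied forward then time-reversed with centers summing to length(h) + 1,
# which makes the stage exactly zero-phase (db8 itself is strongly
# asymmetric; a one-sided pass would skew the baseline estimate by seconds
# at deep levels).
.swt_smooth <- function(x, level, decay = NULL) {
  h <- .db8_scaling / sum(.db8_scaling)
  step <- 2L^(level - 1L)
  c1 <- ceiling(length(h) / 2)
  .dilated_conv(.dilated_conv(x, h, step, c1, decay), rev(h), step,
                length(h) + 1L - c1, decay)
}

#' Remove baseline wander by wavelet approximation subtraction
#'
#' Estimates the baseline as the stationary-wavelet (a-trous, db8)
#' approximation at the decomposition level whose equivalent band lies below
#' 0.5 Hz for the given sampling rate, and subtracts it. This removes
#' respiratory and contact-pressure drift while leaving pulse morphology
#' (>= 1 Hz) essentially untouched.
#'
#' @param samples Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @return Baseline-corrected signal, same length; its mean is close to zero.
#' @export
remove_baseline <- function(samples, fs) {
  samples <- as.numeric(samples)
  # smallest L with fs / 2^(L+1) < 0.5 Hz
  level <- ceiling(log2(fs / 0.5)) - 1L
  if (length(samples) < 2L^4) {
    stop("signal too short for baseline decomposition", call. = FALSE)
  }
  n <- length(samples)
  # the baseline lives below 0.5 Hz: compute the approximation on a
  # decimated grid (>= 128 Hz, comfortably above any pulse content) and
  # spline it back; identical estimate at a fraction of the work
  D <- max(1L, 2L^max(0L, floor(log2(fs / 128))))
  zpos <- seq(1L, n, by = D)
  z <- if (D > 1L) .runmean(samples, D)[zpos] else samples
  fsd <- fs / D
  level <- ceiling(log2(fsd / 0.5)) - 1L
  # extend both ends past the deepest filter span so boundary effects fall
  # outside the data: the sub-Hz component is continued by a fitted
  # autoregressive model (Yule-Walker poles are stable, so the forecast can
  # only decay toward the mean), the residual by even reflection
  span <- 16L * 2L^(level - 1L)
  ext <- .lf_extend(z, fsd, span)
  approx <- ext$x
  for (j in seq_len(level)) approx <- .swt_smooth(approx, j)
  approx <- approx[ext$offset + seq_along(z)]
  full <- if (D > 1L) stats::spline(zpos, approx, xout = seq_len(n))$y
          else approx
  samples - full
}

# Extend a signal by `span` samples per side: AR-forecast of its decimated
# low-frequency component plus even reflection of the remainder.
.lf_extend <- function(x, fs, span) {
  n <- length(x)
  M <- max(1L, as.integer(round(fs / 10)))          # decimate to ~10 Hz
  w <- max(1L, as.integer(round(0.5 * fs)))         # 0.5 s pre-smoother
  pad <- c(rep(x[1], w), x, rep(x[n], w))
  sm <- as.numeric(stats::filter(pad, rep(1 / w, w), sides = 2))[w + seq_len(n)]
  z <- sm[seq(1L, n, by = M)]
  K <- as.integer(ceiling(span / M)) + 2L
  fc <- function(series) {
    if (length(series) < 20L || stats::sd(series) == 0) {
      return(rep(series[length(series)], K))
    }
    fit <- stats::ar(series, order.max = min(16L, length(series) - 2L),
                     method = "yule-walker")
    as.numeric(stats::predict(fit, n.ahead = K, se.fit = FALSE))
  }
  zr <- fc(z); zl <- rev(fc(rev(z)))
  # low-frequency path on the sample grid (spline through decimated points)
  zpos <- seq(1L, n, by = M)
  xs <- c(1 - M * (K:1), zpos, zpos[length(zpos)] + M * seq_len(K))
  lf_all <- stats::spline(x = xs, y = c(zl, z, zr),
                          xout = (1 - span):(n + span))$y
  lf_in <- lf_all[span + seq_len(n)]
  hf <- x - lf_in
  hl <- hf[pmin(n, span:1 + 1L)]
  hr <- hf[pmax(1L, n - seq_len(span))]
  list(x = c(lf_all[seq_len(span)] + hl, x, lf_all[span + n + seq_len(span)] + hr),
       offset = span)
}

#' First and second derivatives of a pulse segment
#'
#' Five-point central differences on the signal after a double-pass 20 ms
#' moving average (a triangular smoother). The smoothing is what keeps the
#' second derivative usable at high sampling rates: differencing amplifies
#' in-band noise by the frequency squared, so without it the second
#' derivative of a 2500 Hz recording is noise-dominated even after the
#' 50 Hz low-pass, while pulse-derivative content (below about 15 Hz) is
#' attenuated by under 2%. Derivatives are returned in sensor-units per
#' second and per second squared; edge samples use the nearest interior
#' estimate so output lengths equal the input length.
#'
#' @param ppw_segment Numeric vector, length >= 5.
#' @param fs Sampling rate in Hz.
#' @param smooth_s Moving-average width in seconds (default 0.02; 0 disables
#'   smoothing).
#' @return A list with components `d1` and `d2`, same length as the input.
#' @export
derivatives <- function(ppw_segment, fs, smooth_s = 0.02) {
  x <- as.numeric(ppw_segment)
  n <- length(x)
  if (n < 5L) stop("segment too short for 5-point differences", call. = FALSE)
  w <- round(smooth_s * fs)
  if (w > 1L && n > 3L * w) {
    kern <- rep(1 / w, w)
    for (pass in 1:2) {
      pad <- c(rep(x[1], w), x, rep(x[n], w))
      sm <- as.numeric(stats::filter(pad, kern, sides = 2))
      x <- sm[(w + 1L):(w + n)]
    }
  }
  dt <- 1 / fs
  i <- 3:(n - 2)
  d1 <- numeric(n)
  d2 <- numeric(n)
  d1[i] <- (-x[i + 2] + 8 * x[i + 1] - 8 * x[i - 1] + x[i - 2]) / (12 * dt)
  d2[i] <- (-x[i + 2] + 16 * x[i + 1] - 30 * x[i] + 16 * x[i - 1] - x[i - 2]) /
    (12 * dt^2)
  d1[1:2] <- d1[3]; d1[(n - 1):n] <- d1[n - 2]
  d2[1:2] <- d2[3]; d2[(n - 1):n] <- d2[n - 2]
  list(d1 = d1, d2 = d2)
}

#' Preprocess a pulse record
#'
#' Applies the standard chain: 50 Hz zero-phase low-pass on both channels,
#' then wavelet baseline removal on the PPW. The filtered-but-not-detrended
#' PPW is retained because the peak-to-foot intensity ratio (PIR) is defined
#' on raw-frame amplitudes.
#'
#' @param record A [pulse_record()].
#' @param config A [ppw_config()] (cutoff frequency is taken from it).
#' @return The record with elements `ppw` (filtered + baseline-removed),
#'   `ppw_nobr` (filtered only) and logical flag `preprocessed`.
#' @export
preprocess_record <- function(record, config = ppw_config()) {
  stopifnot(inherits(record, "pulse_record"))
  filt <- lowpass_filter(record$ppw, record$fs, config$cutoff_hz)
  record$ppw_nobr <- filt
  record$ppw <- remove_baseline(filt, record$fs)
  if (!is.null(record$ecg)) {
    record$ecg <- lowpass_filter(record$ecg, record$fs, config$cutoff_hz)
  }
  record$preprocessed <- TRUE
  record
}
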