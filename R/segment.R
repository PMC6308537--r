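# strict local maxima above a threshold, enforcing a minimum spacing
# (larger peak wins inside a conflict window)
.local_maxima <- function(x, min_height = -Inf, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  idx <- idx[x[idx] >= min_height]
  if (length(idx) < 2L || min_dist <= 1L) return(idx)
  idx <- idx[order(x[idx], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in idx) {
    if (all(abs(i - kept) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Segment a preprocessed record into beats
#'
#' Beat feet are located at the PPW minimum preceding each systolic-upstroke
#' maximum of the first derivative; beats are delimited foot-to-foot
#' (half-open index intervals). Candidate beats shorter than 0.3 s, longer
#' than 2 s, or containing more than one prominent systolic peak are dropped
#' and counted (attribute `n_dropped`).
#'
#' @param record A preprocessed [pulse_record()] (see [preprocess_record()]).
#' @param config A [ppw_config()].
#' @return A list of beats. Each beat is a list with `start`, `end` (1-based,
#'   half-open `[start, end)` in record samples), `ppw` (baseline-removed
#'   segment), `raw` (filtered-only segment, for PIR), `d1`, `d2`, `fs`.
#'   Empty list (with a warning) when no beats are found.
#' @export
segment_beats <- function(record, config = ppw_config()) {
  stopifnot(inherits(record, "pulse_record"))
  if (is.null(record$preprocessed)) record <- preprocess_record(record, config)
  x <- record$ppw
  fs <- record$fs
  # no-signal guard: pulse amplitude below 0.1% of the raw signal level is
  # indistinguishable from filter numerics
  raw <- if (is.null(record$ppw_nobr)) record$ppw else record$ppw_nobr
  level <- max(1e-12, abs(mean(raw)), max(abs(raw)) * 1e-3)
  if (diff(range(x)) < 1e-3 * level) {
    warning("no beats found in record", call. = FALSE)
    return(structure(list(), n_dropped = 0L))
  }
  d <- derivatives(x, fs)
  d1 <- d$d1
  # threshold from the median of 2 s block maxima of d1: tracks the typical
  # systolic upstroke height and is robust to isolated large artifacts
  blocks <- split(d1, floor((seq_along(d1) - 1) / (2 * fs)))
  thr <- 0.4 * stats::median(vapply(blocks, max, 1))
  up <- .local_maxima(d1, min_height = max(thr, 0), min_dist = round(0.3 * fs))
  if (length(up) < 2L || thr <= 0) {
    warning("no beats found in record", call. = FALSE)
    return(structure(list(), n_dropped = 0L))
  }
  # foot = last point before the upstroke where the slope has died away
  # (below 3% of the upstroke d1 peak); more robust on a flat diastolic
  # tail than a plain window minimum, which is the fallback
  feet <- vapply(seq_along(up), function(i) {
    lo <- max(1L, as.integer(up[i] - round(0.4 * fs)),
              if (i > 1L) up[i - 1L] else 1L)
    flat <- which(d1[lo:up[i]] <= 0.03 * d1[up[i]])
    if (length(flat) > 0L) lo + flat[length(flat)] - 1L
    else lo + which.min(x[lo:up[i]]) - 1L
  }, integer(1))
  feet <- unique(feet)
  beats <- list()
  n_dropped <- 0L
  for (i in seq_len(length(feet) - 1L)) {
    s <- feet[i]; e <- feet[i + 1L]
    dur <- (e - s) / fs
    if (dur < 0.3 || dur > 2) { n_dropped <- n_dropped + 1L; next }
    seg <- x[s:(e - 1L)]
    amp <- max(seg) - min(seg)
    # exactly one prominent systolic peak
    pk <- .local_maxima(seg, min_height = min(seg) + 0.7 * amp,
                        min_dist = round(0.05 * fs))
    if (length(pk) != 1L) { n_dropped <- n_dropped + 1L; next }
    beats[[length(beats) + 1L]] <- list(
      start = s, end = e, fs = fs,
      ppw = seg,
      raw = if (!is.null(record$ppw_nobr)) record$ppw_nobr[s:(e - 1L)] else NULL,
      d1 = d$d1[s:(e - 1L)], d2 = d$d2[s:(e - 1L)]
    )
  }
  if (length(beats) == 0L) warning("no beats found in record", call. = FALSE)
  structure(beats, n_dropped = n_dropped)
}

#' Detect ECG R-peaks
#'
#' A light energy-based detector: 5-40 Hz zero-phase band-pass, squaring,
#' 80 ms moving-average smoothing, adaptive threshold, then refinement to the
#' local extremum of the band-passed ECG. Returns a strictly increasing index
#' vector; an empty vector on flat input.
#'
#' @param ecg Numeric ECG vector.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of R-peak sample indices (possibly empty).
#' @export
detect_r_peaks <- function(ecg, fs) {
  ecg <- as.numeric(ecg)
  if (length(ecg) < 5L || max(ecg) == min(ecg)) return(integer(0))
  bf <- signal::butter(2, c(5, min(40, 0.45 * fs)) / (fs / 2), type = "pass")
  b <- as.numeric(signal::filtfilt(bf, ecg))
  e <- b^2
  w <- max(1L, round(0.08 * fs))
  e <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  e[is.na(e)] <- 0
  thr <- 0.25 * stats::quantile(e, 0.99, names = FALSE)
  if (thr <= 0) return(integer(0))
  cand <- .local_maxima(e, min_height = thr, min_dist = round(0.25 * fs))
  # refine to the absolute-value peak of the band-passed ECG nearby
  half <- as.integer(round(0.05 * fs))
  r <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(length(b), i + half)
    as.integer(lo + which.max(abs(b[lo:hi])) - 1L)
  }, integer(1))
  sort(unique(r))
}
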