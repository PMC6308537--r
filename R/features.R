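#' Canonical names of the 21 pulse-wave features
#'
#' Order follows the study's feature table: amplitude/time ratios of the
#' dicrotic landmarks, the three K-values, the ascending-sum feature, the
#' first/second-derivative amplitude, width, slope and area features, and
#' the intensity ratio PIR. The 22nd quantity, PTT, is reported separately
#' because it needs the ECG channel.
#'
#' @format Character vector of length 21.
#' @export
ppw_feature_names <- c(
  "RtAmCE", "TmAE", "TmBE", "TmCD", "RtTP", "K", "K1", "K2", "AS",
  "d1_PAm", "d1_TW", "d2_TAm", "d2_PAm", "d2_FAm",
  "d1_AS", "d1_DS", "d1_AA", "d2_AS", "d2_DS", "d2_AA", "PIR"
)

.trapz_mean <- function(x, from, to) {
  # trapezoid-rule mean of x over index range [from, to]
  if (to <= from) return(x[from])
  seg <- x[from:to]
  n <- length(seg)
  sum((seg[-1] + seg[-n]) / 2) / (n - 1)
}

#' K-values of one beat
#'
#' The waveform characteristic value `K = (Pm - Pd) / (Ps - Pd)` where `Pd`
#' and `Ps` are the foot and peak pressures and `Pm` is the trapezoid-rule
#' mean of the waveform over the full beat. `K1` restricts the mean to the
#' systolic interval `[0, t1]` and `K2` to the diastolic interval
#' `[t1, t2]`, with `t1` the time of the dicrotic foot `D` and `t2` the beat
#' end. All three lie in `[0, 1]` for a valid beat.
#'
#' @param ppw_segment Beat waveform samples.
#' @param fs Sampling rate in Hz.
#' @param fiducials A `"fiducial_set"` with `A`, `C`, `D`.
#' @return Named numeric vector `c(K, K1, K2)`.
#' @export
k_values <- function(ppw_segment, fs, fiducials) {
  x <- as.numeric(ppw_segment)
  Pd <- x[fiducials$A]
  Ps <- x[fiducials$C]
  if (Ps <= Pd) stop("degenerate beat: peak not above foot", call. = FALSE)
  n <- length(x)
  t1 <- fiducials$D
  Pm <- .trapz_mean(x, 1L, n)
  Pm1 <- .trapz_mean(x, 1L, t1)
  Pm2 <- .trapz_mean(x, t1, n)
  c(K = (Pm - Pd) / (Ps - Pd),
    K1 = (Pm1 - Pd) / (Ps - Pd),
    K2 = (Pm2 - Pd) / (Ps - Pd))
}

#' Features of a single beat
#'
#' Computes the 21 pulse-wave features plus PTT (when an R-peak is paired)
#' from one beat and its fiducial set. Timing features are in seconds,
#' amplitude features in sensor units (or per second for derivative
#' amplitudes); ratio features are dimensionless. Sum-type features (`AS`,
#' `d1_AA`, `d2_AA`) are stored normalised by the sampling rate so they are
#' rate-independent; the raw printed sums are attached as attribute
#' `raw_sums`.
#'
#' Feature definitions, with `t(X)` the time of landmark `X` and `P`, `P'`,
#' `P''` the waveform and its derivatives:
#' \itemize{
#'   \item `RtAmCE = P2 / P1` with `P1 = P(C) - P(A)`, `P2 = P(E) - P(A)`;
#'   \item `TmAE = t(E) - t(A)`, `TmBE = t(E) - t(B)`, `TmCD = t(D) - t(C)`;
#'   \item `RtTP = TmCD / T` with `T` the beat duration (peak interval);
#'   \item `K`, `K1`, `K2`: see [k_values()];
#'   \item `AS = sum_{i=A..C} (P_i - P_A)` (discrete ascending area);
#'   \item `d1_PAm = P'(G)`, `d1_TW = t(H) - t(F)`;
#'   \item `d2_TAm = P''(M) - P''(L)`, `d2_PAm = P''(M)`, `d2_FAm = P''(L)`;
#'   \item `d1_AS = P'(G) / (t(G) - t(F))`,
#'     `d1_DS = |min P' after G| / (t(H) - t(G))`;
#'   \item `d1_AA = sum_{i=F..C} (P'_i - P'_F)`;
#'   \item `d2_AS = P''(M) / (t(M) - t(N))`,
#'     `d2_DS = P''(M) / (t(L) - t(M))`;
#'   \item `d2_AA = sum_{i=N..M} (P''_i - P''_N)`;
#'   \item `PIR = P(C) / P(A)` evaluated on the filtered signal before
#'     baseline removal (foot amplitude must be positive in that frame,
#'     otherwise PIR is reported missing);
#'   \item `PTT = t(G) - t(R-peak)`.
#' }
#' Degenerate-dicrotic beats (D = E) give `TmCD = 0` and `RtTP = 0`; this is
#' a valid observation, not an error.
#'
#' @param beat One beat from [segment_beats()].
#' @param fiducials A complete `"fiducial_set"` for that beat.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector: the 21 features of [ppw_feature_names] plus
#'   `PTT` (`NA` when no R-peak is paired). Attribute `raw_sums` carries the
#'   unnormalised `AS`, `d1_AA`, `d2_AA` sums.
#' @export
beat_features <- function(beat, fiducials, fs = beat$fs) {
  f <- fiducials
  if (!isTRUE(f$usable)) stop("fiducial set flagged unusable", call. = FALSE)
  x <- beat$ppw; d1 <- beat$d1; d2 <- beat$d2
  n <- length(x)
  tt <- function(i) (i - 1) / fs
  P1 <- x[f$C] - x[f$A]
  P2 <- x[f$E] - x[f$A]
  Tdur <- n / fs
  kv <- k_values(x, fs, f)
  AS_raw <- sum(x[f$A:f$C] - x[f$A])
  d1_AA_raw <- sum(d1[f$F:f$C] - d1[f$F])
  d2_AA_raw <- sum(d2[f$N:f$M] - d2[f$N])
  d1_min_after_G <- if (f$G < n) abs(min(d1[(f$G + 1L):n])) else NA_real_
  pir <- NA_real_
  if (!is.null(beat$raw) && beat$raw[f$A] > 0) {
    pir <- beat$raw[f$C] / beat$raw[f$A]
  }
  # a degenerate dicrotic wave (D == E) has no notch-to-peak interval
  tmcd <- if (isTRUE(f$degenerate_dicrotic)) 0 else tt(f$D) - tt(f$C)
  feats <- c(
    RtAmCE = P2 / P1,
    TmAE = tt(f$E) - tt(f$A),
    TmBE = tt(f$E) - tt(f$B),
    TmCD = tmcd,
    RtTP = tmcd / Tdur,
    kv,
    AS = AS_raw / fs,
    d1_PAm = d1[f$G],
    d1_TW = tt(f$H) - tt(f$F),
    d2_TAm = d2[f$M] - d2[f$L],
    d2_PAm = d2[f$M],
    d2_FAm = d2[f$L],
    d1_AS = d1[f$G] / (tt(f$G) - tt(f$F)),
    d1_DS = d1_min_after_G / (tt(f$H) - tt(f$G)),
    d1_AA = d1_AA_raw / fs,
    d2_AS = d2[f$M] / (tt(f$M) - tt(f$N)),
    d2_DS = d2[f$M] / (tt(f$L) - tt(f$M)),
    d2_AA = d2_AA_raw / fs,
    PIR = pir,
    PTT = if (!is.null(f$r_peak)) {
      (beat$start + f$G - 1L - f$r_peak) / fs
    } else NA_real_
  )
  structure(feats,
            raw_sums = c(AS = AS_raw, d1_AA = d1_AA_raw, d2_AA = d2_AA_raw))
}

#' Record-level feature vector
#'
#' Segments a record into beats, detects fiducials, computes per-beat
#' features and averages them arithmetically over accepted beats (the
#' beat-to-beat average over the recording). A feature missing in a beat is
#' excluded from that feature's mean; per-feature counts are returned.
#'
#' @param record A [pulse_record()] (preprocessed automatically if needed).
#' @param config A [ppw_config()].
#' @return A list of class `"ppw_features"` with elements `features` (named
#'   vector, 21 features + `PTT`), `n_beats` (per-feature counts),
#'   `n_accepted`, `n_dropped`, and record metadata. Errors when fewer than
#'   `config$min_beats` beats are accepted.
#' @export
record_features <- function(record, config = ppw_config()) {
  stopifnot(inherits(record, "pulse_record"))
  if (is.null(record$preprocessed)) record <- preprocess_record(record, config)
  beats <- segment_beats(record, config)
  r_peaks <- if (!is.null(record$ecg)) detect_r_peaks(record$ecg, record$fs)
             else integer(0)
  rows <- list()
  n_unusable <- 0L
  for (b in beats) {
    fid <- beat_fiducials(b, r_peaks = r_peaks, config = config)
    if (!isTRUE(fid$usable)) { n_unusable <- n_unusable + 1L; next }
    rows[[length(rows) + 1L]] <- beat_features(b, fid)
  }
  if (length(rows) < config$min_beats) {
    stop(sprintf("record rejected: only %d accepted beats (need >= %d)",
                 length(rows), config$min_beats), call. = FALSE)
  }
  mat <- do.call(rbind, rows)
  feats <- colMeans(mat, na.rm = TRUE)
  feats[!is.finite(feats)] <- NA_real_
  structure(
    list(features = feats,
         n_beats = colSums(!is.na(mat)),
         n_accepted = length(rows),
         n_dropped = attr(beats, "n_dropped") + n_unusable,
         subject_id = record$subject_id,
         session_time = record$session_time,
         ref_sbp = record$ref_sbp, ref_dbp = record$ref_dbp),
    class = "ppw_features"
  )
}

#' @export
print.ppw_features <- function(x, ...) {
  cat(sprintf("<ppw_features> subject %s: %d beats accepted, %d dropped\n",
              x$subject_id, x$n_accepted, x$n_dropped))
  print(round(x$features, 4))
  invisible(x)
}

#' Stack record-level feature vectors into a table
#'
#' @param feature_list List of `"ppw_features"` objects.
#' @return Data frame with one row per record: `subject_id`, `session_time`,
#'   `n_beats`, the 21 features, `PTT`, `ref_sbp`, `ref_dbp`.
#' @export
features_table <- function(feature_list) {
  rows <- lapply(feature_list, function(f) {
    cbind(
      data.frame(subject_id = f$subject_id,
                 session_time = if (is.null(f$session_time)) NA else f$session_time,
                 n_beats = f$n_accepted),
      as.data.frame(as.list(f$features)),
      data.frame(ref_sbp = if (is.null(f$ref_sbp)) NA_real_ else f$ref_sbp,
                 ref_dbp = if (is.null(f$ref_dbp)) NA_real_ else f$ref_dbp)
    )
  })
  do.call(rbind, rows)
}
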