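#' Fiducial landmarks of one pulse beat
#'
#' Locates the eleven landmark points on a beat of the pressure pulse wave
#' and its derivatives:
#' \itemize{
#'   \item on the PPW: `A` (foot), `B` (point at the first-derivative
#'     maximum), `C` (systolic peak), `D` (dicrotic foot/notch), `E`
#'     (dicrotic peak);
#'   \item on the first derivative: `F` (start/onset), `G` (peak), `H` (foot,
#'     first zero-crossing after `G`);
#'   \item on the second derivative: `N` (start), `M` (peak), `L` (foot).
#' }
#' When the dicrotic wave is absent (monotone decay after the systolic peak,
#' no first-derivative zero-crossing in the search window), the fallback rule
#' assigns `D = E =` the first-derivative maximum inside the window and sets
#' `degenerate_dicrotic = TRUE`.
#'
#' All indices are 1-based positions into the beat's own segments. Ties in
#' argmax are broken to the first index. The dicrotic search window and the
#' 10%-of-peak onset threshold are configurable.
#'
#' @param beat One beat from [segment_beats()].
#' @param r_peaks Optional integer vector of ECG R-peak record indices from
#'   [detect_r_peaks()]; used to pair the R-peak opening this cycle.
#' @param config A [ppw_config()].
#' @return A list of class `"fiducial_set"` with integer landmarks `A`, `B`,
#'   `C`, `D`, `E`, `F`, `G`, `H`, `N`, `M`, `L`, optional `r_peak` (record
#'   index), logical `degenerate_dicrotic`, logical `usable` and a `reason`
#'   string when unusable.
#' @export
beat_fiducials <- function(beat, r_peaks = NULL, config = ppw_config()) {
  fid <- detect_ppw_fiducials(beat)
  if (!fid$usable) return(fid)
  de <- detect_dicrotic(beat, fid$C, config)
  if (!de$usable) { fid$usable <- FALSE; fid$reason <- de$reason; return(fid) }
  fid$D <- de$D; fid$E <- de$E; fid$degenerate_dicrotic <- de$degenerate
  fid <- detect_derivative_fiducials(beat, fid, config)
  if (fid$usable && !is.null(r_peaks)) {
    fid$r_peak <- pair_r_peak(beat, fid, r_peaks, config)
  }
  fid
}

#' Locate foot, upstroke point and systolic peak on the PPW
#'
#' `A` is the minimum of the region up to the systolic peak (the beat starts
#' at its foot by construction), `C` the global maximum of the beat, and `B`
#' the point on the PPW at the maximum of the first derivative between `A`
#' and `C`.
#'
#' @param beat One beat from [segment_beats()].
#' @return A partial `"fiducial_set"` with `A`, `B`, `C` and `usable`.
#' @export
detect_ppw_fiducials <- function(beat) {
  x <- beat$ppw
  C <- which.max(x)
  out <- structure(list(A = NA_integer_, B = NA_integer_, C = C,
                        D = NA_integer_, E = NA_integer_,
                        F = NA_integer_, G = NA_integer_, H = NA_integer_,
                        N = NA_integer_, M = NA_integer_, L = NA_integer_,
                        r_peak = NULL, degenerate_dicrotic = FALSE,
                        usable = TRUE, reason = NULL),
                   class = "fiducial_set")
  if (C <= 1L || C >= length(x)) {
    out$usable <- FALSE; out$reason <- "no interior systolic peak"
    return(out)
  }
  out$A <- which.min(x[1:C])
  out$B <- out$A + which.max(beat$d1[out$A:C]) - 1L
  out
}

#' Locate the dicrotic foot and peak
#'
#' Searches the window `C + [w1, w2] * T` (`T` = beat duration, defaults
#' `w1 = 0.15`, `w2 = 0.60`) after the systolic peak for the first upward
#' zero-crossing of the first derivative following a downward one: that index
#' is the dicrotic foot `D`, and the subsequent local PPW maximum (downward
#' d1 zero-crossing) is the dicrotic peak `E`. If no such pair exists the
#' beat has no distinct dicrotic wave and the fallback assigns
#' `D = E = argmax(d1)` in the window with `degenerate = TRUE`.
#'
#' @param beat One beat from [segment_beats()].
#' @param C Index of the systolic peak.
#' @param config A [ppw_config()].
#' @return List with `D`, `E`, `degenerate`, `usable`, `reason`.
#' @export
detect_dicrotic <- function(beat, C, config = ppw_config()) {
  d1 <- beat$d1
  n <- length(d1)
  win <- C + round(config$dicrotic_window * n)
  lo <- max(C + 1L, win[1]); hi <- min(n, win[2])
  if (lo >= hi) {
    return(list(D = NA_integer_, E = NA_integer_, degenerate = FALSE,
                usable = FALSE, reason = "empty dicrotic search window"))
  }
  seg <- d1[lo:hi]
  # upward zero-crossings of d1 (local PPW minima): d1 <= 0 then > 0
  up <- which(seg[-length(seg)] <= 0 & seg[-1] > 0)
  D <- E <- NA_integer_
  if (length(up) > 0L) {
    D <- lo + up[1] - 1L
    after <- d1[(D + 1L):n]
    down <- which(after[-length(after)] >= 0 & after[-1] < 0)
    E <- if (length(down) > 0L) D + down[1] else {
      # no downward crossing before beat end: take the PPW maximum after D
      D + which.max(beat$ppw[(D + 1L):hi])
    }
    return(list(D = D, E = E, degenerate = FALSE, usable = TRUE, reason = NULL))
  }
  # fallback: no dicrotic wave; D and E coincide at the d1 maximum in window
  D <- E <- lo + which.max(seg) - 1L
  list(D = D, E = E, degenerate = TRUE, usable = TRUE, reason = NULL)
}

#' Locate start/peak/foot landmarks on the derivative traces
#'
#' `G` (`M`) is the argmax of the first (second) derivative between `A` and
#' `C`; `F` (`N`) is the onset, the last index before the peak at which the
#' trace is still below 10% of its peak value; `H` (`L`) is the first
#' zero-crossing after the peak.
#'
#' @param beat One beat from [segment_beats()].
#' @param fiducials Partial fiducial set with `A` and `C`.
#' @param config A [ppw_config()] (onset fraction).
#' @return The fiducial set with `F`, `G`, `H`, `N`, `M`, `L` filled in, or
#'   flagged unusable with a reason.
#' @export
detect_derivative_fiducials <- function(beat, fiducials, config = ppw_config()) {
  fid <- fiducials
  A <- fid$A; C <- fid$C
  res1 <- .onset_peak_foot(beat$d1, A, C, config$onset_frac)
  if (is.null(res1)) {
    fid$usable <- FALSE; fid$reason <- "first-derivative landmarks not found"
    return(fid)
  }
  res2 <- .onset_peak_foot(beat$d2, A, C, config$onset_frac)
  if (is.null(res2)) {
    fid$usable <- FALSE; fid$reason <- "second-derivative landmarks not found"
    return(fid)
  }
  fid$F <- res1$start; fid$G <- res1$peak; fid$H <- res1$foot
  fid$N <- res2$start; fid$M <- res2$peak; fid$L <- res2$foot
  fid
}

.onset_peak_foot <- function(tr, A, C, onset_frac) {
  peak <- A + which.max(tr[A:C]) - 1L
  pv <- tr[peak]
  if (!is.finite(pv) || pv <= 0) return(NULL)
  below <- which(tr[A:peak] <= onset_frac * pv)
  # onset may precede the detected foot; fall back to the beat start
  start <- if (length(below) == 0L) A else A + below[length(below)] - 1L
  if (start >= peak) return(NULL)
  n <- length(tr)
  if (peak >= n) return(NULL)
  zc <- which(tr[(peak + 1L):n] <= 0)
  if (length(zc) == 0L) return(NULL)
  foot <- peak + zc[1]
  list(start = start, peak = peak, foot = foot)
}

#' Pair the ECG R-peak opening a beat's cardiac cycle
#'
#' Returns the latest R-peak preceding the beat's first-derivative peak `G`
#' by at least 50 ms and at most 600 ms (the physiologic pulse-transit
#' range); `NULL` when none qualifies.
#'
#' @param beat One beat from [segment_beats()].
#' @param fiducials Fiducial set containing `G` (beat-local index).
#' @param r_peaks Integer vector of R-peak record indices.
#' @param config A [ppw_config()].
#' @return Record index of the paired R-peak, or `NULL`.
#' @export
pair_r_peak <- function(beat, fiducials, r_peaks, config = ppw_config()) {
  if (length(r_peaks) == 0L || is.na(fiducials$G)) return(NULL)
  g_global <- beat$start + fiducials$G - 1L
  lag <- (g_global - r_peaks) / beat$fs
  ok <- which(lag >= 0.05 & lag <= 0.6)
  if (length(ok) == 0L) return(NULL)
  r_peaks[ok[length(ok)]]
}

#' Tabulate fiducials for audit
#'
#' @param fiducial_sets List of `"fiducial_set"` objects (one per beat).
#' @param fs Sampling rate in Hz.
#' @return Data frame with columns `beat_id`, `landmark`, `sample_index`,
#'   `time_s` (beat-local), suitable for writing as delimited text.
#' @export
fiducial_table <- function(fiducial_sets, fs) {
  marks <- c("A", "B", "C", "D", "E", "F", "G", "H", "N", "M", "L")
  rows <- lapply(seq_along(fiducial_sets), function(i) {
    f <- fiducial_sets[[i]]
    idx <- unlist(f[marks])
    data.frame(beat_id = i, landmark = marks, sample_index = idx,
               time_s = (idx - 1) / fs)
  })
  do.call(rbind, rows)
}
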