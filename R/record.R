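#' Construct a pulse-wave acquisition record
#'
#' A `pulse_record` holds one acquisition: the pressure pulse wave (PPW)
#' sampled at the radial artery, an optional simultaneously recorded ECG
#' channel (same length and rate), the sampling rate, and the per-record
#' reference blood pressure measured with a cuff device immediately before
#' the waveform acquisition.
#'
#' @param ppw Numeric vector of PPW samples (sensor units, arbitrary scale).
#' @param fs Sampling rate in Hz; must be > 0.
#' @param ecg Optional numeric vector of ECG samples, same length as `ppw`.
#' @param subject_id Opaque subject identifier.
#' @param session_time Timestamp or day-index of the acquisition (kept as-is).
#' @param ref_sbp,ref_dbp Optional reference systolic/diastolic pressure in
#'   mmHg; when both are present `ref_sbp > ref_dbp` is required.
#'
#' @return An object of class `"pulse_record"`: a list with the fields above.
#' @export
#' @examples
#' r <- pulse_record(sin(seq(0, 10, by = 1 / 250)), fs = 250)
#' print(r)
pulse_record <- function(ppw, fs, ecg = NULL, subject_id = "anon",
                         session_time = NA, ref_sbp = NULL, ref_dbp = NULL) {
  ppw <- as.numeric(ppw)
  if (length(ppw) == 0L) stop("'ppw' must be non-empty", call. = FALSE)
  if (!all(is.finite(ppw))) stop("non-finite PPW samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number", call. = FALSE)
  }
  if (!is.null(ecg)) {
    ecg <- as.numeric(ecg)
    if (length(ecg) != length(ppw)) {
      stop("'ecg' must have the same number of samples as 'ppw'", call. = FALSE)
    }
    if (!all(is.finite(ecg))) stop("non-finite ECG samples", call. = FALSE)
  }
  if (!is.null(ref_sbp) && !is.null(ref_dbp) &&
      is.finite(ref_sbp) && is.finite(ref_dbp) && ref_sbp <= ref_dbp) {
    stop("'ref_sbp' must exceed 'ref_dbp'", call. = FALSE)
  }
  structure(
    list(ppw = ppw, ecg = ecg, fs = fs, subject_id = as.character(subject_id),
         session_time = session_time,
         ref_sbp = if (is.null(ref_sbp)) NULL else as.numeric(ref_sbp),
         ref_dbp = if (is.null(ref_dbp)) NULL else as.numeric(ref_dbp)),
    class = "pulse_record"
  )
}

#' @export
print.pulse_record <- function(x, ...) {
  cat(sprintf("<pulse_record> subject %s, %.1f s @ %g Hz (%d samples)%s\n",
              x$subject_id, length(x$ppw) / x$fs, x$fs, length(x$ppw),
              if (is.null(x$ecg)) ", no ECG" else " + ECG"))
  if (!is.null(x$ref_sbp) || !is.null(x$ref_dbp)) {
    cat(sprintf("  reference BP: %s/%s mmHg\n",
                if (is.null(x$ref_sbp)) "?" else format(x$ref_sbp),
                if (is.null(x$ref_dbp)) "?" else format(x$ref_dbp)))
  }
  invisible(x)
}

#' Read a pulse record from a signal file and JSON sidecar
#'
#' The signal file is delimited text with a header row naming at minimum a
#' `ppw` column, optionally `ecg` and `time` columns. The sidecar is a JSON
#' document with keys `fs` (required, Hz), `subject_id`, `session_time`, and
#' optional `ref_sbp`/`ref_dbp` (mmHg). When a `time` column is present its
#' spacing must agree with `fs` to within 1 part in 10^3.
#'
#' @param signal_path Path to the delimited signal file (comma-separated).
#' @param sidecar_path Path to the JSON metadata sidecar.
#' @return A validated [pulse_record()].
#' @seealso [write_record()] for the inverse.
#' @export
read_record <- function(signal_path, sidecar_path) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar is missing 'fs'", call. = FALSE)
  fs <- as.numeric(meta$fs)
  if (!is.finite(fs) || fs <= 0) stop("sidecar 'fs' must be > 0", call. = FALSE)
  tab <- utils::read.csv(signal_path, check.names = TRUE)
  if (!"ppw" %in% names(tab)) stop("signal file has no 'ppw' column", call. = FALSE)
  if (!all(is.finite(tab$ppw))) stop("non-finite PPW samples", call. = FALSE)
  if ("ecg" %in% names(tab) && !all(is.finite(tab$ecg))) {
    stop("non-finite ECG samples", call. = FALSE)
  }
  if ("time" %in% names(tab) && nrow(tab) > 1L) {
    dt <- diff(tab$time)
    if (any(abs(dt * fs - 1) > 1e-3)) {
      stop("'time' column spacing inconsistent with fs", call. = FALSE)
    }
  }
  pulse_record(
    ppw = tab$ppw, fs = fs,
    ecg = if ("ecg" %in% names(tab)) tab$ecg else NULL,
    subject_id = if (is.null(meta$subject_id)) "anon" else meta$subject_id,
    session_time = if (is.null(meta$session_time)) NA else meta$session_time,
    ref_sbp = meta$ref_sbp, ref_dbp = meta$ref_dbp
  )
}

#' Write a pulse record to a signal file and JSON sidecar
#'
#' Inverse of [read_record()]: samples are written with full precision so
#' that a read/write round trip reproduces them bit-exactly.
#'
#' @param record A [pulse_record()].
#' @param signal_path,sidecar_path Output paths.
#' @return Invisibly, `record`.
#' @export
write_record <- function(record, signal_path, sidecar_path) {
  stopifnot(inherits(record, "pulse_record"))
  tab <- data.frame(ppw = record$ppw)
  if (!is.null(record$ecg)) tab$ecg <- record$ecg
  # format with 17 significant digits: lossless for doubles
  out <- vapply(tab, function(col) sprintf("%.17g", col), character(nrow(tab)))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1L)
  con <- file(signal_path, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = ","), con)
  writeLines(apply(out, 1L, paste, collapse = ","), con)
  meta <- list(fs = record$fs, subject_id = record$subject_id,
               session_time = record$session_time)
  if (!is.null(record$ref_sbp)) meta$ref_sbp <- record$ref_sbp
  if (!is.null(record$ref_dbp)) meta$ref_dbp <- record$ref_dbp
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(record)
}
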