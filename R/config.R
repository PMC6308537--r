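#' Pipeline configuration
#'
#' Collects the tunable parameters of the extraction and modelling pipeline
#' with their documented defaults.
#'
#' @param cutoff_hz Low-pass cutoff in Hz (default 50).
#' @param baseline_max_hz Upper edge of the baseline band removed by the
#'   wavelet approximation, Hz (default 0.5; the decomposition level is
#'   derived from it and the sampling rate).
#' @param dicrotic_window Search window for the dicrotic wave, as fractions
#'   of the beat duration after the systolic peak (default `c(0.15, 0.60)`).
#' @param onset_frac Onset threshold for derivative start points `F`/`N`, as
#'   a fraction of the derivative peak (default 0.10).
#' @param gamma Trimming fraction of the fusion estimator, in `[0, 0.5)`
#'   (default 0.1, i.e. 2 of 21 predictions trimmed from each end).
#' @param cp_boundary `"closed"` (default: an error exactly at a threshold
#'   counts as within it) or `"open"`.
#' @param ttest_var_equal Logical; `FALSE` (default) uses Welch's two-sample
#'   t-test, `TRUE` the pooled-variance test.
#' @param min_beats Minimum accepted beats for a record-level feature vector
#'   (default 5).
#' @param seed Optional integer seed recorded with the config.
#' @return A list of class `"ppw_config"`.
#' @export
ppw_config <- function(cutoff_hz = 50, baseline_max_hz = 0.5,
                       dicrotic_window = c(0.15, 0.60), onset_frac = 0.10,
                       gamma = 0.1, cp_boundary = c("closed", "open"),
                       ttest_var_equal = FALSE, min_beats = 5L, seed = NULL) {
  cp_boundary <- match.arg(cp_boundary)
  stopifnot(cutoff_hz > 0, baseline_max_hz > 0,
            length(dicrotic_window) == 2L,
            dicrotic_window[1] >= 0, dicrotic_window[2] > dicrotic_window[1],
            onset_frac > 0, onset_frac < 1,
            gamma >= 0, gamma < 0.5, min_beats >= 1)
  structure(list(cutoff_hz = cutoff_hz, baseline_max_hz = baseline_max_hz,
                 dicrotic_window = dicrotic_window, onset_frac = onset_frac,
                 gamma = gamma, cp_boundary = cp_boundary,
                 ttest_var_equal = ttest_var_equal,
                 min_beats = as.integer(min_beats), seed = seed),
            class = "ppw_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' The file form round-trips losslessly through [ppw_config()] validation.
#'
#' @param path File path.
#' @param config A [ppw_config()].
#' @return `read_config()` returns a `"ppw_config"`; `write_config()` its
#'   input, invisibly.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(ppw_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ppw_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(config)
}
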