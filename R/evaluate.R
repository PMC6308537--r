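#' Mean and standard difference of estimation errors
#'
#' `MD` is the mean of the errors `y - x` (estimate minus reference) and
#' `SD` their sample standard deviation (n - 1 denominator).
#'
#' @param references Reference blood-pressure values, mmHg.
#' @param estimates Estimated values, mmHg, same length (n >= 2).
#' @return List with `MD` and `SD` in mmHg.
#' @export
md_sd <- function(references, estimates) {
  e <- as.numeric(estimates) - as.numeric(references)
  if (length(e) < 2L) stop("need at least 2 paired values", call. = FALSE)
  list(MD = mean(e), SD = stats::sd(e))
}

#' Cumulative percentages of absolute error
#'
#' Percentage of absolute errors within 5, 10 and 15 mmHg; the basis of BHS
#' grading. An error exactly at a threshold counts as within it (closed
#' interval) unless `boundary = "open"`.
#'
#' @param errors Numeric vector of estimation errors, mmHg.
#' @param boundary `"closed"` (default) or `"open"`.
#' @return Named numeric vector `c(CP5, CP10, CP15)` in percent.
#' @export
cumulative_percentages <- function(errors, boundary = c("closed", "open")) {
  boundary <- match.arg(boundary)
  if (length(errors) < 1L) stop("empty error vector", call. = FALSE)
  a <- abs(as.numeric(errors))
  cmp <- if (boundary == "closed") `<=` else `<`
  vapply(c(CP5 = 5, CP10 = 10, CP15 = 15),
         function(th) 100 * mean(cmp(a, th)), numeric(1))
}

# BHS grade thresholds (percent within 5/10/15 mmHg); A and B as printed in
# the study, C from the BHS standard itself.
.bhs_thresholds <- list(
  A = c(60, 85, 95),
  B = c(50, 75, 90),
  C = c(40, 65, 85)
)

#' British Hypertension Society grade from a CP triple
#'
#' Returns the highest grade whose three thresholds are all strictly
#' exceeded: Grade A requires CP5 > 60, CP10 > 85, CP15 > 95; Grade B
#' 50/75/90; Grade C 40/65/85; otherwise D. Monotone in each CP.
#'
#' @param cp5,cp10,cp15 Cumulative percentages within 5/10/15 mmHg.
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
#' @examples
#' bhs_grade(50.95, 81.18, 94.77)  # "B"
bhs_grade <- function(cp5, cp10, cp15) {
  cp <- c(cp5, cp10, cp15)
  stopifnot(all(is.finite(cp)), all(cp >= 0), all(cp <= 100))
  for (g in names(.bhs_thresholds)) {
    if (all(cp > .bhs_thresholds[[g]])) return(g)
  }
  "D"
}

#' AAMI accuracy verdict
#'
#' The AAMI standard requires estimation errors within 5 +/- 8 mmHg, read as
#' `|MD| <= 5` and `SD <= 8` (inclusive bounds).
#'
#' @param MD,SD Mean and standard deviation of errors, mmHg.
#' @return Logical.
#' @export
aami_check <- function(MD, SD) {
  isTRUE(abs(MD) <= 5 && SD <= 8)
}

#' Pearson correlation between reference and estimated pressure
#'
#' @param references,estimates Paired numeric vectors, n >= 3, both
#'   non-constant.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(references, estimates) {
  x <- as.numeric(references); y <- as.numeric(estimates)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias equals the mean difference MD; the limits are `MD +/- 1.96 * SD`.
#'
#' @inheritParams md_sd
#' @return List with `bias`, `lower`, `upper` (mmHg).
#' @export
bland_altman <- function(references, estimates) {
  m <- md_sd(references, estimates)
  list(bias = m$MD, lower = m$MD - 1.96 * m$SD, upper = m$MD + 1.96 * m$SD)
}

#' Two-sample t-test between the error samples of two models
#'
#' Welch's test by default (`var_equal = TRUE` gives the pooled-variance
#' flavour); p < 0.05 is conventionally regarded as a significant accuracy
#' difference.
#'
#' @param errors_a,errors_b Error samples of the two models, mmHg.
#' @param var_equal Logical, default `FALSE` (Welch).
#' @return List with `t_statistic`, `p_value`, `df`.
#' @export
compare_models <- function(errors_a, errors_b, var_equal = FALSE) {
  if (length(errors_a) < 2L || length(errors_b) < 2L) {
    stop("need at least 2 errors per sample", call. = FALSE)
  }
  if (stats::sd(errors_a) == 0 && stats::sd(errors_b) == 0) {
    if (isTRUE(all.equal(mean(errors_a), mean(errors_b)))) {
      return(list(t_statistic = 0, p_value = 1, df = NA_real_))
    }
    stop("degenerate variance in both samples", call. = FALSE)
  }
  tt <- stats::t.test(errors_a, errors_b, var.equal = var_equal)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Full accuracy report for one model and target
#'
#' Bundles every evaluation measure: MD/SD of the errors, cumulative
#' percentages, BHS grade, AAMI verdict, Pearson correlation and
#' Bland-Altman limits.
#'
#' @param references Reference BP values, mmHg.
#' @param estimates Estimated BP values, mmHg.
#' @param target Label, `"SBP"` or `"DBP"` (cosmetic).
#' @param boundary CP boundary convention, see [cumulative_percentages()].
#' @return Object of class `"bp_eval"`.
#' @export
bp_evaluate <- function(references, estimates, target = "SBP",
                        boundary = c("closed", "open")) {
  boundary <- match.arg(boundary)
  ok <- is.finite(references) & is.finite(estimates)
  x <- references[ok]; y <- estimates[ok]
  m <- md_sd(x, y)
  cp <- cumulative_percentages(y - x, boundary)
  structure(
    list(target = target, n = length(x), MD = m$MD, SD = m$SD,
         CP5 = cp[["CP5"]], CP10 = cp[["CP10"]], CP15 = cp[["CP15"]],
         bhs_grade = bhs_grade(cp[["CP5"]], cp[["CP10"]], cp[["CP15"]]),
         aami_pass = aami_check(m$MD, m$SD),
         pearson_r = if (length(x) >= 3L && stats::sd(x) > 0 &&
                         stats::sd(y) > 0) pearson_cc(x, y) else NA_real_,
         bland_altman = bland_altman(x, y)),
    class = "bp_eval"
  )
}

#' @export
print.bp_eval <- function(x, ...) {
  cat(sprintf("<bp_eval> %s, n = %d\n", x$target, x$n))
  cat(sprintf("  error: %.2f +/- %.2f mmHg  (AAMI %s)\n", x$MD, x$SD,
              if (x$aami_pass) "pass" else "fail"))
  cat(sprintf("  CP5/10/15: %.2f%% / %.2f%% / %.2f%%  (BHS grade %s)\n",
              x$CP5, x$CP10, x$CP15, x$bhs_grade))
  cat(sprintf("  Pearson r = %.3f; Bland-Altman %.2f [%.2f, %.2f] mmHg\n",
              x$pearson_r, x$bland_altman$bias, x$bland_altman$lower,
              x$bland_altman$upper))
  invisible(x)
}

#' @export
as.data.frame.bp_eval <- function(x, ...) {
  data.frame(target = x$target, n = x$n, MD = x$MD, SD = x$SD,
             CP5 = x$CP5, CP10 = x$CP10, CP15 = x$CP15,
             bhs_grade = x$bhs_grade, aami_pass = x$aami_pass,
             pearson_r = x$pearson_r,
             ba_lower = x$bland_altman$lower, ba_upper = x$bland_altman$upper)
}
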