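#' Univariate least-squares calibration of one feature
#'
#' Ordinary least squares of a blood-pressure target on a single pulse-wave
#' feature: `BP = slope * feature + intercept`, the building block of the
#' fusion estimator.
#'
#' @param x Feature values.
#' @param y Reference blood-pressure values, mmHg.
#' @return List with `slope` and `intercept` (mmHg per feature-unit, mmHg).
#' @export
fit_univariate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (diff(range(x)) == 0) {
    stop("degenerate fit: feature is constant", call. = FALSE)
  }
  cf <- stats::coef(stats::lm(y ~ x))
  list(slope = unname(cf[2]), intercept = unname(cf[1]))
}

#' Multiparameter-fusion combination of single-feature predictions
#'
#' The fusion estimate is the symmetrically trimmed mean of the `N`
#' single-feature predictions minus their (untrimmed) sample standard
#' deviation: with `F(1) <= ... <= F(N)` the ordered predictions and
#' `g = floor(gamma * N)`,
#' \deqn{MPF = \frac{F_{(g+1)} + \cdots + F_{(N-g)}}{N - 2g} - STD}
#' where `STD` is the n-1-denominator standard deviation of all `N`
#' predictions. With `gamma = 0` this is exactly `mean(F) - sd(F)`.
#'
#' @param predictions Numeric vector of single-feature predictions, mmHg.
#'   The reference ensemble size is 21; other sizes are accepted.
#' @param gamma Trimming fraction in `[0, 0.5)`.
#' @return Fused estimate in mmHg.
#' @export
#' @examples
#' mpf_predict(1:21, gamma = 0.1)  # mean(3:19) - sd(1:21)
mpf_predict <- function(predictions, gamma = 0.1) {
  predictions <- as.numeric(predictions)
  N <- length(predictions)
  if (N < 1L) stop("empty prediction vector", call. = FALSE)
  if (!all(is.finite(predictions))) {
    stop("non-finite prediction in fusion input", call. = FALSE)
  }
  if (gamma < 0 || gamma >= 0.5) stop("'gamma' must be in [0, 0.5)", call. = FALSE)
  g <- floor(gamma * N)
  if (N - 2 * g < 1L) stop("trimming removes all predictions", call. = FALSE)
  s <- sort(predictions)
  mean(s[(g + 1L):(N - g)]) - stats::sd(predictions)
}

#' Fit a per-subject multiparameter-fusion blood-pressure model
#'
#' Fits, for each target (SBP and DBP), 21 univariate least-squares
#' calibrations — one per pulse-wave feature — whose predictions are later
#' combined by [mpf_predict()]: the trimmed mean of the 21 single-feature
#' estimates minus their standard deviation. Calibration is strictly
#' per subject; pass one subject's training rows.
#'
#' @param data Data frame of training rows: the 21 feature columns of
#'   [ppw_feature_names] plus `ref_sbp` and `ref_dbp` (mmHg). At least 2
#'   rows; the study protocol collects no fewer than 16 calibration
#'   records spread over one day.
#' @param gamma Trimming fraction of the fusion, in `[0, 0.5)`; default 0.1.
#' @param features Feature set to calibrate (default all 21).
#' @return An object of class `"mpf_model"`: coefficient array
#'   `coef[feature, c(slope, intercept), target]`, `gamma`, `n` and training
#'   metadata. Supports `print`, `summary`, `coef`, `predict`, `residuals`
#'   and `plot`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 1, link = "linear"))
#' tr <- subset(co$features, day == 0)
#' m <- mpf_fit(tr)
#' predict(m, tr)[1:2, ]
mpf_fit <- function(data, gamma = 0.1, features = ppw_feature_names) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 2L) stop("need at least 2 training rows", call. = FALSE)
  missing_cols <- setdiff(c(features, "ref_sbp", "ref_dbp"), names(data))
  if (length(missing_cols) > 0L) {
    stop("training data lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  targets <- c(sbp = "ref_sbp", dbp = "ref_dbp")
  cf <- array(NA_real_, dim = c(length(features), 2L, 2L),
              dimnames = list(features, c("slope", "intercept"),
                              names(targets)))
  for (tg in names(targets)) {
    y <- data[[targets[[tg]]]]
    for (fn in features) {
      fit <- tryCatch(fit_univariate(data[[fn]], y), error = function(e) {
        stop(sprintf("feature '%s' (%s): %s", fn, tg, conditionMessage(e)),
             call. = FALSE)
      })
      cf[fn, , tg] <- c(fit$slope, fit$intercept)
    }
  }
  out <- structure(
    list(coef = cf, gamma = gamma, features = features, n = nrow(data),
         subject_id = if ("subject_id" %in% names(data))
           as.character(data$subject_id[1]) else NA_character_,
         train = data[, c(features, "ref_sbp", "ref_dbp")]),
    class = "mpf_model"
  )
  out
}

# 21 single-feature predictions for each row; matrix rows x features
.component_predictions <- function(object, newdata, target) {
  cf <- object$coef[, , target, drop = FALSE]
  sapply(object$features, function(fn) {
    cf[fn, "slope", 1] * newdata[[fn]] + cf[fn, "intercept", 1]
  })
}

#' Predict blood pressure from a fitted fusion model
#'
#' @param object An `"mpf_model"`.
#' @param newdata Data frame with the model's feature columns.
#' @param type `"fused"` (default) returns the fusion estimate per row;
#'   `"components"` returns the 21 single-feature predictions (a matrix per
#'   target) for audit.
#' @param ... Unused.
#' @return For `"fused"`: data frame with columns `sbp` and `dbp` (mmHg),
#'   with the component predictions attached as attribute `components`. For
#'   `"components"`: list of two matrices.
#' @export
predict.mpf_model <- function(object, newdata, type = c("fused", "components"),
                              ...) {
  type <- match.arg(type)
  if (missing(newdata)) newdata <- object$train
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata)
  comp <- list(
    sbp = .component_predictions(object, newdata, "sbp"),
    dbp = .component_predictions(object, newdata, "dbp")
  )
  for (tg in names(comp)) {
    if (is.null(dim(comp[[tg]]))) {
      comp[[tg]] <- matrix(comp[[tg]], nrow = 1L,
                           dimnames = list(NULL, object$features))
    }
  }
  if (type == "components") return(comp)
  fused <- data.frame(
    sbp = apply(comp$sbp, 1L, mpf_predict, gamma = object$gamma),
    dbp = apply(comp$dbp, 1L, mpf_predict, gamma = object$gamma)
  )
  attr(fused, "components") <- comp
  fused
}

#' @export
print.mpf_model <- function(x, ...) {
  cat(sprintf(
    "<mpf_model> subject %s: %d univariate calibrations per target, gamma = %g (trim %d of %d), n = %d\n",
    x$subject_id, length(x$features), x$gamma,
    floor(x$gamma * length(x$features)), length(x$features), x$n))
  invisible(x)
}

#' @export
coef.mpf_model <- function(object, ...) object$coef

#' @export
residuals.mpf_model <- function(object, ...) {
  p <- predict(object, object$train)
  data.frame(sbp = p$sbp - object$train$ref_sbp,
             dbp = p$dbp - object$train$ref_dbp)
}

#' @export
summary.mpf_model <- function(object, ...) {
  r <- residuals(object)
  out <- list(model = object,
              train_md_sd = rbind(sbp = unlist(md_sd(object$train$ref_sbp,
                                                     predict(object)$sbp)),
                                  dbp = unlist(md_sd(object$train$ref_dbp,
                                                     predict(object)$dbp))))
  class(out) <- "summary.mpf_model"
  out
}

#' @export
print.summary.mpf_model <- function(x, ...) {
  print(x$model)
  cat("Slopes (mmHg per feature-unit):\n")
  print(round(t(x$model$coef[, "slope", ]), 3))
  cat("Training error (MD, SD) mmHg:\n")
  print(round(x$train_md_sd, 3))
  invisible(x)
}

#' @export
plot.mpf_model <- function(x, ...) {
  p <- predict(x)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (tg in c("sbp", "dbp")) {
    ref <- x$train[[paste0("ref_", tg)]]
    graphics::plot(ref, p[[tg]], xlab = sprintf("reference %s (mmHg)", toupper(tg)),
                   ylab = "fused estimate (mmHg)",
                   main = sprintf("%s calibration fit", toupper(tg)), ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Fit the pulse-transit-time baseline models
#'
#' Three classical PTT calibration models per target: `"linear"`
#' (`BP = a * PTT + b`), `"inverse"` (`BP = a / PTT + b`), and
#' `"log_inv_sq"` (`BP = a * ln(1/PTT) + b / PTT^2 + c`).
#'
#' @param data Data frame with columns `PTT`, `ref_sbp`, `ref_dbp`.
#' @param variant One of `"linear"`, `"inverse"`, `"log_inv_sq"`.
#' @return Object of class `"ptt_model"` with per-target coefficient lists.
#' @export
ptt_fit <- function(data, variant = c("linear", "inverse", "log_inv_sq")) {
  variant <- match.arg(variant)
  if (!"PTT" %in% names(data) || !any(is.finite(data$PTT))) {
    stop("no PTT values in training data", call. = FALSE)
  }
  models <- list()
  for (tg in c("sbp", "dbp")) {
    y <- data[[paste0("ref_", tg)]]
    ptt <- data$PTT
    ok <- is.finite(ptt) & is.finite(y) & ptt > 0
    if (sum(ok) < 3L) stop("too few PTT observations", call. = FALSE)
    df <- switch(variant,
      linear = data.frame(y = y[ok], x1 = ptt[ok]),
      inverse = data.frame(y = y[ok], x1 = 1 / ptt[ok]),
      log_inv_sq = data.frame(y = y[ok], x1 = log(1 / ptt[ok]),
                              x2 = 1 / ptt[ok]^2)
    )
    models[[tg]] <- stats::coef(stats::lm(y ~ ., data = df))
  }
  structure(list(variant = variant, coef = models, n = sum(is.finite(data$PTT))),
            class = "ptt_model")
}

#' @export
print.ptt_model <- function(x, ...) {
  cat(sprintf("<ptt_model> variant '%s', n = %d\n", x$variant, x$n))
  print(lapply(x$coef, round, 3))
  invisible(x)
}

#' @export
predict.ptt_model <- function(object, newdata, ...) {
  ptt <- newdata$PTT
  out <- data.frame(sbp = rep(NA_real_, length(ptt)), dbp = NA_real_)
  ok <- is.finite(ptt) & ptt > 0
  for (tg in c("sbp", "dbp")) {
    cf <- object$coef[[tg]]
    out[[tg]][ok] <- switch(object$variant,
      linear = cf[1] + cf[2] * ptt[ok],
      inverse = cf[1] + cf[2] / ptt[ok],
      log_inv_sq = cf[1] + cf[2] * log(1 / ptt[ok]) + cf[3] / ptt[ok]^2
    )
  }
  out
}

#' Fit all calibration models for one subject
#'
#' Convenience wrapper fitting the fusion model and, when PTT is available,
#' the three PTT baselines on one subject's training rows.
#'
#' @param data One subject's training rows (see [mpf_fit()]).
#' @param gamma Trimming fraction for the fusion.
#' @return List with `mpf` (an `"mpf_model"`) and `ptt` (named list of
#'   `"ptt_model"`, empty when the data carry no PTT).
#' @export
fit_subject <- function(data, gamma = 0.1) {
  mpf <- mpf_fit(data, gamma = gamma)
  ptt <- list()
  if ("PTT" %in% names(data) && sum(is.finite(data$PTT)) >= 3L) {
    for (v in c("linear", "inverse", "log_inv_sq")) {
      ptt[[v]] <- ptt_fit(data, v)
    }
  }
  list(mpf = mpf, ptt = ptt)
}

#' Save / load fitted models as JSON
#'
#' The persistence format is a diffable JSON document keyed by target and
#' feature, carrying slope/intercept pairs, the trimming fraction, and PTT
#' baseline coefficients.
#'
#' @param models Result of [fit_subject()] (or an `"mpf_model"` alone).
#' @param path File path.
#' @return `read_models()` reconstructs the list; `write_models()` returns
#'   its input invisibly.
#' @export
write_models <- function(models, path) {
  if (inherits(models, "mpf_model")) models <- list(mpf = models, ptt = list())
  m <- models$mpf
  doc <- list(
    subject_id = m$subject_id, gamma = m$gamma, n = m$n,
    features = m$features,
    coef = lapply(c(sbp = "sbp", dbp = "dbp"), function(tg) {
      lapply(stats::setNames(m$features, m$features), function(fn) {
        list(slope = m$coef[fn, "slope", tg],
             intercept = m$coef[fn, "intercept", tg])
      })
    }),
    ptt = lapply(models$ptt, function(p) {
      list(variant = p$variant, n = p$n, coef = lapply(p$coef, as.list))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(models)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  features <- unlist(doc$features)
  cf <- array(NA_real_, dim = c(length(features), 2L, 2L),
              dimnames = list(features, c("slope", "intercept"),
                              c("sbp", "dbp")))
  for (tg in c("sbp", "dbp")) {
    for (fn in features) {
      cf[fn, , tg] <- c(doc$coef[[tg]][[fn]]$slope, doc$coef[[tg]][[fn]]$intercept)
    }
  }
  mpf <- structure(
    list(coef = cf, gamma = doc$gamma, features = features, n = doc$n,
         subject_id = if (is.null(doc$subject_id)) NA_character_
                      else doc$subject_id,
         train = NULL),
    class = "mpf_model"
  )
  ptt <- lapply(doc$ptt, function(p) {
    structure(list(variant = p$variant,
                   coef = lapply(p$coef, function(v) unlist(v)),
                   n = p$n), class = "ptt_model")
  })
  list(mpf = mpf, ptt = ptt)
}
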