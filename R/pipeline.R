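#' Extract features from every record in a directory
#'
#' Reads each signal/sidecar pair (written by [write_record()] or
#' [write_cohort()]), runs preprocessing, beat segmentation, fiducial
#' detection and feature averaging, and stacks the results. A file that
#' fails to read or a record that yields too few beats is reported and
#' skipped; the run continues.
#'
#' @param signals_dir Directory of `*.csv` signal files with `*.json`
#'   sidecars.
#' @param config A [ppw_config()].
#' @return Feature table as in [features_table()], with attribute
#'   `rejected`: data frame of skipped files and reasons.
#' @export
run_extract <- function(signals_dir, config = ppw_config()) {
  sidecars <- sort(list.files(signals_dir, pattern = "^rec.*\\.json$",
                              full.names = TRUE))
  feats <- list()
  rej <- list()
  for (sc in sidecars) {
    sig <- sub("\\.json$", ".csv", sc)
    res <- tryCatch(
      record_features(read_record(sig, sc), config),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      rej[[length(rej) + 1L]] <- data.frame(file = basename(sig), reason = res)
      warning(sprintf("skipping %s: %s", basename(sig), res), call. = FALSE)
    } else {
      feats[[length(feats) + 1L]] <- res
    }
  }
  tab <- if (length(feats) > 0L) {
    features_table(feats)
  } else {
    cols <- c("subject_id", "session_time", "n_beats", ppw_feature_names,
              "PTT", "ref_sbp", "ref_dbp")
    stats::setNames(data.frame(matrix(nrow = 0L, ncol = length(cols))), cols)
  }
  attr(tab, "rejected") <- if (length(rej) > 0L) do.call(rbind, rej) else
    data.frame(file = character(0), reason = character(0))
  tab
}

# extract the feature table for a cohort (regenerating waveform records on
# the fly); linear-link cohorts already carry their features
.cohort_features <- function(cohort, config = ppw_config()) {
  if (!is.null(cohort$features)) return(cohort$features)
  m <- cohort$manifest
  rows <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    rec <- cohort_record(cohort, i)$record
    rf <- record_features(rec, config)
    rows[[i]] <- cbind(
      data.frame(subject_id = m$subject_id[i], set = m$set[i], day = m$day[i],
                 hour = m$hour[i], n_beats = rf$n_accepted),
      as.data.frame(as.list(rf$features)),
      data.frame(ref_sbp = m$ref_sbp[i], ref_dbp = m$ref_dbp[i])
    )
  }
  do.call(rbind, rows)
}

#' Run the full calibration/test experiment on a synthetic cohort
#'
#' Simulates (or accepts) a cohort, extracts record-level features, fits the
#' per-subject fusion model and PTT baselines on each subject's training
#' day, predicts every test record, and evaluates: pooled accuracy per model
#' and target (the fusion, the 21 single-feature calibrations, the three
#' PTT baselines), per-test-day accuracy of the fusion and best PTT
#' baseline, and two-sample t-tests comparing fusion errors with each PTT
#' baseline's.
#'
#' @param spec A [cohort_spec()] or an already generated `"ppw_cohort"`.
#' @param config A [ppw_config()].
#' @return Object of class `"bp_experiment"`: `features`, `pooled` (data
#'   frame of accuracy rows), `per_day`, `ttests`, `evals` (named list of
#'   [bp_evaluate()] objects), `predictions`, `spec`, `config`.
#' @export
run_experiment <- function(spec = cohort_spec(), config = ppw_config()) {
  cohort <- if (inherits(spec, "ppw_cohort")) spec else generate_cohort(spec)
  feats <- .cohort_features(cohort, config)
  test <- feats[feats$set == "test", , drop = FALSE]
  n_feat <- length(ppw_feature_names)
  has_ptt <- "PTT" %in% names(feats) && any(is.finite(feats$PTT))
  # per-subject calibration, prediction on that subject's test rows
  pred <- list(mpf = data.frame(sbp = rep(NA_real_, nrow(test)), dbp = NA_real_))
  comp <- list(sbp = matrix(NA_real_, nrow(test), n_feat,
                            dimnames = list(NULL, ppw_feature_names)))
  comp$dbp <- comp$sbp
  ptt_variants <- c("linear", "inverse", "log_inv_sq")
  if (has_ptt) {
    for (v in ptt_variants) pred[[paste0("ptt_", v)]] <- pred$mpf
  }
  for (sid in unique(feats$subject_id)) {
    tr <- feats[feats$set == "train" & feats$subject_id == sid, , drop = FALSE]
    te_idx <- which(test$subject_id == sid)
    if (length(te_idx) == 0L) next
    models <- fit_subject(tr, gamma = config$gamma)
    p <- predict(models$mpf, test[te_idx, , drop = FALSE])
    pred$mpf[te_idx, ] <- p
    cc <- attr(p, "components")
    comp$sbp[te_idx, ] <- cc$sbp
    comp$dbp[te_idx, ] <- cc$dbp
    for (v in names(models$ptt)) {
      pred[[paste0("ptt_", v)]][te_idx, ] <-
        predict(models$ptt[[v]], test[te_idx, , drop = FALSE])
    }
  }
  # pooled evaluation per model and target
  evals <- list()
  for (tg in c("sbp", "dbp")) {
    ref <- test[[paste0("ref_", tg)]]
    evals[[paste0("mpf_", tg)]] <-
      bp_evaluate(ref, pred$mpf[[tg]], toupper(tg), config$cp_boundary)
    for (fn in ppw_feature_names) {
      evals[[paste0(fn, "_", tg)]] <-
        bp_evaluate(ref, comp[[tg]][, fn], toupper(tg), config$cp_boundary)
    }
    if (has_ptt) {
      for (v in ptt_variants) {
        evals[[paste0("ptt_", v, "_", tg)]] <-
          bp_evaluate(ref, pred[[paste0("ptt_", v)]][[tg]], toupper(tg),
                      config$cp_boundary)
      }
    }
  }
  pooled <- do.call(rbind, lapply(names(evals), function(nm) {
    cbind(data.frame(model = sub("_(sbp|dbp)$", "", nm)),
          as.data.frame(evals[[nm]]))
  }))
  # per-day robustness of the fusion (and best PTT baseline)
  per_day <- list()
  for (d in sort(unique(test$day))) {
    sel <- test$day == d
    for (tg in c("sbp", "dbp")) {
      ref <- test[[paste0("ref_", tg)]][sel]
      row <- cbind(data.frame(day = d, model = "mpf"),
                   as.data.frame(bp_evaluate(ref, pred$mpf[[tg]][sel],
                                             toupper(tg), config$cp_boundary)))
      per_day[[length(per_day) + 1L]] <- row
      if (has_ptt) {
        row <- cbind(data.frame(day = d, model = "ptt_log_inv_sq"),
                     as.data.frame(
                       bp_evaluate(ref, pred$ptt_log_inv_sq[[tg]][sel],
                                   toupper(tg), config$cp_boundary)))
        per_day[[length(per_day) + 1L]] <- row
      }
    }
  }
  per_day <- do.call(rbind, per_day)
  # fusion vs PTT baselines, two-sample t-test on errors
  ttests <- NULL
  if (has_ptt) {
    tt_rows <- list()
    for (tg in c("sbp", "dbp")) {
      ref <- test[[paste0("ref_", tg)]]
      e_mpf <- pred$mpf[[tg]] - ref
      for (v in ptt_variants) {
        e_ptt <- pred[[paste0("ptt_", v)]][[tg]] - ref
        ok <- is.finite(e_mpf) & is.finite(e_ptt)
        ct <- compare_models(e_mpf[ok], e_ptt[ok], config$ttest_var_equal)
        tt_rows[[length(tt_rows) + 1L]] <- data.frame(
          target = toupper(tg), baseline = paste0("ptt_", v),
          t_statistic = ct$t_statistic, p_value = ct$p_value)
      }
    }
    ttests <- do.call(rbind, tt_rows)
  }
  structure(list(features = feats, pooled = pooled, per_day = per_day,
                 ttests = ttests, evals = evals, predictions = pred,
                 spec = cohort$spec, config = config),
            class = "bp_experiment")
}

#' @export
print.bp_experiment <- function(x, ...) {
  cat("<bp_experiment>\n")
  show <- x$pooled[x$pooled$model %in%
                     c("mpf", "ptt_linear", "ptt_inverse", "ptt_log_inv_sq"), ]
  cat("Pooled test accuracy (fusion and PTT baselines):\n")
  print(cbind(show[, c("model", "target", "n")],
              round(show[, c("MD", "SD", "CP5", "CP10", "CP15")], 2),
              show[, c("bhs_grade", "aami_pass")]), row.names = FALSE)
  if (!is.null(x$ttests)) {
    cat("Fusion vs PTT baselines (two-sample t-test on errors):\n")
    print(cbind(x$ttests[, c("target", "baseline")],
                t = round(x$ttests$t_statistic, 2),
                p = signif(x$ttests$p_value, 3)), row.names = FALSE)
  }
  invisible(x)
}
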