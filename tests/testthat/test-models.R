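# brute-force oracle for the fusion combination: sort, trim, average,
# subtract the untrimmed sample SD
oracle_mpf <- function(v, gamma) {
  N <- length(v)
  g <- floor(gamma * N)
  s <- sort(v)
  kept <- s[(g + 1):(N - g)]
  sum(kept) / length(kept) - sqrt(sum((v - mean(v))^2) / (N - 1))
}

test_that("univariate least squares recovers exact and noisy slopes", {
  x <- c(1, 2, 3, 5, 8)
  fit <- fit_univariate(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  # noisy case: slope within 3 standard errors
  set.seed(7)
  x <- rnorm(16, 10, 3)
  y <- 0.8 * x + rnorm(16, 0, 1)
  fit <- fit_univariate(x, y)
  se <- 1 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(fit$slope - 0.8), 3 * se)
  expect_error(fit_univariate(rep(2, 5), 1:5), "constant")
  expect_error(fit_univariate(1, 2), "at least 2")
})

test_that("fusion combination matches the brute-force oracle", {
  # identical predictions: zero dispersion, output is the common value
  expect_equal(mpf_predict(rep(100, 21), gamma = 0.3), 100)
  # worked example: 1..21 at gamma 0.1 (g = 2)
  expect_equal(mpf_predict(1:21, gamma = 0.1),
               mean(3:19) - sd(1:21))
  # randomized equivalence across gammas
  set.seed(123)
  for (gamma in c(0, 0.05, 0.1, 0.2)) {
    for (i in 1:200) {
      v <- rnorm(21, 120, 10)
      expect_equal(mpf_predict(v, gamma), oracle_mpf(v, gamma))
    }
  }
  expect_error(mpf_predict(c(1:20, NA)), "non-finite")
  expect_error(mpf_predict(1:21, gamma = 0.5), "gamma")
})

test_that("fusion is order-invariant, shift-equivariant and outlier-robust", {
  set.seed(5)
  v <- rnorm(21, 120, 8)
  expect_equal(mpf_predict(sample(v), 0.1), mpf_predict(v, 0.1))
  # gamma = 0 equals mean - sd exactly
  expect_equal(mpf_predict(v, 0), mean(v) - sd(v))
  # adding a constant raises the output by exactly that constant
  expect_equal(mpf_predict(v + 7.3, 0.1), mpf_predict(v, 0.1) + 7.3)
  # the trimmed-mean term is insensitive to the magnitude of the extreme
  # predictions: grossly corrupting the largest and smallest leaves it put
  trim_term <- function(x) { s <- sort(x); mean(s[3:19]) }
  w <- v
  w[which.max(v)] <- 1e6
  w[which.min(v)] <- -1e6
  expect_equal(trim_term(w), trim_term(v))
  # the untrimmed plain mean is not robust
  expect_false(isTRUE(all.equal(mean(w), mean(v))))
})

test_that("subject calibration fits 21 models per target and predicts", {
  co <- generate_cohort(cohort_spec(n_subjects = 1, link = "linear", seed = 3))
  tr <- co$features[co$features$set == "train", ]
  m <- mpf_fit(tr, gamma = 0.1)
  expect_s3_class(m, "mpf_model")
  expect_equal(dim(coef(m)), c(21L, 2L, 2L))
  expect_equal(m$n, nrow(tr))
  p <- predict(m, tr)
  expect_true(all(is.finite(p$sbp)), all(is.finite(p$dbp)))
  comp <- attr(p, "components")
  expect_equal(dim(comp$sbp), c(nrow(tr), 21L))
  # errors: too few rows, missing features, degenerate feature
  expect_error(mpf_fit(tr[1, ]), "at least 2")
  expect_error(mpf_fit(tr[, -match("K", names(tr))]), "K")
  bad <- tr; bad$K <- 1
  expect_error(mpf_fit(bad), "K")
  # arithmetic check of a univariate prediction path
  m2 <- m
  m2$coef["K", , "sbp"] <- c(2, 1)
  row <- tr[1, ]; row$K <- 3
  expect_equal(unname(predict(m2, row, type = "components")$sbp[, "K"]), 7)
})

test_that("model methods print, summarise, and expose residuals", {
  co <- generate_cohort(cohort_spec(n_subjects = 1, link = "linear", seed = 4))
  tr <- co$features[co$features$set == "train", ]
  m <- mpf_fit(tr)
  expect_output(print(m), "univariate calibrations")
  expect_output(print(summary(m)), "Slopes")
  r <- residuals(m)
  expect_equal(nrow(r), nrow(tr))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})

test_that("PTT baseline models fit their three functional forms", {
  set.seed(11)
  ptt <- runif(20, 0.15, 0.3)
  dat <- data.frame(PTT = ptt,
                    ref_sbp = 10 / ptt + 40 + rnorm(20, 0, 0.1),
                    ref_dbp = 5 / ptt + 30 + rnorm(20, 0, 0.1))
  m_inv <- ptt_fit(dat, "inverse")
  expect_equal(unname(m_inv$coef$sbp[2]), 10, tolerance = 0.05)
  # prediction arithmetic: a / PTT + b
  m_inv$coef$sbp <- c(70, 10)
  expect_equal(predict(m_inv, data.frame(PTT = 0.2))$sbp, 120)
  m_lin <- ptt_fit(dat, "linear")
  expect_length(m_lin$coef$sbp, 2L)
  m_lg <- ptt_fit(dat, "log_inv_sq")
  expect_length(m_lg$coef$sbp, 3L)
  expect_error(ptt_fit(data.frame(PTT = rep(NA_real_, 5),
                                  ref_sbp = 1:5, ref_dbp = 1:5)), "PTT")
})

test_that("fit_subject returns the fusion model plus PTT set when available", {
  co <- generate_cohort(cohort_spec(n_subjects = 1, link = "linear", seed = 5))
  tr <- co$features[co$features$set == "train", ]
  ms <- fit_subject(tr)
  expect_s3_class(ms$mpf, "mpf_model")
  expect_named(ms$ptt, c("linear", "inverse", "log_inv_sq"))
  # without PTT the baselines are absent but the fusion fits
  tr$PTT <- NA_real_
  ms2 <- fit_subject(tr)
  expect_length(ms2$ptt, 0L)
  expect_s3_class(ms2$mpf, "mpf_model")
})

test_that("model persistence round-trips through JSON", {
  co <- generate_cohort(cohort_spec(n_subjects = 1, link = "linear", seed = 6))
  tr <- co$features[co$features$set == "train", ]
  ms <- fit_subject(tr, gamma = 0.15)
  path <- withr::local_tempfile(fileext = ".json")
  write_models(ms, path)
  back <- read_models(path)
  expect_equal(back$mpf$coef, ms$mpf$coef)
  expect_equal(back$mpf$gamma, 0.15)
  expect_named(back$ptt, names(ms$ptt))
  for (v in names(ms$ptt)) {
    expect_equal(unname(back$ptt[[v]]$coef$sbp), unname(ms$ptt[[v]]$coef$sbp))
  }
  te <- co$features[co$features$set == "test", ]
  expect_equal(predict(back$mpf, te), predict(ms$mpf, te),
               ignore_attr = TRUE)
})

test_that("zero-noise linear cohorts are recovered exactly by every model", {
  co <- generate_cohort(cohort_spec(n_subjects = 2, link = "linear",
                                    ref_noise_sd = 0, seed = 8))
  for (sid in unique(co$features$subject_id)) {
    tr <- co$features[co$features$set == "train" & co$features$subject_id == sid, ]
    te <- co$features[co$features$set == "test" & co$features$subject_id == sid, ]
    m <- mpf_fit(tr)
    p <- predict(m, te)
    expect_lt(max(abs(p$sbp - te$ref_sbp)), 1e-8)
    expect_lt(max(abs(p$dbp - te$ref_dbp)), 1e-8)
    comp <- attr(p, "components")
    expect_lt(max(abs(comp$sbp - te$ref_sbp)), 1e-8)
  }
})
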