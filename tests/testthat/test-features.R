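# independent dense-grid oracle for the trapezoid mean of a beat
oracle_k <- function(f, Pd, Ps, T, n = 2e5) {
  t <- seq(0, T, length.out = n)
  y <- f(t)
  Pm <- mean((y[-1] + y[-n]) / 2)
  (Pm - Pd) / (Ps - Pd)
}

test_that("K-values match closed forms for canonical beat shapes", {
  fs <- 2500
  # symmetric triangle rising Pd -> Ps -> Pd: mean is halfway
  n <- fs  # 1 s beat
  tri <- c(seq(0, 1, length.out = n / 2), seq(1, 0, length.out = n / 2))
  fid <- list(A = which.min(tri[1:(n / 2)]), C = which.max(tri), D = round(0.75 * n))
  kv <- k_values(tri, fs, fid)
  expect_equal(unname(kv["K"]), 0.5, tolerance = 1e-3)
  # half-sine beat: K = 2 / pi
  t <- seq(0, 1 - 1 / n, length.out = n)
  hs <- 2 + 3 * sin(pi * t)
  fid2 <- list(A = 1L, C = which.max(hs), D = round(0.8 * n))
  kv2 <- k_values(hs, fs, fid2)
  expect_equal(unname(kv2["K"]), 2 / pi, tolerance = 0.005 * 2 / pi)
  # constant diastole equal to the foot value gives K2 = 0
  flatd <- c(seq(0, 1, length.out = 100), seq(1, 0, length.out = 100),
             rep(0, 200))
  fid3 <- list(A = 1L, C = 100L, D = 201L)
  expect_equal(unname(k_values(flatd, fs, fid3)["K2"]), 0, tolerance = 1e-9)
  # degenerate beat: peak not above foot
  expect_error(k_values(rep(1, 100), fs, list(A = 1L, C = 50L, D = 80L)),
               "degenerate")
})

test_that("trapezoid beat mean agrees with a dense-oversampled oracle", {
  for (seed in 1:4) {
    tpl <- beat_template(100 + 15 * seed, 65 + 8 * seed)
    b <- generate_beat(tpl, fs = 2500)
    d <- derivatives(b$ppw, 2500)
    beat <- list(ppw = b$ppw, d1 = d$d1, d2 = d$d2, fs = 2500, start = 1L)
    f <- beat_fiducials(beat)
    kv <- k_values(beat$ppw, 2500, f)
    k_or <- oracle_k(tpl$f, min(b$ppw[1:f$C]), max(b$ppw), tpl$period)
    expect_lt(abs(kv[["K"]] - k_or), 0.001)
  }
})

test_that("beat features have the right structure, units and couplings", {
  fx <- fixture_beat()
  f <- beat_fiducials(fx$beat)
  feats <- beat_features(fx$beat, f)
  expect_named(feats, c(ppw_feature_names, "PTT"))
  expect_true(all(is.finite(feats[ppw_feature_names])))
  # timing features non-negative; ratios in range
  expect_gte(feats[["TmAE"]], 0)
  expect_gte(feats[["TmBE"]], 0)
  expect_gte(feats[["TmCD"]], 0)
  expect_gt(feats[["RtTP"]], 0)
  expect_lte(feats[["RtTP"]], 1)
  expect_true(all(feats[c("K", "K1", "K2")] >= 0 & feats[c("K", "K1", "K2")] <= 1))
  # raw sums attached and consistent with the normalised features
  rs <- attr(feats, "raw_sums")
  expect_equal(unname(rs["AS"] / fx$beat$fs), unname(feats["AS"]))
  expect_equal(unname(rs["d1_AA"] / fx$beat$fs), unname(feats["d1_AA"]))
  # no R-peak paired: PTT missing
  expect_true(is.na(feats[["PTT"]]))
})

test_that("degenerate-dicrotic beats yield TmCD = 0 and RtTP = 0", {
  tpl0 <- beat_template(120, 80, dicrotic_amp = 0)
  b0 <- generate_beat(tpl0, fs = 2500)
  d <- derivatives(b0$ppw, 2500)
  beat0 <- list(ppw = b0$ppw, d1 = d$d1, d2 = d$d2, fs = 2500, start = 1L,
                raw = b0$ppw + 2)
  f0 <- beat_fiducials(beat0)
  expect_true(f0$degenerate_dicrotic)
  feats <- beat_features(beat0, f0)
  expect_identical(unname(feats["TmCD"]), 0)
  expect_identical(unname(feats["RtTP"]), 0)
  # TmAE - TmBE is the A-to-B interval by construction
  expect_equal(unname(feats["TmAE"] - feats["TmBE"]),
               (f0$B - f0$A) / 2500)
})

test_that("dimensionless features are invariant to amplitude scaling, others scale", {
  fx <- fixture_beat()
  f <- beat_fiducials(fx$beat)
  feats1 <- beat_features(fx$beat, f)
  scaled <- fx$beat
  for (nm in c("ppw", "raw", "d1", "d2")) scaled[[nm]] <- scaled[[nm]] * 3
  f2 <- beat_fiducials(scaled)
  feats3 <- beat_features(scaled, f2)
  for (nm in c("RtAmCE", "K", "K1", "K2", "RtTP", "PIR")) {
    expect_equal(feats3[[nm]], feats1[[nm]], tolerance = 1e-9)
  }
  expect_equal(feats3[["d1_PAm"]], 3 * feats1[["d1_PAm"]], tolerance = 1e-9)
  expect_equal(feats3[["AS"]], 3 * feats1[["AS"]], tolerance = 1e-9)
})

test_that("PIR uses the raw frame and is missing for non-positive feet", {
  fx <- fixture_beat()
  f <- beat_fiducials(fx$beat)
  feats <- beat_features(fx$beat, f)
  expect_equal(feats[["PIR"]],
               fx$beat$raw[f$C] / fx$beat$raw[f$A])
  # foot at or below zero in the raw frame: PIR missing, not an error
  neg <- fx$beat
  neg$raw <- neg$raw - neg$raw[f$A] - 1
  featsn <- beat_features(neg, beat_fiducials(neg))
  expect_true(is.na(featsn[["PIR"]]))
})

test_that("record-level features average beats and enforce the minimum count", {
  fs <- 500
  g <- generate_record(121, 79, fs = fs, duration = 40, noise_snr_db = Inf,
                       drift_amp = 0, seed = 31)
  rf <- record_features(g$record)
  expect_s3_class(rf, "ppw_features")
  expect_named(rf$features, c(ppw_feature_names, "PTT"))
  expect_gte(rf$n_accepted, 5)
  # extractor recovers the generator's analytic K closely
  expect_lt(abs(rf$features[["K"]] - g$truth$K), 0.01)
  # PTT recovered against the generator's coupling
  expect_lt(abs(rf$features[["PTT"]] - mean(g$truth$ptt)), 0.005)
  # record of identical beats: record vector equals the single-beat vector
  rec <- preprocess_record(g$record)
  beats <- segment_beats(rec)
  fb <- beat_features(beats[[4]], beat_fiducials(beats[[4]]))
  expect_equal(rf$features[["RtAmCE"]], unname(fb["RtAmCE"]), tolerance = 0.05)
  # too short a record: rejected with reason
  short <- pulse_record(g$record$ppw[1:(2 * fs)], fs = fs)
  expect_error(suppressWarnings(record_features(short)), "rejected")
})

test_that("feature table stacks records with metadata and missing-value bookkeeping", {
  fs <- 500
  feats <- lapply(c(11, 12), function(s) {
    g <- generate_record(120, 80, fs = fs, duration = 30, noise_snr_db = Inf,
                         drift_amp = 0, seed = s)
    g$record$subject_id <- sprintf("S%02d", s)
    record_features(g$record)
  })
  tab <- features_table(feats)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("subject_id", "n_beats", ppw_feature_names, "PTT",
                    "ref_sbp", "ref_dbp") %in% names(tab)))
  expect_equal(tab$ref_sbp, c(120, 120))
})
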