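#' Parametric beat template with analytic landmarks
#'
#' A single pulse beat is modelled as three Gaussian components in
#' normalized time — systolic wave, reflected wave and dicrotic wave — with
#' a linear edge correction so the waveform starts and ends exactly at zero
#' (clean feet for concatenation). Landmark times (foot, systolic peak,
#' dicrotic foot, dicrotic peak, first-derivative peak) are computed from
#' the continuous template on a dense grid and returned as ground truth.
#' Setting the dicrotic amplitude to zero produces the degenerate case:
#' monotone decay after the systolic peak, no dicrotic notch.
#'
#' The default morphology couplings make template parameters monotone
#' functions of blood pressure: pulse pressure scales the amplitude, higher
#' systolic pressure steepens (narrows) the systolic upstroke and advances
#' the dicrotic wave, and higher mean pressure raises the reflected-wave
#' fraction (so the waveform characteristic value K rises with pressure).
#'
#' @param sbp,dbp Blood pressure driving the morphology, mmHg.
#' @param hr Heart rate in beats per minute (sets the beat period).
#' @param dicrotic_amp Relative dicrotic amplitude; 0 gives the degenerate
#'   beat. `NULL` (default) uses the pressure-coupled value.
#' @return Object of class `"beat_template"`: component amplitudes `a`,
#'   centres `mu`, widths `sig` (normalized time), beat `period` (s), the
#'   template function `f(t)`, and `truth` (landmark times in seconds plus
#'   the analytic K-value).
#' @export
beat_template <- function(sbp = 120, dbp = 80, hr = 70, dicrotic_amp = NULL,
                          nuisance = NULL) {
  stopifnot(sbp > dbp, hr > 20, hr < 200)
  if (is.null(nuisance)) {
    nuisance <- list(a2 = 1, kd = 1, s1 = 1, dmu3 = 0, a3 = 1, sig2 = 1,
                     sig3 = 1, dmu2 = 0)
  }
  period <- 60 / hr
  s_n <- (sbp - 120) / 60          # systolic driver
  m_n <- ((sbp + 2 * dbp) / 3 - 93.3) / 40  # mean-pressure driver
  p_n <- ((sbp - dbp) - 40) / 40   # pulse-pressure driver
  amp <- 1 + 0.9 * p_n
  if (amp <= 0.1) amp <- 0.1
  a <- c(amp,
         amp * nuisance$a2 * max(0.05, 0.42 + 0.18 * m_n),
         if (is.null(dicrotic_amp))
           amp * nuisance$a3 * max(0.04, 0.15 + 0.10 * m_n)
         else amp * dicrotic_amp)
  mu <- c(0.14, 0.24 + nuisance$dmu2,
          min(0.60, max(0.40, 0.50 - 0.06 * s_n + nuisance$dmu3)))
  sig <- c(max(0.02, 0.050 * nuisance$s1 * (1 - 0.25 * s_n)),
           0.11 * nuisance$sig2, 0.035 * nuisance$sig3)
  # systolic timing scales only fractionally with heart rate (the diastole
  # absorbs most of the period change, as in real pulses): component centres
  # and widths follow (period / reference)^0.35 in absolute time
  ratio <- period / (60 / 70)
  mu <- pmin(c(0.6, 0.7, 0.8), mu * ratio^(-0.65))
  sig <- sig * ratio^(-0.65)
  # diastolic runoff: smooth-onset exponential decay raising the diastolic
  # level (waveform fullness), coupled to mean pressure
  k_d <- amp * nuisance$kd * max(0.05, 0.30 + 0.20 * m_n)
  onset <- 0.18 * ratio^(-0.65)
  raw <- function(u) {
    a[1] * exp(-(u - mu[1])^2 / (2 * sig[1]^2)) +
      a[2] * exp(-(u - mu[2])^2 / (2 * sig[2]^2)) +
      a[3] * exp(-(u - mu[3])^2 / (2 * sig[3]^2)) +
      k_d * stats::pnorm((u - onset) / 0.05) * exp(-pmax(0, u - onset) / 0.35)
  }
  f <- function(t) {
    u <- t / period
    # linear edge correction: exact zeros at u = 0 and u = 1
    raw(u) - ((1 - u) * raw(0) + u * raw(1))
  }
  tpl <- structure(list(a = a, mu = mu, sig = sig, period = period, f = f),
                   class = "beat_template")
  tpl$truth <- .template_truth(tpl)
  tpl
}

# dense-grid landmark extraction from the continuous template
.template_truth <- function(tpl) {
  n <- 20000L
  t <- seq(0, tpl$period, length.out = n)
  y <- tpl$f(t)
  d1 <- c(diff(y), 0) * (n - 1) / tpl$period
  i_peak <- which.max(y)
  t_peak <- t[i_peak]
  i_d1max <- which.max(d1[1:i_peak])
  # first local minimum after the systolic peak = dicrotic foot
  t_notch <- NA_real_; t_dpeak <- NA_real_
  post <- y[i_peak:n]
  mins <- which(diff(sign(diff(post))) > 0) + 1L
  if (length(mins) > 0L) {
    i_notch <- i_peak + mins[1] - 1L
    t_notch <- t[i_notch]
    maxs <- which(diff(sign(diff(y[i_notch:n]))) < 0) + 1L
    if (length(maxs) > 0L) t_dpeak <- t[i_notch + maxs[1] - 1L]
  }
  Pd <- min(y[1:i_peak]); Ps <- y[i_peak]
  Pm <- mean((y[-1] + y[-n]) / 2)
  list(t_foot = t[which.min(y[1:i_peak])], t_peak = t_peak,
       t_notch = t_notch, t_dpeak = t_dpeak,
       t_d1max = t[i_d1max], K = (Pm - Pd) / (Ps - Pd),
       degenerate = is.na(t_notch))
}

#' Sample one beat from a template
#'
#' @param template A [beat_template()].
#' @param fs Sampling rate, Hz.
#' @param duration Beat duration in seconds (default the template period).
#' @return List with `ppw` (samples) and `truth` (ground-truth landmark
#'   times in seconds; see [beat_template()]). When `duration` differs from
#'   the template period the template is time-dilated and the landmark times
#'   scale accordingly.
#' @export
generate_beat <- function(template, fs, duration = template$period) {
  stopifnot(inherits(template, "beat_template"), fs > 0, duration > 0)
  scale <- duration / template$period
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  ppw <- template$f(t / scale)
  truth <- template$truth
  for (nm in c("t_foot", "t_peak", "t_notch", "t_dpeak", "t_d1max")) {
    truth[[nm]] <- truth[[nm]] * scale
  }
  list(ppw = ppw, truth = truth, fs = fs)
}

#' Generate a synthetic two-channel pulse record with ground truth
#'
#' Builds a beat train whose morphology is a deterministic monotone function
#' of the driving blood pressure (see [beat_template()]), adds sinusoidal
#' baseline drift at 0.2 Hz and white Gaussian noise at a stated SNR, and —
#' unless `with_ecg = FALSE` — a synchronous ECG impulse train placed so
#' that the R-peak precedes each beat's first-derivative peak by
#' \deqn{PTT = a + b / \sqrt{SBP}}
#' (inverse-square-root coupling, so the PTT baseline models are
#' non-trivially fittable) plus small timing jitter. A constant sensor
#' offset keeps the raw-frame foot amplitude positive, as a contact pressure
#' sensor's operating point would.
#'
#' @param true_sbp,true_dbp Driving pressure, mmHg (`true_sbp > true_dbp`).
#' @param fs Sampling rate, Hz (study device rate: 2500).
#' @param duration Record length in seconds (study recordings: 60).
#' @param noise_snr_db Additive-noise SNR in dB relative to signal power;
#'   `Inf` (default) for noiseless.
#' @param drift_amp Amplitude of the 0.2 Hz baseline drift, sensor units.
#' @param hr Mean heart rate, bpm; beat-to-beat periods get multiplicative
#'   jitter `hr_jitter`.
#' @param hr_jitter Relative SD of beat-period jitter (default 0.02).
#' @param ptt_a,ptt_b PTT coupling coefficients, seconds and
#'   seconds*sqrt(mmHg).
#' @param ptt_jitter_s SD of per-beat PTT jitter in seconds (default 2 ms;
#'   use 0 for exact-recovery settings).
#' @param offset Mean sensor offset added to the PPW, sensor units.
#' @param morph_sd Relative SD of the per-record morphology nuisance
#'   (vasomotor-tone variation of the reflected/dicrotic components,
#'   independent of pressure); default 0.03, 0 disables.
#' @param gain_sd,offset_sd Log-scale SDs of the per-record sensor gain and
#'   offset (the contact-pressure sensor is re-applied for every record, so
#'   its coupling efficiency varies); defaults 0.02 and 0.05.
#' @param with_ecg Logical; generate the ECG channel?
#' @param seed Optional integer seed (sets the RNG locally).
#' @return List with `record` (a [pulse_record()] carrying
#'   `ref_sbp`/`ref_dbp` equal to the true pressure) and `truth`: absolute
#'   landmark times (`feet`, `peaks`, `notches`, `dpeaks`, `d1peaks`,
#'   `r_times`, all seconds), per-beat `ptt`, the analytic `K`, and the
#'   template.
#' @export
generate_record <- function(true_sbp, true_dbp, fs = 2500, duration = 60,
                            noise_snr_db = Inf, drift_amp = 0, hr = 70,
                            hr_jitter = 0.02, ptt_a = 0.10, ptt_b = 1.4,
                            ptt_jitter_s = 0.002, offset = 2,
                            morph_sd = 0.03, gain_sd = 0.02, offset_sd = 0.05,
                            with_ecg = TRUE, seed = NULL) {
  stopifnot(true_sbp > true_dbp)
  if (!is.null(seed)) set.seed(seed)
  # relative scales chosen so that, across the 21-feature set, morphological
  # variability disperses single-feature predictions much more than it
  # shifts their average (vasomotor variation is largely uninformative
  # about pressure)
  nuis <- list(a2 = exp(stats::rnorm(1, 0, morph_sd)),
               kd = exp(stats::rnorm(1, 0, 0.75 * morph_sd)),
               s1 = exp(stats::rnorm(1, 0, 0.5 * morph_sd)),
               dmu3 = stats::rnorm(1, 0, 0.05 * morph_sd),
               a3 = exp(stats::rnorm(1, 0, morph_sd)),
               sig2 = exp(stats::rnorm(1, 0, 1.25 * morph_sd)),
               sig3 = exp(stats::rnorm(1, 0, 0.75 * morph_sd)),
               dmu2 = stats::rnorm(1, 0, 0.03 * morph_sd))
  hr <- hr + stats::rnorm(1, 0, 0.5)
  gain <- exp(stats::rnorm(1, 0, gain_sd))
  off <- offset * exp(stats::rnorm(1, 0, offset_sd))
  tpl <- beat_template(true_sbp, true_dbp, hr = hr, nuisance = nuis)
  n <- round(duration * fs)
  ppw <- numeric(n)
  feet <- peaks <- notches <- dpeaks <- d1peaks <- r_times <- numeric(0)
  ptt0 <- ptt_a + ptt_b / sqrt(true_sbp)
  ptts <- numeric(0)
  t0 <- 0
  while (TRUE) {
    per <- tpl$period * (1 + stats::rnorm(1, 0, hr_jitter))
    if (t0 + 0.05 >= duration) break
    b <- generate_beat(tpl, fs, duration = per)
    i0 <- round(t0 * fs) + 1L
    i1 <- min(n, i0 + length(b$ppw) - 1L)
    if (i1 > i0) ppw[i0:i1] <- ppw[i0:i1] + b$ppw[1:(i1 - i0 + 1L)]
    feet <- c(feet, t0 + b$truth$t_foot)
    peaks <- c(peaks, t0 + b$truth$t_peak)
    notches <- c(notches, t0 + b$truth$t_notch)
    dpeaks <- c(dpeaks, t0 + b$truth$t_dpeak)
    d1peaks <- c(d1peaks, t0 + b$truth$t_d1max)
    ptt_i <- ptt0 + if (ptt_jitter_s > 0) stats::rnorm(1, 0, ptt_jitter_s) else 0
    ptts <- c(ptts, ptt_i)
    r_times <- c(r_times, t0 + b$truth$t_d1max - ptt_i)
    t0 <- t0 + per
  }
  tt <- (0:(n - 1)) / fs
  sig_pow <- stats::var(ppw)
  if (drift_amp > 0) {
    ppw <- ppw + drift_amp * sin(2 * pi * 0.2 * tt + stats::runif(1, 0, 2 * pi))
  }
  if (is.finite(noise_snr_db)) {
    ppw <- ppw + stats::rnorm(n, 0, sqrt(sig_pow / 10^(noise_snr_db / 10)))
  }
  ppw <- gain * ppw + off
  ecg <- NULL
  if (with_ecg) {
    ecg <- numeric(n)
    keep <- r_times > 0 & r_times < duration
    r_times <- r_times[keep]
    for (tr in r_times) {
      # narrow Gaussian R spike (sd 8 ms)
      lo <- max(1L, round((tr - 0.04) * fs)); hi <- min(n, round((tr + 0.04) * fs))
      idx <- lo:hi
      ecg[idx] <- ecg[idx] + exp(-((idx - 1) / fs - tr)^2 / (2 * 0.008^2))
    }
    if (is.finite(noise_snr_db)) {
      ecg <- ecg + stats::rnorm(n, 0, sqrt(stats::var(ecg) / 10^(noise_snr_db / 10)))
    }
  }
  record <- pulse_record(ppw, fs = fs, ecg = ecg,
                         ref_sbp = true_sbp, ref_dbp = true_dbp)
  list(record = record,
       truth = list(feet = feet, peaks = peaks, notches = notches,
                    dpeaks = dpeaks, d1peaks = d1peaks, r_times = r_times,
                    ptt = ptts, K = tpl$truth$K, template = tpl))
}

#' Specify a synthetic multi-day cohort
#'
#' Describes a cohort following the multi-day calibration/test protocol: on
#' the training day (day 0) each subject contributes `n_train` records
#' evenly spread between 9:00 and 17:00; on each test day (defaults 1, 3, 6
#' and 8 days after calibration) 4 records at random times. Subjects are
#' drawn from normotensive, hypertensive and hypotensive strata. True
#' pressure follows a per-subject trajectory: baseline + circadian swing +
#' day-to-day drift + record-level variation, sized so the per-subject
#' dynamic range is realistic (about 25 mmHg systolic, 18 diastolic).
#'
#' Two feature links are available. `"waveform"` (default) synthesises full
#' two-channel records whose morphology is coupled to pressure and extracts
#' features through the measurement pipeline. `"linear"` writes feature
#' values directly as exact affine functions of the systolic driver (with
#' diastolic pressure affine in systolic), the idealised setting in which
#' every univariate calibration — and hence the fusion — recovers pressure
#' exactly when reference noise is off.
#'
#' @param n_subjects Number of subjects (default 5).
#' @param strata Named proportions for `normal`, `hyper`, `hypo` strata.
#' @param n_train Training records on day 0 (protocol floor: 16).
#' @param test_days Integer vector of test days (default `c(1, 3, 6, 8)`).
#' @param n_test_per_day Records per test day (default 4).
#' @param circadian_amp Circadian systolic amplitude, mmHg (default 8).
#' @param day_drift_sd Day-to-day systolic drift SD, mmHg (default 4).
#' @param record_sd Record-level true-pressure variation SD, mmHg (default 3).
#' @param ref_noise_sd SD of cuff-device reference noise, mmHg (default 2;
#'   set 0 for exact-recovery settings).
#' @param noise_snr_db Waveform SNR in dB (default 25; `Inf` = clean).
#' @param morph_sd,gain_sd,offset_sd Per-record nuisance variability of the
#'   waveform generator (see [generate_record()]).
#' @param drift_amp Baseline-drift amplitude in sensor units (default 0.3).
#' @param fs,duration Sampling rate (Hz) and record length (s).
#' @param link `"waveform"` or `"linear"`.
#' @param seed Integer seed; makes the whole cohort reproducible.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 5,
                        strata = c(normal = 0.72, hyper = 0.12, hypo = 0.16),
                        n_train = 16, test_days = c(1, 3, 6, 8),
                        n_test_per_day = 4,
                        circadian_amp = 8, day_drift_sd = 4, record_sd = 3,
                        ref_noise_sd = 2, noise_snr_db = 25, drift_amp = 0.3,
                        morph_sd = 0.03, gain_sd = 0.02, offset_sd = 0.05,
                        fs = 2500, duration = 60,
                        link = c("waveform", "linear"), seed = 1L) {
  link <- match.arg(link)
  stopifnot(n_subjects >= 1, n_train >= 2, all(test_days >= 1))
  structure(list(n_subjects = n_subjects, strata = strata, n_train = n_train,
                 test_days = test_days, n_test_per_day = n_test_per_day,
                 circadian_amp = circadian_amp, day_drift_sd = day_drift_sd,
                 record_sd = record_sd, ref_noise_sd = ref_noise_sd,
                 noise_snr_db = noise_snr_db, drift_amp = drift_amp,
                 morph_sd = morph_sd, gain_sd = gain_sd,
                 offset_sd = offset_sd,
                 fs = fs, duration = duration, link = link,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# stratum baseline means (mmHg)
.stratum_bp <- list(normal = c(sbp = 120, dbp = 75),
                    hyper = c(sbp = 150, dbp = 92),
                    hypo = c(sbp = 95, dbp = 60))

# deterministic linear-link coefficients for the 21 features + PTT
.linear_link_coefs <- function() {
  j <- seq_along(ppw_feature_names)
  list(intercept = j, slope = 0.8 + 0.4 * sin(j))
}

#' Generate a multi-day synthetic cohort
#'
#' Draws the per-record true and reference pressures for every subject and
#' session of the protocol in [cohort_spec()]. Waveform records are not
#' materialised here (a full cohort holds hours of 2500 Hz signal); instead
#' the manifest stores a per-record seed and [cohort_record()] regenerates
#' any record deterministically. Under the `"linear"` link the feature table
#' is computed directly and returned in `$features`.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `"ppw_cohort"`: `manifest` (one row per record:
#'   subject, stratum, set, day, hour, true/reference pressures, seed),
#'   `features` (data frame under the linear link, otherwise `NULL`), and
#'   `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  strata <- rep(names(spec$strata),
                times = diff(round(cumsum(c(0, spec$strata)) * spec$n_subjects)))
  if (length(strata) < spec$n_subjects) {
    strata <- c(strata, rep("normal", spec$n_subjects - length(strata)))
  }
  rows <- list()
  for (s in seq_len(spec$n_subjects)) {
    base <- .stratum_bp[[strata[s]]]
    sbp0 <- base["sbp"] + stats::rnorm(1, 0, 6)
    dbp0 <- base["dbp"] + stats::rnorm(1, 0, 4)
    days <- c(0, spec$test_days)
    day_off <- stats::setNames(c(0, stats::rnorm(length(spec$test_days), 0,
                                                 spec$day_drift_sd)),
                               as.character(days))
    for (d in days) {
      is_train <- d == 0
      nrec <- if (is_train) spec$n_train else spec$n_test_per_day
      hours <- if (is_train) seq(9, 17, length.out = nrec)
               else sort(stats::runif(nrec, 9, 17))
      for (h in hours) {
        circ <- spec$circadian_amp * sin(pi * (h - 9) / 8)
        sbp <- sbp0 + day_off[[as.character(d)]] + circ +
          stats::rnorm(1, 0, spec$record_sd)
        if (spec$link == "linear") {
          dbp <- 0.55 * sbp + (dbp0 - 0.55 * sbp0)
        } else {
          dbp <- dbp0 + 0.45 * (sbp - sbp0) + stats::rnorm(1, 0, 1.5)
        }
        if (sbp - dbp < 15) dbp <- sbp - 15
        ref_sbp <- sbp + stats::rnorm(1, 0, spec$ref_noise_sd)
        ref_dbp <- dbp + stats::rnorm(1, 0, spec$ref_noise_sd)
        if (ref_sbp <= ref_dbp) ref_sbp <- ref_dbp + 1
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%02d", s), stratum = strata[s],
          set = if (is_train) "train" else "test", day = d, hour = h,
          true_sbp = sbp, true_dbp = dbp,
          ref_sbp = ref_sbp, ref_dbp = ref_dbp,
          record_seed = sample.int(2^31 - 1, 1))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  features <- NULL
  if (spec$link == "linear") {
    cfs <- .linear_link_coefs()
    fmat <- outer(manifest$true_sbp, cfs$slope) +
      matrix(cfs$intercept, nrow(manifest), 21, byrow = TRUE)
    colnames(fmat) <- ppw_feature_names
    features <- cbind(
      manifest[, c("subject_id", "set", "day", "hour")],
      data.frame(n_beats = NA_integer_),
      as.data.frame(fmat),
      data.frame(PTT = 0.28 - 8e-4 * manifest$true_sbp,
                 ref_sbp = manifest$ref_sbp, ref_dbp = manifest$ref_dbp)
    )
  }
  structure(list(manifest = manifest, features = features, spec = spec),
            class = "ppw_cohort")
}

#' @export
print.ppw_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<ppw_cohort> %d subjects, %d records (%d train / %d test), link '%s'\n",
              length(unique(m$subject_id)), nrow(m), sum(m$set == "train"),
              sum(m$set == "test"), x$spec$link))
  invisible(x)
}

#' Regenerate one cohort record deterministically
#'
#' @param cohort A `"ppw_cohort"` with a waveform link.
#' @param i Manifest row index.
#' @return As [generate_record()], with the manifest's reference pressures
#'   attached to the record.
#' @export
cohort_record <- function(cohort, i) {
  stopifnot(inherits(cohort, "ppw_cohort"))
  row <- cohort$manifest[i, ]
  sp <- cohort$spec
  out <- generate_record(row$true_sbp, row$true_dbp, fs = sp$fs,
                         duration = sp$duration,
                         noise_snr_db = sp$noise_snr_db,
                         drift_amp = sp$drift_amp,
                         morph_sd = sp$morph_sd, gain_sd = sp$gain_sd,
                         offset_sd = sp$offset_sd,
                         hr = 62 + 0.1 * (row$true_sbp - 110),  # mild chronotropic coupling
                         seed = row$record_seed)
  out$record$subject_id <- row$subject_id
  out$record$session_time <- sprintf("day%02d_%05.2fh", row$day, row$hour)
  out$record$ref_sbp <- row$ref_sbp
  out$record$ref_dbp <- row$ref_dbp
  out
}

#' Write a cohort to disk as signal files, sidecars and a manifest
#'
#' Emits one delimited signal file plus JSON sidecar per record and a
#' `manifest.csv`. Under the linear link only the feature table and manifest
#' are written.
#'
#' @param cohort A `"ppw_cohort"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest with file paths added.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cohort$manifest
  if (cohort$spec$link == "linear") {
    utils::write.csv(cohort$features, file.path(dir, "features.csv"),
                     row.names = FALSE)
  } else {
    m$signal_file <- sprintf("rec%04d.csv", seq_len(nrow(m)))
    m$sidecar_file <- sprintf("rec%04d.json", seq_len(nrow(m)))
    for (i in seq_len(nrow(m))) {
      rec <- cohort_record(cohort, i)$record
      write_record(rec, file.path(dir, m$signal_file[i]),
                   file.path(dir, m$sidecar_file[i]))
    }
  }
  utils::write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}
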