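---
title: "Pulse-wave blood-pressure estimation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-wave blood-pressure estimation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppwbp)
```

## The estimation problem

A contact pressure sensor at the radial artery records the pressure pulse
wave (PPW). Its morphology carries information about arterial pressure:
higher pressure steepens and amplifies the systolic upstroke, raises the
waveform-fullness K-value, and advances the dicrotic wave; the transit time
from the ECG R-peak to pulse arrival (PTT) shortens. `ppwbp` turns these
observations into per-subject calibration models: each of 21 morphological
features is linearly regressed on reference cuff pressure over one
calibration day, and at test time the 21 single-feature predictions are
fused.

The fusion estimator is the symmetrically trimmed mean of the ordered
predictions minus their (untrimmed, n−1) standard deviation,

$$\mathrm{MPF} = \frac{F_{(g+1)} + \cdots + F_{(N-g)}}{N-2g} - \mathrm{SD}(F_1,\dots,F_N), \qquad g = \lfloor \gamma N \rfloor,\; N = 21 .$$

The trimmed mean gives robustness against single-feature failures (up to
`g` gross outliers per tail leave it unchanged — a property the test suite
asserts); the SD term penalises ensemble disagreement, pulling the estimate
down when the features are inconsistent. Calibration is strictly per
subject: the models capture an individual's feature–pressure relationship
and are not transferable.

Assumptions worth stating plainly: (i) each feature–pressure link is
approximately affine over a subject's pressure range (a few tens of mmHg);
(ii) the calibration day's range brackets the test conditions — univariate
least squares extrapolates linearly outside it; (iii) all 21 features are
available, so records must show a measurable (or explicitly degenerate)
dicrotic wave and stable derivative landmarks.

## Pipeline parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff_hz` | 50 | Hz | zero-phase low-pass (4th-order Butterworth, forward–backward) on both channels |
| `baseline_max_hz` | 0.5 | Hz | upper edge of the wavelet-approximation band subtracted as baseline |
| `dicrotic_window` | (0.15, 0.60) | fraction of beat | search window after the systolic peak for the dicrotic foot/peak |
| `onset_frac` | 0.10 | fraction of peak | threshold defining derivative onset points `F`, `N` |
| `gamma` | 0.1 | — | trimming fraction; `g = 2` of 21 predictions trimmed per tail |
| `cp_boundary` | closed | — | an error exactly at 5/10/15 mmHg counts as within |
| `ttest_var_equal` | FALSE | — | Welch two-sample t-test between model errors |
| `min_beats` | 5 | beats | minimum accepted beats for a record-level feature vector |

The 50 Hz cutoff and the sub-0.5 Hz baseline band reflect standard pulse
practice: pulse morphology lives below roughly 15 Hz, wander (respiration,
contact-pressure drift) below 0.5 Hz. Zero-phase application matters
because every downstream feature is a timing measurement. The dicrotic
window brackets physiologic dicrotic timing and, together with the
first-crossing rule, makes the detection deterministic when several late
reflections exist. `gamma` trades robustness against efficiency; 0.1 keeps
17 of 21 predictions.

## Numerical choices

* **Baseline removal** is an à trous (stationary-wavelet) approximation
  with the db8 scaling filter, decomposed to the level whose band falls
  below 0.5 Hz. Two implementation details decide its quality. Each stage
  applies the filter forward and time-reversed with alignment centres
  summing to filter length + 1, making the stage exactly zero-phase — db8
  is strongly asymmetric, and a one-sided cascade would shift the baseline
  estimate by seconds at deep levels. Second, the record is extended past
  the deepest filter span before decomposing: the sub-Hz component is
  continued by a Yule–Walker autoregressive forecast (stable poles, so the
  extension can only decay toward the mean) and the remainder by even
  reflection; boundary artefacts then fall outside the data. The cascade
  runs on a ≥ 128 Hz decimated grid (the baseline is sub-0.5 Hz) and is
  splined back, which changes nothing measurable and keeps preprocessing
  fast. The suite verifies ≥ 95 % removal of 0.2 Hz drift energy, ≤ 2 %
  per-beat morphology distortion on interior beats, and idempotence.
* **Derivatives** are 5-point central differences after a double-pass 20 ms
  moving average. The smoothing is not cosmetic: differencing amplifies
  in-band noise as frequency squared, and at 2500 Hz the second derivative
  of an unsmoothed record is noise-dominated even after the 50 Hz low-pass,
  while the smoother distorts sub-15 Hz derivative content by under 2 %.
* **Beat feet** are the last point before each systolic upstroke at which
  the first derivative has fallen below 3 % of the upstroke peak. A plain
  window minimum is ambiguous on flat diastolic tails, where residual
  sub-mmHg ripple moves it by tens of milliseconds.
* **Ties** in any argmax are broken to the first index. Degenerate inputs
  follow explicit rules: a beat with no interior maximum, or whose
  derivative landmarks cannot all be found, is flagged unusable (with a
  reason) rather than guessed; a missing dicrotic wave is *not* an error —
  the fallback sets `D = E` at the first-derivative maximum inside the
  window, flags the beat `degenerate_dicrotic`, and the features `TmCD`
  and `RtTP` are 0 by definition.
* **PIR** is computed on the filtered but *not* baseline-removed signal:
  after detrending, foot amplitudes hover near zero and the printed
  peak-to-foot ratio is numerically meaningless. The raw frame requires a
  positive foot amplitude; otherwise PIR is reported missing and excluded
  from that beat's average.
* **K-value bounds**: the systolic/diastolic sub-means `K1`/`K2` integrate
  over `[0, t_D]` and `[t_D, T]`, with the dicrotic foot as the
  systole/diastole boundary and the trapezoid rule as quadrature (the suite
  checks triangle and half-sine closed forms and a dense-grid oracle).
* **Eq.-style conventions in the fusion**: `g = ⌊γN⌋` makes the trim count
  integral for any `γ ∈ [0, 0.5)`; the subtracted SD uses the n−1
  denominator, consistent with the error-SD definition used in evaluation;
  the SD is computed over all 21 predictions (untrimmed), as defined.
* **Grading conventions**: BHS thresholds are strict inequalities, with the
  C-grade triple (40/65/85) from the BHS standard; cumulative percentages
  use closed intervals; the AAMI rule is read as `|MD| ≤ 5` and `SD ≤ 8`
  inclusive.

## The synthetic generator

`generate_record()` builds each beat from three Gaussian components
(systolic, reflected, dicrotic) plus a smooth-onset exponential diastolic
runoff, with a linear edge correction so beats start and end exactly at
zero. Landmark times and the analytic K-value are extracted from the
continuous template on a dense grid and returned as ground truth. Pressure
couples to morphology monotonically: pulse pressure scales amplitude,
systolic pressure narrows the upstroke and advances the dicrotic wave, mean
pressure raises the reflected-wave fraction and diastolic fullness. Beat
timing scales only fractionally with heart rate (exponent 0.35), as in real
pulses, where diastole absorbs most of a period change; heart rate itself
gets a mild chronotropic coupling to pressure. The ECG channel is an
impulse train placed so that per-beat PTT follows an inverse-square-root
law in systolic pressure — qualitatively the Moens–Korteweg behaviour — so
the three PTT baselines are non-trivially fittable.

Nuisance realism, all per-record and seeded: morphology scatter on the
reflected/dicrotic parameters (relative SD 0.03 across eight template
dimensions, scales set from a measured sensitivity analysis so that the
scatter disperses single-feature predictions far more than it shifts their
average), sensor gain and offset variation (log-SD 0.02 and 0.05 — a
contact sensor is re-applied for every record), ±0.5 bpm heart-rate
scatter, 2 ms PTT jitter, 0.2 Hz sinusoidal baseline drift, and additive
white noise at a stated SNR. Reference readings can carry Gaussian cuff
error (σ = 2 mmHg by default).

`generate_cohort()` arranges records into the multi-day protocol: per
subject, 16 calibration records spread over 9:00–17:00 on day 0, then 4
records on each of days 1, 3, 6 and 8. True pressure follows baseline +
circadian swing (8 mmHg systolic amplitude) + day-to-day drift (SD 4 mmHg)
+ record-level variation (SD 3 mmHg), sized to give per-subject dynamic
ranges around 25 mmHg systolic / 18 mmHg diastolic; subjects draw from
normotensive/hypertensive/hypotensive strata (0.72/0.12/0.16). Waveform
records are not materialised up front — the manifest stores one seed per
record and `cohort_record()` regenerates any record bit-identically.

Two feature links exist. The default `"waveform"` link synthesises full
records and extracts features through the measurement pipeline. The
`"linear"` link writes features directly as exact affine functions of the
systolic driver (with diastolic pressure affine in systolic), the idealised
setting in which every univariate calibration — and hence the fusion —
must recover pressure to machine precision when reference noise is off;
the suite asserts exactly that.

What the generator does **not** emulate: motion artefacts, arrhythmic or
ectopic beats, sensor saturation, the age- and stiffness-dependence of
dicrotic visibility, and — most importantly — the biological diversity of
feature–pressure links. All 21 features derive from one low-dimensional
morphological state, so their errors are far more correlated than in real
cohorts, and a handful of features are nearly noise-free proxies of the
driving pressure. Passing tests therefore demonstrate correctness of the
algorithms and calibration machinery, not clinical-grade accuracy on real
subjects.

## Design choices where the design was open

* **Filter realisation**: zero-phase (forward–backward) 4th-order
  Butterworth. A causal filter would shift fiducial timing by
  frequency-dependent amounts.
* **Wavelet family/level**: db8, level from the 0.5 Hz band rule; db8's
  16-tap support is long enough for a smooth sub-Hz approximation and short
  enough to keep the edge-extension span manageable.
* **Dicrotic search origin**: the search runs after the systolic peak `C`.
  The landmark definitions label the foot `A`, yet the dicrotic wave
  physiologically follows the peak; searching after `C` is the only
  reading consistent with both the morphology and the published landmark
  figure.
* **Onset definition**: derivative onsets `F`/`N` use a 10 %-of-peak
  threshold, the common pulse-wave-analysis convention; exposed as
  `onset_frac`.
* **`γ` default 0.1**: trims two predictions per tail — enough to reject
  the occasional unstable second-derivative feature without discarding
  real information. The published description of the estimator leaves `γ`
  unspecified; 0.1 is this package's choice, exposed as config.
* **Second-derivative slope features**: the d2 ascending/descending slopes
  divide the a-wave amplitude by very short intervals and are intrinsically
  the noisiest of the 21 features (the interval endpoints ride on argmax
  decisions that can toggle between near-equal humps). A first-major-peak
  alternative was evaluated and measured worse end-to-end, so the plain
  argmax stands; the fusion's trimming is what absorbs these features.
* **Sum-type features** (`AS`, `d1_AA`, `d2_AA`) are defined as printed —
  discrete sums, not slopes. They are stored normalised by the sampling
  rate (the raw sums are attached as an attribute) so their values are
  rate-independent; the models consume the normalised form.
* **t-test flavour**: Welch by default; the pooled-variance form is one
  flag away.

## Problem sizes used by the test and acceptance suites

Unit tests run single records of 8–60 s at 250–2500 Hz. The acceptance
suite uses 500 single beats at 2500 Hz for landmark recovery; a
five-subject linear-link cohort for exact recovery; three five-subject
waveform cohorts at 2500 Hz / 60 s (16 + 16 records per subject) for the
noisy-cohort checks; and 10⁴ random 21-vectors for the fusion oracle. The
acceptance script simulates one five-subject waveform cohort. These sizes
are the package's choice of a desk-scale replica of the study protocol
(which enrolled 65 subjects over five days).

## Known limitations

* The fusion weighs all 21 features equally. When feature precisions are
  heterogeneous — as they inevitably are in synthetic cohorts, and
  plausibly in real ones — an inverse-variance weighting would dominate it;
  the equal-weight estimator is implemented because it is the method under
  study. Its subtracted-SD term also biases estimates downward by the mean
  ensemble disagreement.
* Univariate calibrations extrapolate linearly outside the calibration
  day's pressure range.
* Records without ECG lose only PTT and its baselines; records whose beats
  lack usable landmarks are rejected with per-record reasons rather than
  imputed.
* The BHS/AAMI machinery grades pooled errors; it does not implement the
  full per-subject device-validation protocols of those standards.
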