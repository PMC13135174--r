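---
title: "Grading coronary stenosis from diastolic heart sounds: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading coronary stenosis from diastolic heart sounds: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Turbulent flow through a stenosed left anterior descending (LAD) coronary
artery radiates a faint murmur in early diastole, when coronary flow velocity
peaks. The murmur's energy is concentrated above 150 Hz, while the bulk of
the heart-sound signal (valve closure sounds S1 and S2, chest-wall rumble)
lives below. `pcgewt` quantifies this by decomposing a fixed early-diastolic
window into three spectral modes with a Meyer-type empirical wavelet
transform (EWT) and measuring each mode's spectral energy:

* band 1: 0–150 Hz, energy `e(1)` — valve-sound tails and low-frequency
  background; carries no stenosis ordering,
* band 2: 150–500 Hz, energy `e(2)` — the primary murmur band,
* band 3: >500 Hz, energy `e(3)` — the murmur's high tail.

`e(2)` and `e(3)` increase monotonically with stenosis severity; the ratios
`P1 = e2/e1` and `P2 = e3/e1` normalize out recording gain. All five
features feed an RBF-kernel SVM and a gradient-boosted tree classifier that
grade stenosis as mild (<50%), moderate (50–75%, boundaries inclusive) or
severe (>75%).

# Pipeline stages and their parameters

## Preprocessing

Records are resampled to 2000 Hz (rational-factor polyphase resampling with
a windowed-sinc anti-alias filter), normalized per record so the amplitude
range is [−1, 1], and denoised by wavelet thresholding: a 3-level sym3
decomposition in which each detail band `CD_j` is soft-thresholded at the
universal threshold

```
beta_j = sigma_j * sqrt(2 * ln N_j),   sigma_j = median(|CD_j|) / 0.6745,
```

with `N_j` the coefficient count of level j and the approximation band left
untouched. Soft thresholding is a convention choice (smoother
reconstructions); "log" is the natural logarithm, the standard
universal-threshold reading.

**Numerical choice — boundary handling.** The discrete wavelet transform is
periodized (the signal is zero-padded to a multiple of `2^J`), because the
orthonormal sym3 pair only gives exact perfect reconstruction under
periodization; with symmetric extension an orthogonal basis is not
perfectly reconstructing. Reconstruction error is below 1e−10 and the
transform is energy-preserving, which the tests assert directly.

**Known limitation.** sym3 is a short filter with wide spectral
transitions: a tone within roughly half an octave of a detail-band edge
leaks into that band and thresholding then distorts it slightly. This is
inherent to the stated basis, not to the implementation.

## Segmentation

S2 candidates are envelope peaks of the high-pass-filtered signal. The
nominal 200–2000 Hz detection band is realized as a 200 Hz high-pass
(2000 Hz sampling puts Nyquist at 1000 Hz). The envelope is the magnitude
of the analytic signal smoothed by a 20 ms moving average; peaks must
exceed 30% of the envelope's 95th percentile and be 200 ms apart. S1/S2
disambiguation uses ECG R-peak gating when R times are available (the peak
0.25–0.55 of the RR interval after each R peak is S2); otherwise the member
of the alternating peak train followed by the longer gap is S2 (diastole is
longer than systole). The S2 end is the first time the envelope falls below
10% of the S2 peak envelope.

The analysis window is fixed: 100 ms after the S2 end, 128 ms long
(256 samples), i.e. 100–228 ms post-S2 — early diastole, where coronary
flow velocity peaks, clear of the valve sounds. Windows that run past the
record end, or into the next S1 onset when S1 times are known, are dropped;
the first 10 valid windows per record are kept.

## The empirical wavelet transform

Band boundaries are fixed at 150 and 500 Hz (mapped to radians/sample as
`w = pi * f / (fs/2)`), not estimated from the spectrum: the bands encode
prior physiology, and config supports the 120/450 and 180/550 Hz
sensitivity variants. Transitions have constant half-width `tau = 0.1*pi`
and are shaped by `beta(x) = x^2(3−2x)`, which satisfies
`beta(x) + beta(1−x) = 1`, so the three squared responses sum to one at
every frequency — a tight frame.

**Design decision — reconstruction convention.** Two desiderata compete:
exact additive reconstruction needs responses summing to 1, while the Meyer
construction makes *squared* responses sum to 1. The package adopts the
standard tight-frame resolution: `ewt_decompose()` produces analysis modes
`m_n = IFFT(H_n · X)` whose energies partition the segment energy exactly
(Parseval), and `ewt_reconstruct()` performs frame synthesis — it applies
the same filters once more and sums, returning the input to machine
precision since `sum_n H_n^2 = 1`. The plain element-wise sum of analysis
modes is only an approximation (it differs in the transition bands);
`ewt_reconstruct()` on a bare matrix of hand-built modes falls back to that
element-wise sum.

Segments are zero-padded to `nfft = 1024` (4× padding for a 256-sample
window) for a finer frequency grid. Mode energies are computed on the
padded spectra, where Parseval holds exactly; the truncated time-domain
modes are what the user sees. The DC bin belongs to mode 1 and the Nyquist
bin to mode 3.

## Features

Energies use the Parseval convention: the squared magnitude spectrum is
scaled so its full-range sum equals `sum(x^2)/fs`, giving units of V²·s for
a dimensionless normalized amplitude. Each `e(n)` integrates mode n's
spectrum over the *full* grid rather than hard band cutoffs: the filters
already confine each mode to its nominal band, and this is what makes
`e1 + e2 + e3` equal the segment energy to machine precision. In the
transition zones energy is split smoothly between adjacent modes; a tone at
100 Hz, for instance, contributes ~94% to `e(1)` and ~6% to `e(2)`.
The upper limit of band 3 is Nyquist (1000 Hz at `fs` 2000); a nominal
2000 Hz upper edge is not realizable at this rate.

Features are standardized to zero mean and unit variance using training-set
statistics only. No feature selection is performed: all five features go to
the classifiers even though `e(1)` and `P1` are not monotone in stenosis.

## Statistics

Group comparisons are rank-based: Mann–Whitney U (exact enumeration for at
most 8 per side without ties, otherwise a tie-corrected normal
approximation with continuity correction) and Kruskal–Wallis H with tie
correction, gated by a Shapiro–Wilk normality check (delegated to
`stats::shapiro.test`). AUC comparison between classifiers uses the paired
DeLong test via structural components, applied per class one-vs-rest with
no multiplicity correction (none is conventional here; this is logged).
Identical score vectors are reported as exact equality (z = 0, p = 1)
rather than 0/0.

## Classification

Splits are participant-wise: all 10 segments of a participant land on one
side. CV folds for tuning are additionally stratified by class and grouped
by participant — stricter than plain stratification, preventing
segment-level leakage. The SVM (RBF kernel) is trained by a derandomized
SMO solver on a grid spanning C in 0.1–10 and gamma in 0.001–0.1 including
(C = 1, gamma = 0.01); the boosted-tree model is a second-order softmax
booster (exact greedy splits, shrinkage, per-round row subsampling,
L2 leaf penalty 1.0, min hessian 1.0) tuned over 100–500 estimators,
learning rate 0.01–0.1, depth 3–7, subsample 0.7–1.0 including
(300, 0.05, 5, 0.8). Both learners are implemented in compiled code inside
the package because no SVM or boosting library is part of the supported
environment; both are deterministic given the configured seed. SVM ROC
scores are one-vs-rest decision values; boosted-tree scores are softmax
probabilities.

# The synthetic cohort generator

No public recordings exist for this problem, so `simulate_cohort()`
generates a labeled stand-in cohort whose *statistical structure* matches
what the clinical analysis relies on:

* 75 participants in seven stenosis groups (10/10/10/15/10/10/10) spanning
  0, 30, 40–50, 50–60, 70–75, 85 and 90–95 percent, 10 analyzable diastoles
  each (14 cycles are simulated so 10 survive extraction);
* cardiac cycles at 75 ± 5 bpm (physiologic resting default; per-cycle
  jitter), S1/S2 as Gaussian-enveloped tone bursts (60/90 Hz centers,
  70/60 ms envelopes, amplitudes 1.0/0.8) each carrying a weaker 220/250 Hz
  "click" component — valve closures are mildly broadband, and the click is
  what survives the 200 Hz detection high-pass;
* a diastolic murmur: band-limited (150–700 Hz) Gaussian noise occupying
  60–300 ms after the S2 end, so the 100–228 ms analysis window sits fully
  inside it. Its RMS amplitude is `murmur_amp_30 * (stenosis/30)^1.5` —
  zero for a normal subject, strictly increasing — with 20% lognormal
  cycle-to-cycle jitter (the true within-patient variability is
  unreported; this is a stand-in);
* a stenosis-independent low-frequency background ("rumble", 15–80 Hz,
  RMS 0.015, 30% lognormal between-participant jitter). It dominates
  `e(1)` so band-1 energy carries no stenosis ordering, as observed
  clinically; it is part of the noise model, so the "silent diastole"
  invariant is checked with it disabled;
* white measurement noise at a configurable SNR, default 50 dB (a
  high-SNR chest sensor in a quiet room; S2 detection tolerates 20 dB).

**Calibration.** `murmur_amp_30 = 7e-3` was fitted once, through the full
pipeline (denoising included, which shrinks weak murmur coefficients
nonlinearly), so that the cohort-mean `e(2)` of 30%-stenosis participants
lands at ~1e-6 V²·s — the documented anchor. The constant lives in
`sim_params()` and is not revisited.

**What a green test does not establish.** The generator reproduces event
timing, band structure, monotone energy growth and participant-level
variability; it does not model hemodynamics, respiration, motion artifacts,
arrhythmia, sensor coupling or real murmur spectra. Classification accuracy
on this cohort (~0.8 with either learner) therefore validates the
*pipeline machinery* — leakage-free splitting, feature informativeness,
calibrated evaluation — not clinical performance; the clinical accuracy and
AUC figures quoted for real cohorts are not reproducible from synthetic
data, and the tests instead pin chance-level behavior when the murmur is
silenced and clearly above-chance behavior with it present.

# Degenerate inputs and tie-breaks

* All-zero records: normalization errors out; silent records yield zero S2
  events (logged, not fatal).
* Two S2 candidates within 200 ms: the larger envelope peak wins.
* `e1 = 0`: ratios are flagged `NA` and the row is excluded with a warning.
* Zero-variance features abort standardization naming the feature.
* Grid-search ties prefer the earliest grid point (smallest C, then
  smallest gamma; fewest estimators first for the booster).
* Class boundaries at exactly 50% and 75% map to moderate.

# Known limitations

* The sym3 transition-leakage effect on tones near detail-band edges
  (above).
* Energies from the padded spectrum are exactly shift-invariant only on a
  matched (unpadded) grid; with 4× padding, circular-shift invariance is
  approximate.
* The S1/S2 alternation rule assumes a detectable peak train; it is not an
  arrhythmia-robust segmenter (arrhythmic records are excluded upstream by
  design).
* Absolute synthetic energy scales are calibrated, not derived from
  physiology; only their ordering and the 30% anchor are meaningful.
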