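---
title: "Detecting artefact in single-channel neonatal ERP epochs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting artefact in single-channel neonatal ERP epochs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neonartefact)
```

## The detection problem

Neonatal ERP studies frequently yield exactly one 1.5 s epoch of
single-channel EEG per stimulus per infant: a window from −0.5 s to
+1.0 s around the event, sampled at 2 kHz (3000 samples, stimulus at
sample 1001). Multi-channel artefact-removal methods are unusable here —
there is one channel and no long recording to calibrate against — so the
task is detect-and-reject: decide, per epoch, whether a panel of expert
raters would exclude it. `neonartefact` frames this as binary
classification with a consensus-labelled training set, and this vignette
records the model, its parameters and the design decisions that were
genuinely open.

## Conditioning chain

Continuous recordings are band-pass filtered 0.1–70 Hz and band-stop
filtered 49–51 Hz with non-causal (zero-phase) windowed-sinc FIR kernels
before epochs are cut. Zero phase matters because ERP latency is the
scientific quantity downstream; a causal filter would shift it.

Open choices, and what we chose:

* **Taper and transition widths.** The source method names neither. We
  use a Hamming taper with transition widths 0.1 Hz at the band-pass low
  edge, 5 Hz at its high edge and 1 Hz for the band-stop, via the
  standard Hamming design rule (≈3.3/N normalised transition). A
  band-pass with unequal edges is built as the cascade of a high-pass
  and a low-pass kernel; kernels are symmetrised exactly so
  `filter_signal()` is zero-phase to machine precision.
* **Continuous-first filtering.** A 0.1 Hz edge requires a kernel of
  ~67000 taps at 2 kHz — far longer than one epoch — so filtering is
  defined on the continuous recording. For stand-alone epochs
  `preprocess_epoch()` offers a relaxed low edge (default 0.5 Hz) with
  tiled reflection padding and warns that its response differs from the
  continuous chain.
* **Event-to-sample mapping.** An event maps to the first sample at or
  after its time (half-open convention). Epochs are pure slices; no
  resampling.
* **Clinical-trial compatibility.** `preprocess_recording(mode =
  "petal")` selects a 0.5–30 Hz band-pass, matching data that was
  manually rated under heavier filtering.

## The feature bank

Thirty-one scalars per epoch, frozen in `feature_manifest()` (version 1,
also shipped as `inst/extdata/feature_manifest_v1.txt`). Models embed
this manifest and refuse to predict when a feature table's columns
disagree with it — silent feature-order drift is the classic failure mode
of deployed feature pipelines.

Conventions that apply across the bank:

* **Kurtosis and skewness** are moment ("Pearson") forms: a Gaussian
  gives kurtosis ≈ 3, a full-period sinusoid exactly 1.5. The source
  method does not state Fisher vs Pearson; Pearson is used everywhere.
* **Degenerate inputs return 0.** Any feature whose defining moment is
  0/0 (constant epoch, zero-variance segment, empty band) returns 0
  rather than NaN, so the ensemble downstream is a total function.
* **"Sum of derivatives" telescopes.** The sum of first differences in a
  window equals the net change across it, so the statistic is computed
  as the sliding maximum of |x(t+w) − x(t)|, normalised by the variance
  of x²(t); this is algebraically identical to summing derivatives and
  O(n) per window length.
* **Spectral estimation.** The periodogram is a rectangular-window FFT
  of the whole epoch, evaluated on a zero-padded grid (4× the next power
  of two) so that the 0.5 Hz low-frequency bound — below the epoch's
  native 1/1.5 s ≈ 0.67 Hz resolution — contains bins. The epoch mean is
  removed before padding (a nonzero mean would otherwise leak into every
  low-frequency bin through the pad boundary) and its power is assigned
  to the DC bin, preserving the Parseval identity: the spectral integral
  equals the mean squared amplitude to machine precision. Band edges are
  half-open `[lo, hi)`.
* **Spectral slope.** λ is the least-squares slope of log₁₀ power on
  log₁₀ frequency in each band, with the fit error the RMSE of the
  residuals in log-power units. The power-law literature and the prose
  description agree on log power vs log frequency; the printed equation
  in the source (linear P against log f) appears to be a typesetting
  loss, and we follow the prose.
* **Bands.** delta 0.2–3.5, theta 4–7.5, alpha 8–13, beta 14–30, gamma
  30–70, broadband 2–70 Hz (EEG spectra follow a power law only above
  ~2 Hz). The delta band keeps its 0.2 Hz lower edge even when the
  filter low edge is higher; the band then starts at the first available
  bin.
* **Fractal dimensions.** Two estimators — Higuchi (curve length over
  lags 1..k_max, k_max = 8) and Katz (waveform length over diameter) —
  are applied in 100 ms windows with 50% overlap (29 windows per
  canonical epoch), and the feature is the kurtosis of each FD series.
  The windowing scheme is our convention; the source cites two
  estimators without naming a scheme, and Higuchi/Katz are the standard
  pair. A straight segment has Katz FD exactly 1; white noise has
  Higuchi FD ≈ 2.
* **Haar feature.** Full-depth orthonormal Haar decomposition; the
  feature is the kurtosis of all detail coefficients concatenated
  (whether one level or all levels was unstated; all levels retain the
  multi-scale information). The series is padded to the next power of
  two by replicating the final sample: zero-padding would fabricate a
  step at the pad boundary, and edge-value padding is what makes a
  constant epoch yield all-zero details, as the degenerate convention
  requires.
* **Amplitude change** is the sliding-window max − min over 50 ms; the
  alternative reading max |x(t+50 ms) − x(t)| is a lower bound of it,
  and max − min was chosen as the superset statistic.

Every feature is checked against an independently coded brute-force
oracle on random epochs (relative error < 10⁻⁶), and the bank satisfies
the expected scale laws: λ, kurtoses and skewness are scale-invariant,
amplitude change scales linearly and the power variance quartically.

## Consensus labels and rater agreement

Seven raters label each epoch artefact/clean; the consensus is the
majority, with a certainty weight `n_agree / n_raters` — between all
seven agreeing (weight 1) and a 4–3 split (weight 4/7). Agreement is
quantified by pairwise Cohen's κ with per-rater means (diagonal
excluded). Degenerate κ (both raters constant) is defined as 1 when they
agree everywhere, else 0.

Ground truth for scoring any one rater — or the classifier, treated as an
eighth rater — is the majority of the *other* raters. With six remaining
raters a 3–3 split can occur; such epochs are excluded from that
comparison rather than given a fabricated label (the source is silent on
this; exclusion injects no information).

## Classifier

A probability random forest (`ranger`, single-threaded, seeded) with
per-observation weights equal to the consensus certainty. The posterior —
mean per-tree class probability — is reported to the user as the
probability that the panel would reject the epoch; classification at
threshold t calls artefact when posterior ≥ t (the boundary goes to
artefact, favouring sensitivity). Thresholds sweep out the ROC curve
exactly.

Cross-validation is leave-one-subject-out: folds are whole infants, so
correlated epochs from one infant never straddle train/validation. The
train/test split is likewise grouped by infant and stratified by
(age group × stimulus) via a best-fit greedy assignment of whole infants
to the test side; when exact stratification is impossible the attained
deviation is attached and a warning logged.

The hyperparameter grid defaults to trees {100, 300}, depth {∞, 5, 10},
minimum leaf {1, 5, 10, 20}, features-per-split {√p, p}; minimum leaf
gets the widest range because it is the one hyperparameter whose tuning
visibly moves performance on this problem. The grid score is
class-support-weighted F1 averaged over folds; ties break
deterministically (fewer trees, then shallower, then larger leaf), so the
search result is independent of grid enumeration order. McNemar's test
(exact binomial below 25 discordant pairs, continuity-corrected χ²
otherwise) compares paired classifiers.

## Evaluation battery

Artefact is the positive class: sensitivity = TP/(TP+FN), specificity =
TN/(TN+FP), balanced accuracy their mean (an identity asserted on every
report). AUC is trapezoidal and equals concordance probability with ties
at ½. Permutation importance shuffles each feature 100 times and reports
the mean drop in *balanced* accuracy with a 95% normal interval — the
headline metric here, rather than raw accuracy; correlated features mask
one another under permutation, which is a property of the method, not a
bug. Univariate screening uses a single-predictor binomial logit with a
two-sided Wald p; perfect separation is flagged rather than Wald-ed.
Subgroup accuracy (by stimulus, age group or rater-agreement count) uses
a seeded percentile bootstrap with 1000 resamples. The evoked-response
SNR is max |post-stimulus amplitude| / sd(baseline); a peak-to-peak
numerator is available by option since the underlying magnitude
definition is not fixed in the literature.

## Synthetic data: what it does and does not show

The generator's defaults are the study conditions the detector targets:
2 kHz, 1.5 s epochs with the event at +0.5 s; pink (1/f) background at
20 µV RMS; a 30 µV Gaussian-windowed half-sine deflection peaking 0.35 s
post-stimulus; 21% artefact prevalence split across six classes; a
registry of 410 epochs from 160 infants over three age groups and seven
stimulus types, each infant contributing at most one epoch per stimulus;
and a 7-rater panel of four experienced (15% symmetric error) and three
expert (5%) raters, chosen so the expert tier agrees more strongly —
mirroring the qualitative ordering seen in real panels.

Artefact classes at default severity shift their designated features by
construction: mains breakthrough multiplies gamma band power ≥5×,
detachment flatline (random onset within the first 30 ms, collapse to 2%
amplitude thereafter — a detachment that leaves most of the epoch intact
could not produce the required variance collapse) divides the power
variance ≥10×, slow drift multiplies sub-0.5 Hz power ≥5×, and
burst/step/spike multiply the 50 ms amplitude change ≥3×. Severity scales
linearly; severity 0 is the identity.

Rater errors are independent across raters and epochs. Real raters
correlate — they look at the same waveform — so the closed-form expected
κ (`expected_kappa()`) holds only under this model, and simulated panels
are optimistic about the value of adding raters. Similarly, synthetic
artefacts at default severity are overt; a pipeline that reaches balanced
accuracy ≥0.90 here demonstrates that the mechanics (features →
weights → forest → evaluation) recover known structure, not that the
detector reaches any particular accuracy on clinical data. The generator
makes no attempt at neonatal EEG microstructure (sleep states, trace
alternant, burst suppression).

## Numerical and scale choices

Problem sizes in the test suite and the acceptance script — 50 oracle
epochs, 200/100 pipeline-recovery epochs, 2000-epoch κ calibration, the
410-epoch registry run — were chosen as the smallest sizes at which each
property is stably measurable. Sub-seeds are derived from the single
user seed; all randomness (generation, splits, forests, bootstraps,
permutations) flows from explicit seeds, and fixed-seed runs are
bit-reproducible, including across model serialization.

Known limitations: the EDF reader/writer covers exactly the single-EEG-
channel-plus-annotations layout this workflow produces (no multi-channel
montages, BDF, or BrainVision); the detector performs no artefact
*correction* — detect-and-reject only, by design; and feature extraction
dominates runtime (~40 ms per epoch), which is ample for study-scale
corpora but not for streaming use.
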