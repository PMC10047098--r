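---
title: "Methods: wavelet scattering detection of sleep apnea from single-lead ECG"
author: "apneaScatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet scattering detection of sleep apnea from single-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Obstructive sleep apnea (OSA) leaves a characteristic cardiac signature:
during an apneic event the heart rate drops, then surges as the event
resolves, producing a cyclical variation of heart rate (CVHR) with a period
of roughly 30–60 s, together with slow modulation of the R-wave amplitude.
`apneaScatter` classifies single-lead ECG recordings minute by minute
(normal vs apnea) without any beat detection or QRS delineation: the
waveform of each one-minute segment is mapped to a translation-stable
representation by a wavelet scattering transform, summarized by ten
statistical and entropy measures, and classified by a random forest.

The pipeline has four stages.

### 1. Preprocessing and quality weighting

Segments are 60 s long (6000 samples at 100 Hz). Each is band-pass filtered
to 3–45 Hz with a zero-phase linear-phase FIR filter (windowed sinc, Hamming
window, 101 taps), which removes baseline wander below the passband and
50 Hz power-line interference above it.

Noisy segments are rejected by mutual similarity of autocorrelation
signatures, computed per record (per patient). For segments $s,t$ with ACF
vectors $X_s, X_t$ (500 lags = 5 s, several RR intervals), the pairwise
weight is the centred cosine similarity

$$w_{st} = \frac{(X_s-\bar X_s)(X_t-\bar X_t)^{\mathsf T}}
  {\lVert X_s-\bar X_s\rVert\,\lVert X_t-\bar X_t\rVert},$$

which is algebraically the Pearson correlation of the two ACF vectors (the
package tests verify this identity against an independent correlation
oracle). A segment's weight is the mean of $w_{st}$ over the other segments
of the same record; segments with weight below $\lambda = 0.8$ are dropped.
The self-similarity (unit diagonal) is excluded from the mean by default —
including it shifts every weight toward 1 by the same amount, and the
clean/noisy contrast is unaffected; the `includeSelf` switch exposes the
other convention. Zero-variance or non-finite segments are flagged
degenerate and always dropped.

### 2. Wavelet scattering

The scattering network cascades analytic Gabor wavelet convolutions with a
modulus nonlinearity, then averages with a Gaussian low-pass $\phi$ whose
time support sets the invariance scale $T$:

$$S_0 f = f * \phi, \qquad
  S_1 f(j_1) = |f * \psi_{j_1}| * \phi, \qquad
  S_2 f(j_1,j_2) = \bigl||f * \psi_{j_1}| * \psi_{j_2}\bigr| * \phi .$$

Defaults: $T = 60$ s at 100 Hz, $Q_1 = 8$ and $Q_2 = 1$ wavelets per octave,
maximum order 2. Design choices the transform's definition leaves open:

* **Wavelet family.** Analytic Gabor (Gaussian in frequency) with an
  admissibility correction subtracting a scaled Gaussian at DC so every
  wavelet has exactly zero mean. Centre frequencies descend geometrically
  from $0.35 f_s$ by $2^{-1/Q}$; bandwidths are proportional to centre
  frequency and floored at the bandwidth of $\phi$ so no wavelet outlasts
  the averaging window.
* **Normalisation.** Each wavelet family is rescaled so the
  Littlewood–Paley sum $|\hat\phi|^2 + \sum_j |\hat\psi_j|^2 \le 1$ on the
  FFT grid, making the transform non-expansive:
  $\sum_m \lVert S_m f\rVert^2 \le \lVert f\rVert^2$ (asserted in the test
  suite at relative tolerance $10^{-6}$).
* **Paths.** Only frequency-decreasing pairs ($\xi_{j_2} < \xi_{j_1}$) are
  kept; ascending paths carry negligible energy. With the defaults this
  gives 1 + 84 + 440 = 525 paths. We deliberately do not chase any
  particular path count from other implementations — filter-ladder design
  rules differ across toolboxes, and the downstream feature bank is
  computed across whatever paths exist.
* **Boundaries and output grid.** Segments are reflection-padded to twice
  their length before circular FFT convolution. The averaged outputs are
  sampled on 6 frames per 60-s segment (10-s hop). A critically sampled
  grid at $T = 60$ s would give a single frame; the 6-frame grid is an
  oversampled output that multiplies the sample count available to the
  classifier by six, and the hop is configurable.
* **Order-0 sign.** $S_0 = f * \phi$ is a plain average and is negative for
  zero-mean content; only orders $\ge 1$ pass through a modulus and are
  nonnegative. The container enforces nonnegativity for modulus-derived
  rows only.
* **Order 3** exists solely for the energy-decay diagnostic (the order-2
  family is reused as the third filter bank): on band-limited noise, orders
  0–2 retain more than 99% of the energy of a maximal order-3 computation,
  which is why the pipeline truncates at order 2.

The implementation replaces the final low-pass FFT of every path by an
exact small inverse-DFT operator on the handful of frequency bins where
$\hat\phi$ exceeds $10^{-8}$ (equivalently a 6-row time-domain convolution
matrix), which removes about 60% of the FFT work without approximation.

### 3. The feature bank

The flattened coefficients form one sample per (segment, window) pair —
e.g. 489 segments × 6 windows = 2934 samples — and each sample's
coefficient sequence across paths is summarised by ten measures: the four
population moments (mean, standard deviation, skewness, non-excess kurtosis
— a Gaussian scores 3), histogram Shannon entropy, approximate entropy,
sample entropy, spectral entropy, attention entropy, and cumulative
residual entropy. Conventions that the definitions leave open:

* **Shannon entropy** uses 32 equal-width bins over the sample range and
  natural logarithms. Binning and log base are configuration, not claims.
* **ApEn/SampEn** use embedding dimension $m = 2$ (standard in the HRV
  literature) and tolerance $r = 0.25\,\mathrm{STD}$ of the sequence
  (population form), which makes both measures scale-invariant. ApEn counts
  self-matches with denominator $N-m+1$; SampEn excludes them with
  denominator $N-m$ and reports $+\infty$ (rather than a silent cap) when
  no templates match. Both are implemented in C++ ($O(N^2)$ template
  counting) and verified against naive R oracles.
* **Spectral entropy** is the Shannon entropy of the one-sided periodogram
  (DC through Nyquist) normalised to a distribution, divided by
  $\log N_f$, hence in $[0,1]$.
* **Attention entropy** uses the single-stream convention: key points are
  strict local maxima and minima pooled into one sequence, and the measure
  is the Shannon entropy of the distribution of index intervals between
  successive key points. The interval is an index difference; a
  value-difference reading would not be an interval count.
* **Cumulative residual entropy** is estimated as the survival-function
  integral, the spacing-weighted sum
  $\sum_i (x_{(i+1)}-x_{(i)})\,(-p_i\log p_i)$ with
  $p_i = \hat P(X > x_{(i)})$. A bare sum of $-p\log p$ over sample points
  depends only on ranks — it is the same constant for every continuous
  sample of a given length and could not discriminate anything — so the
  estimator that weights by spacings is the only reading under which CRE is
  a usable feature.

Features are z-scored per column, $z = (x - \bar X)/\sigma(X)$ with
population $\sigma$; inside cross-validation the statistics are fitted on
each training split only and applied unchanged to the test split.

### 4. Classification and validation

The reference classifier is a random forest (500 trees, $\sqrt p$
candidates per split, unlimited depth, seeded); ten comparison classifiers
(AdaBoost over depth-1 stumps, extremely randomised trees, Gaussian naive
Bayes, k-NN, LDA, logistic regression, QDA, SGD-trained logistic
regression, RBF SVM, gradient boosting) run on identical folds for paired
comparison. Two validation protocols are provided, each repeated (10 by
default) with mean ± sd reporting across repeats: stratified 50/50
hold-out (optionally subject-wise via a `groups` argument, so whole
records stay on one side of the split) and stratified 10-fold CV, pooling
each repeat's held-out predictions before computing accuracy, sensitivity,
specificity, precision, F1, Cohen's kappa and AUC (rank statistic; equal to
trapezoidal ROC integration, which the tests assert). Apnea is the positive
class. PCA reduction (fit on the training split) and sequential feature
selection (greedy, scored by 5-fold random-forest accuracy; forward or
floating bidirectional — the two directions are both legitimate
conventions and neither is privileged) are available on top.

## The synthetic generator

Real overnight recordings cannot ship with the package, so every stage is
exercised on synthetic ECG whose statistical structure matches what the
pipeline exploits:

* normal minutes: a Gaussian-derivative QRS template train at base RR
  0.8 s with respiratory sinus modulation (0.25 Hz, 5% depth);
* apnea minutes: the same train with RR and R-amplitude modulated by a
  sinusoid whose period is drawn once per record from 30–60 s (CVHR);
* both: broadband beat-to-beat RR jitter of 5% (SDNN ≈ 40 ms, physiologic
  during sleep), white noise, 0.3 Hz baseline wander, 50 Hz interference;
* optional artifact minutes receive high-amplitude broadband bursts.

The RR jitter matters beyond realism: a purely deterministic respiratory
sinusoid cancels exactly over each 4-s cycle, leaving unrealistically
coherent high-lag ACF peaks — under which *any* slow apnea modulation
decorrelates the classes and the λ = 0.8 filter would reject clean
segments wholesale, the opposite of the regime observed on real
recordings, where clean segments weigh near 0.98 and only a fraction of a
percent is rejected. Broadband variability restores that regime for both
classes.

The generator is template-based, not a dynamical heart model: no P/T-wave
morphology, no respiration or SpO2 channels, no inter-subject variability
in QRS shape. Consequently a passing benchmark demonstrates that the
pipeline recovers planted class structure through all of its stages — it
does not certify clinical performance on real recordings, which must be
obtained from real data (the readers accept PhysioNet-style WFDB format-16
records for exactly that use).

Benchmark difficulty settings, frozen as the package's study conditions:
`easy` = modulation depths 0.30, white noise 0.03 mV; `hard` = depths 0.10,
white noise 0.15 mV. Same seeds always reproduce the same records
bit-for-bit.

## Numerical choices and degenerate inputs

* FFT convolutions on the reflection-padded grid; the complex modulus is
  the nonlinearity.
* Constant (zero-variance) segments: degenerate for ACF weighting, dropped
  before the similarity computation; feature measures define entropies 0
  and flag shape moments `NA`.
* Zero-variance feature columns pass through z-scoring unscaled, with a
  warning.
* Folds that would leave a single-class training set are redrawn with a
  logged warning.
* Ties in AUC scores are handled by midranks (equivalently trapezoids).

## Problem sizes used by the shipped checks

The test suite runs entirely on synthetic data: the end-to-end benchmark
uses 200 labelled minutes per class (400 one-minute segments, 2400 feature
rows) with 10-fold CV repeated 3 times; the energy-decay and stability
checks use 10 and 4 noise segments of 6000 samples; the entropy-oracle
battery uses 200 series of length 60; scattering unit tests use a reduced
bank (15-s invariance on 1500-sample inputs). These sizes are the package's
choices for a self-contained, deterministic test bed; all of them scale up
through the same functions.

## Known limitations

* WFDB support is deliberately minimal: plain format-16 single-file
  records, the dialect of the Apnea-ECG corpus; other storage formats are
  rejected rather than guessed.
* The scattering path count depends on the filter-ladder conventions above
  and will not numerically match other scattering toolboxes, although
  order-1 responses agree with closed-form predictions and the energy
  inequalities hold by construction.
* Minute-level labels inherit all the ambiguity of expert minute scoring:
  a minute with a single brief event counts as apnea in its entirety.
* The subject-wise hold-out protocol is available, but the synthetic
  benchmark's records are statistically exchangeable, so it cannot expose
  subject-level domain shift the way real cohorts do.
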