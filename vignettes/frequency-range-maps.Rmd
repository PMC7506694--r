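---
title: "Pairwise spectral band selection for vibroarthrographic signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise spectral band selection for vibroarthrographic signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagfrm)
```

## The problem

A vibroarthrographic (VAG) recording is the output of an accelerometer
mounted on the patella while the knee performs extension–flexion cycles.
Cartilage degeneration — chondromalacia patellae in its three Outerbridge
stages, or osteoarthritis — changes the vibroacoustic emission of the
joint, and with it the spectrum of the recording. The diagnostic task is
five-class: healthy control (`ctrl`), `cmp1`–`cmp3`, `oa`.

Classical spectral descriptors compress each signal into a handful of
fixed quantities (band powers over 50–250 Hz and 250–450 Hz, spectral
density at 470 Hz and 780 Hz) that must separate *all* classes at once. A
single number is easily "typical" of two different conditions, which blurs
diagnosis. This package instead optimizes one frequency band *per class
pair*. With five classes there are ten pairs, hence ten features, and
every pair gets the band in which those two conditions differ most.

## Feature families

For a signal of length N sampled at rate fs, the one-sided DFT magnitude
|X(f)| is computed on the whole, un-windowed signal, giving bins at
multiples of Δf = fs/N (0.1667 Hz for the 6 s, 10 kHz protocol). Four
band-sum functionals — the *families* — are defined over a band
[f₁, f₂]:

1. Σ |X(fᵢ)| — the spectrum;
2. Σ 2πfᵢ|X(fᵢ)| — the spectrum of the signal's derivative, realized by
   frequency-domain multiplication (the transform of a derivative is the
   transform times 2πif), never by finite differencing;
3. Σ |X(fᵢ)|² — the energy;
4. Σ (2πfᵢ)²|X(fᵢ)|² — the energy of the derivative, i.e. the squared
   summand of family 2.

each normalized by 1/(f₂−f₁) so that the value reflects spectral shape
rather than band width. Sums are inclusive of both endpoint bins. Three
conventions are worth making explicit:

* Families 1–2 sum *magnitudes*. Summing raw complex amplitudes would make
  the features phase-dependent and nearly cancel; the nonnegative spectra
  the features are meant to summarize require the modulus.
* Family 4 is exactly the square of family 2's summand, (2πf)²|X|²,
  keeping the energy families the squares of their amplitude
  counterparts.
* A band whose two bounds snap to the same DFT bin is *degenerate* and
  returns that bin's value with normalization factor 1. Single-frequency
  optima occur in practice, so this case is first-class rather than an
  error.

The one-sided spectrum omits the conjugate-symmetry factor of two: it is a
constant that cancels in every Bhattacharyya comparison and in argmin band
selection, so carrying it would only add noise to none of the decisions.
The energy identity that *is* load-bearing — two-sided Σ|X_k|² = N·Σx²
(Parseval) — is enforced in the test suite at relative tolerance 1e−9 after
restoring the symmetry weights.

No per-signal amplitude normalization is applied before feature
computation: VAG amplitude units are arbitrary but consistent within a
recording session, and normalization is a confound best studied
explicitly rather than silently imposed.

## Separability: KDE and the Bhattacharyya coefficient

A candidate band is scored by how little the two classes' feature
distributions overlap. Each class's sample of scalar feature values is
turned into a density with a Gaussian kernel density estimate using the
Silverman rule-of-thumb bandwidth

h = (4/(3n))^(1/5) · σ,

with σ the sample standard deviation (divisor n−1). The overlap is the
Bhattacharyya coefficient

Bcoef(p, q) = ∫ √(p(x) q(x)) dx,

which is 1 exactly when p = q and 0 when the supports are disjoint. The
integrand is √(pq), not pq: only the former integrates to 1 for identical
distributions, which is the defining property of the coefficient.

Numerical choices, each a tolerance-backed default and overridable:

* shared uniform grid of 2048 points spanning both samples plus 4
  bandwidths of margin on each side (beyond 4 bandwidths a Gaussian kernel
  holds < 10⁻⁴ of its mass);
* trapezoid-rule integration; the result is clipped to [0, 1], absorbing
  quadrature error in the third decimal;
* a constant sample (σ = 0) receives a surrogate spread of
  max(|mean|, 1)·10⁻⁶ with a warning, keeping degenerate features finite
  instead of crashing a 100 000-cell search over one pathological band.

The test suite pins this stack to closed forms: the self-overlap
coefficient is 1 ± 10⁻³; two unit-variance Gaussians two standard
deviations apart give exp(−δ²/8σ²) = exp(−0.5) ± 0.02 at n = 5000 (the
KDE widens each density's variance by h², which at that n stays inside
the tolerance); the KDE of standard-normal draws matches the convolution
N(0, 1+h²) at the origin.

## The Frequency Range Map search

A Frequency Range Map (FRM) is a triangular matrix: rows are lower band
bounds, columns upper bounds, entries the Bhattacharyya coefficient of the
band feature. Scanning every bin pair of a 30 001-bin spectrum
(~4.5 × 10⁸ cells) is out of reach, so the search is iterative:

1. full 0–Nyquist range on a coarse grid (default step ~10 Hz, snapped to
   an integer number of bins), strict f₁ < f₂;
2. ±800 Hz around the previous best band's bounds at ~2.5 Hz;
3. ±80 Hz at the native bin width, where single-frequency (degenerate)
   bands are admitted.

Two details the iteration scheme needs but that are easy to get wrong:

* **Previous-best injection.** Each refinement grid is augmented with the
  previous best cell. Without it a refinement grid that happens to miss
  the old optimum could *regress*; with it the best coefficient is
  non-increasing across iterations by construction, and the test suite
  asserts this for all forty searches of a full run.
* **Bin snapping.** Every evaluated bound lies on the DFT bin grid, so
  re-running a search is bit-reproducible and per-signal cumulative sums
  over spectrum bins make each cell's band sums O(1) after an O(N_bins)
  precomputation. The agreement of the cumulative-sum path with direct
  summation is spot-checked at 1e−9.

Ties in a map (exactly equal coefficients, common when several bands fully
separate two synthetic classes) are broken toward the narrower band, then
the smaller lower bound — a determinism-and-parsimony rule.

The full build runs all ten pairs × four families (40 searches, 120 maps,
40 final-iteration maps) and selects per pair the family with the minimal
final coefficient, ties toward the lower family index. Degenerate inputs —
a class missing from the dataset, fewer than two signals in a class, axes
beyond Nyquist — are rejected with named errors before any spectra are
computed.

## The synthetic generator

Clinical VAG recordings are not publicly deposited, so the package ships a
generator whose defaults mirror the study design: five groups of
66/26/30/36/26 signals (184 total), 6 s at 10 kHz, four extension–flexion
cycles. Each class profile is

* a 1/f^α colored-noise baseline (frequency-domain shaping of white
  noise),
* zero or more *emphasis bands*: band-limited noise realized by exact
  frequency-domain masking — not IIR filtering — so band content is
  analytically controllable, scaled by a gain,
* Poisson-distributed crepitus bursts: ~20 ms exponentially damped
  sinusoids (5 ms decay), center frequency uniform in a burst band, event
  times drawn from the cycle-periodic envelope so bursts cluster where
  the joint moves fastest.

The shipped default profiles order severity the way the clinical picture
does — quiet baseline and rare bursts for `ctrl`, increasing burst rate
and amplitude with widening sub-500 Hz emphasis bands through
`cmp1`–`cmp3`, and a strong low-frequency emphasis for `oa` distinct from
`cmp3`. The exact numbers (gains 0.8–3.0, burst rates 0.5–6 per cycle)
were chosen once as plausible magnitudes for band-limited structure
sitting a few decibels above a unit-variance baseline; they live in
`inst/extdata/default_profiles.yaml` and are free parameters, not
calibrated biomechanics.

What the generator does *not* emulate: real crepitus waveform shapes,
inter-patient variability, electrode/sensor artifacts, the correlation
structure of consecutive cycles, or the heavy overlap of neighboring
clinical stages. Passing tests on synthetic data therefore demonstrate
that the pipeline recovers *planted* spectral structure (a band present in
one class and not the other is found by the search in ≥ 9 of 10 seeded
runs, with coefficient < 0.05 at full separation) and that its
bookkeeping, determinism and calibration are correct — not that clinical
accuracy would match the published figures.

## The benchmark

Feature matrices (ten new columns, or the four classical baseline
features P1/P2/F470/F780 computed per the original recipe: 150-sample
Hanning segments with 100-sample overlap for the band powers, a
full-signal periodogram for the point densities) are compared by training
ten classifiers over repeated stratified random splits. Design choices
where the procedure was genuinely open:

* **Split proportions** are 60/20/20 teaching/testing/validation,
  stratified by class; the validation part is reserved for classifiers
  that need early stopping and is unused by the default suite.
* **Pairing.** Per repeat, both feature sets see the *identical*
  partition, making the comparison paired and removing split luck from
  the contrast.
* **Scaling.** Columns are standardized with means and deviations fitted
  on the teaching split only — fitting them on all data would leak test
  information.
* **Improvement sign.** Improvement is reported as (old−new)/old·100 for
  lower-is-better metrics (Bhattacharyya coefficients) and
  (new−old)/old·100 for higher-is-better ones (accuracies), so a positive
  number always favors the new features.
* **Backends.** The classifier suite is a fit/predict contract; the
  defaults are rpart trees grown unpruned and cut back to at most 10 (or
  5) splits via the complexity table, MASS linear discriminant analysis,
  e1071 Gaussian naive Bayes and linear SVM, Euclidean k-NN at k = 20 and
  5, a 100-tree bagging forest, a gradient-boosted forest with an
  11-leaf (= 10-split) budget, and a 10-hidden-unit single-layer
  network. Sigmoid flavor and boosting variant are backend details the
  contract deliberately leaves open.

Every stochastic step — splits and every randomized fit — is re-seeded
from the benchmark seed per repeat and classifier, so results are
bit-reproducible, which the suite checks at 32 repeats with the full
classifier set.

## Problem sizes in the shipped tests

The test suite exercises every stage at reduced scale so it runs in a few
minutes: recordings of 0.05–1.5 s at 1–10 kHz, cohorts of 10–30 signals
(plus one 184-signal run at 0.005 s to check the study-sized bookkeeping),
search schedules of 250/50/10 Hz or coarser, and benchmarks of 2–64
repeats. All scale-dependent checks (chance-level calibration at
0.2 ± 0.05 over five balanced classes, planted-band recovery, monotone
refinement) were sized so that Monte Carlo noise is small against the
asserted bands; none of the tolerances encode fitted constants.

## Known limitations

* The Bhattacharyya computation is O(grid × n) per cell; a full-resolution
  final iteration on 6 s recordings is minutes-scale per class pair in
  pure R. The cumulative-sum trick removes the band-summing cost, but the
  KDE remains the bottleneck for very fine grids.
* Features selected per pair are correlated across pairs (overlapping
  optimal bands), which some classifiers dislike; no decorrelation (e.g.
  PCA) is applied.
* The ten-feature construction assumes exactly the five-class label set;
  generalizing to other label sets changes the pair inventory and letters.
* The KDE bandwidth is the Gaussian-kernel Silverman rule throughout; no
  adaptive or cross-validated bandwidths.
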