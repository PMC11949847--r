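---
title: "Methods: multimodal cardamom grading in gradecard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal cardamom grading in gradecard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `gradecard`: what each stage assumes, which parameters matter and
why their defaults were chosen, what the synthetic-data generator does and
does not emulate, and the known limitations of desk-scale validation.

## The measurement model

A grading experiment observes each sample through two instruments.

**Electronic nose.** An array of nine metal-oxide (MOS) gas sensors (MQ2,
MQ4, MQ6, MQ7, MQ9, TGS813, TGS822, TGS2610, TGS2611) records voltage at
1 Hz through three phases: a clean-air baseline (0–200 s), headspace
injection (200–240 s), and recovery under clean air (240–300 s). MOS
conductance rises when volatiles adsorb, so the informative signal is the
relative departure from the clean-air level. We use fractional baseline
normalization, `y = (V − V0) / V0`, with `V0` the mean voltage over a
reference span; the reference defaults to the final 10 s of the baseline
phase, by which time the sensors should be stationary. This choice makes
all downstream features invariant to the absolute voltage scale (amplifier
gain, load resistor), a property the test suite checks directly.

Six descriptors summarize each sensor's normalized response over the
injection window, taken as the samples at t = 201..240 s inclusive (40
points at 1 Hz): the maximum response MSR; the impregnation time Tim
(time from the window start to the first sample attaining the maximum —
first occurrence wins ties, and a response whose maximum is the first
sample has Tim = 0); the integral value INV (trapezoidal rule — the
response is smooth and densely sampled, so higher-order quadrature would
add nothing); the average ascending slope Sasce (mean of the
instantaneous slopes up to the maximum, which equals the chord slope
under uniform sampling; defined as 0 when the maximum is the first
sample); the maximum instantaneous slope Smax; and the mean differential
coefficient MDCV (mean of all instantaneous slopes). `Smax >= Sasce` and
`Smax >= MDCV` hold on any input because a maximum dominates any mean of
the same quantities.

**Computer vision.** A 400 × 400 pixel block is cropped from the image
centre (for odd residuals the extra margin falls at the bottom/right);
the block is assumed to contain only product, no background — the
synthetic generator guarantees this by construction. Thirty-six colour
features are the mean, sample standard deviation (n−1 denominator),
skewness `m3/m2^1.5` and kurtosis `m4/m2^2` (so a normal channel scores
3, not 0) of the nine channels R, G, B, H, S, V, L\*, a\*, b\*. HSV uses
the standard hexcone transform with all three channels scaled to [0, 1];
CIELAB uses the sRGB → XYZ → Lab path with the D65 white point
(`grDevices::convertColor`), L\* in [0, 100]. Channels with vanishing
variance (m2 < 1e−12) report zero skewness and kurtosis rather than NaN.

Sixteen texture descriptors come from the gray-level co-occurrence matrix
(GLCM). The block is converted to gray with the classical luminance
weights 0.2989/0.5870/0.1140 and quantized linearly into 8 equal bins on
[0, 1] — 8 levels keeps the 30-sample-per-class estimation problem well
conditioned while preserving the coarse/fine contrast between grades.
Pairs are counted at unit distance along 0°, 45°, 90° and 135°;
out-of-bounds neighbours are skipped. Each directional matrix is
symmetrized as `P + t(P)` before averaging, because the texture formulas
assume identical row and column marginals; the average of the four is
normalized to probabilities. Averaging over the four directions makes the
whole 16-vector exactly invariant under 90° image rotation, which the
suite asserts at 1e−12. Logs are base 2 (entropies in bits) with
`0·log 0 := 0`; correlation is defined as 0 when the marginal variance
vanishes (constant image); sum variance is centred on the sum average
(the modern convention) rather than on the sum entropy; homogeneity uses
the `1/(1+|i−j|)` weight and inverse difference moment the `1/(1+(i−j)²)`
weight — the two are listed as distinct features and these denominators
are our documented assignment.

## Feature selection

CFS scores a subset S of k features by

```
M_s = k * mean(r_cf) / sqrt(k + k*(k-1) * mean(r_ff))
```

with `r_cf` the feature–class and `r_ff` the pairwise feature–feature
correlations. Several renderings of this index circulate in the applied
literature, some omitting the radical in the denominator; we implement
the square-root form of Hall's original CFS, since without the radical
the index is no longer normalized like a correlation and collapses
toward zero as k grows. Correlations are symmetrical uncertainties
computed after Fayyad–Irani MDL discretization (recursive binary
entropy splits accepted only when the information gain exceeds the MDL
coding cost). Features that accept no split become single-bin and carry
zero correlation everywhere — a useful, conservative behaviour for pure
noise columns. A Pearson-correlation variant was considered and rejected:
SU handles the strongly non-Gaussian, sometimes multimodal feature
distributions (hue in particular) without distributional assumptions.

The search is forward best-first: an open list of subsets ordered by
merit, the best unexpanded subset expanded by each unused feature, with
the search stopped after five consecutive *expansions* that fail to
improve the global best (strict improvement, tolerance 1e−10). Counting
expansions rather than evaluated children is our reading of the
"five consecutive subsets" patience convention; children would make the
patience depend on the feature count. Ties break toward smaller subsets,
then lexicographic feature order — this is what discards exact duplicates
of an already-selected feature. The open list is unbounded; with ~100
features and patience 5 the search expands a few dozen nodes.

On the default synthetic conditions the selected subsets are small —
often a single colour moment with merit 1 — because symmetrical
uncertainty saturates once a feature separates the 45 samples perfectly.
Real instruments, with overlapping grade distributions, yield larger
subsets; the generator can be pushed into that regime by raising
`noise_sd` or moving the grade palettes closer.

## Classifiers and evaluation

Three families, chosen to span margin-based, probabilistic-graphical and
rule-based learning:

* **SVM** (kernlab backend): one-vs-one margin classifiers with pairwise
  logistic probability coupling. Features are standardized (fit on the
  calibration data only). Kernels: polynomial, normalized polynomial,
  RBF, and the Pearson VII universal kernel
  `K = 1 / (1 + (2*||x−y||*sqrt(2^(1/ω)−1)/σ)²)^ω`, authored in-package;
  with defaults ω = σ = 1. `C` defaults to 1. The PUK Gram matrix is
  positive semidefinite (checked spectrally in the suite).
* **Bayesian network**: features MDL-discretized; the structure is the
  class-parent naive graph, optionally augmented by K2 search (features
  considered in column order, at most one extra parent each, accepted
  only when the Cooper–Herskovits score improves). Conditional
  probability tables use additive smoothing α = 0.5, so bins unseen in
  training predict smoothed, never zero, probabilities.
* **Decision tree**: greedy binary splits on single features maximizing
  gain ratio (information gain over split information), minimum leaf
  size 2, with optional reduced-error pruning against a stratified 25%
  holdout drawn with the classifier seed. Leaf probabilities are
  Laplace-corrected class frequencies.

Evaluation follows a two-stage protocol: a stratified 70/30 split (per
class, `floor(0.7·n)` samples to calibration — 15 per grade gives 10/5,
matching the confusion-matrix marginals such designs report), 10-fold
stratified cross-validation pooled over folds for the calibration
metrics, and a final fit on the full calibration part scored on the
held-out 30%. Accuracy is percent correct; the probabilistic RMSE is
`sqrt(sum (p̂ − onehot)² / (n·C))`, which is 0 for perfect confident
predictions and `sqrt(2/9) ≈ 0.4714` for uniform three-class
predictions regardless of the labels. When a class has fewer calibration
samples than folds, the fold count is reduced with a warning rather than
failing.

Feature-level fusion is plain column concatenation after verifying the
two tables hold the same samples in the same order and disjoint feature
names; no reweighting is applied, since the downstream selection and the
SVM standardization already handle scale.

## The synthetic-data generator

No public dataset accompanies this problem domain, so the generator is a
first-class, tested module that emulates the *statistical structure* the
analysis relies on, not the physics of the instruments.

E-nose curves are piecewise: flat baseline, saturating exponential rise
`A·(1 − exp(−(t−200)/rise_tau))` during injection, exponential decay
during recovery, plus i.i.d. Gaussian noise with standard deviation
`noise_sd · V0`. This is the simplest family reproducing the canonical
MOS response shape. The default amplitude matrix is grade-ordered —
`A[s, Grade1] > A[s, Grade2] > A[s, Grade3]` for every sensor, spanning
0.45–0.90 in fractional-response units for Grade 1 — so higher grades
smell stronger on every sensor, and the per-sensor time constants vary
(rise 8–16 s, fall 18–30 s) so sensors are not exact copies. The default
`noise_sd = 0.005` (0.5% of baseline voltage) represents a well-behaved
bench instrument; it is a placeholder exposed in the configuration, not a
claim about any particular hardware.

Images are composites of randomly placed, randomly sized ellipse
primitives over a light background, colours drawn around a per-grade
CIELAB base colour with Gaussian jitter (sd 3 Lab units), then box
smoothed. Capsule palettes are green / yellow / dull olive; seed palettes
black / brown / yellow-red. The per-grade `texture_scale` (9/14/20 px)
changes primitive size so the co-occurrence features also separate
grades. The primitive lattice uses spacing `s` with radii ≥ 1.2 s and
centre jitter ≤ 0.3 s, which guarantees the central 400 × 400 block is
fully covered — the crop never sees background. Defaults: 480 px images,
15 samples per grade, seed-deterministic throughout (every random draw
descends from `config$seed`; repeated calls are byte-identical).

What the generator does **not** emulate: sensor drift, humidity and
temperature effects, inter-session baseline shifts, real capsule
morphology and specular lighting, correlated sensor noise, or label
noise. Consequently, passing tests demonstrate the *pipeline's*
correctness and the qualitative fusion behaviour, not field performance:
on these synthetic conditions near-perfect accuracies are expected and
observed, whereas real instruments face harder class overlap.

## Problem sizes and numerical choices

The test suite and the acceptance script run the study-scale design (3
grades × 15 samples, 9 sensors, 480 px images) where the property under
test needs it, and smaller instances (3 samples per grade, 16 × 16 blocks,
10-feature tables) for oracle-equivalence checks, keeping the default
suite in the minutes range on one CPU. Brute-force oracles — double-loop
pair counting for the GLCM, naive summations for the texture battery and
channel moments, exhaustive subset enumeration for CFS — are kept in the
test helpers, independent of the package implementations they verify.

Key tolerances: GLCM symmetry/normalization 1e−12; oracle equivalence
1e−10; CFS strict-improvement 1e−10; probability rows sum to 1 within
1e−9; degenerate-variance guards at 1e−12. Monte-Carlo null checks (MDL
accepting no split on label-independent data; SU vanishing under
independence) use fixed seed sets with the acceptance fraction set at
95%.

## Known limitations

* Symmetrical uncertainty saturates at small n, so CFS subset sizes on
  easy synthetic data are smaller than on real instruments.
* The SVM probability calibration (pairwise logistic coupling) is
  fitted on small per-fold samples; its RMSE is meaningful comparatively,
  not absolutely.
* K2 augmentation is limited to one extra parent per node and the given
  column order; it is a structure refinement, not a full structure
  search.
* The generator's noise model is white; autocorrelated sensor noise
  would make the slope features (Smax, MDCV) noisier than simulated.
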