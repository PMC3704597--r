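---
title: "Classifiability-ordered decomposition of dichotomous kinematic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifiability-ordered decomposition of dichotomous kinematic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitSubspace)
```

## The model

A trial is a point in an N-dimensional data space: the time courses of all
markers along all axes, concatenated marker-major (marker 1 x, then y, then
z, then marker 2 x, ...). With 13 markers, 3 axes and 101 normalized stance
time points, N = 3939 and the canonical example is that (marker 3, vertical
axis, time point 39) occupies column 847. `variableIndex()` and
`variableInfo()` implement this bijection; all user-facing indices are
1-based.

The analysis assumes a *dichotomous* design — exactly two conditions, each
subject measured repeatedly under both — and asks which directions of the
data space *classify* the conditions, as opposed to which carry the most
variance. Classifiability is deliberately stricter than separability: every
assessment in the package is leave-one-subject-out (LOSO), so a direction
counts only if it transfers to subjects that played no part in estimating
it.

Three bases are computed on the within-subject whitened matrix:

* the **PCA base** (variance-ordered, the conventional approach), each
  vector scored by its LOSO classification rate;
* the **SVM base**: iteratively extracted mean LOSO linear-SVM
  discriminants, each accepted only while the classification rate stays
  significant, with deflation to the orthogonal complement between steps;
* the **ICA base of the SVM space**: statistically independent directions
  spanning the SVM space, of which at most one is expected to classify.

The orthogonal complement of the SVM space is summarized by PCA; SVM basis
and complement basis together form an orthonormal basis of the space
spanned by the data, and every vector carries the fraction of total
variance it explains (mean squared projection over total sum of squares, so
fractions over a full basis sum to one — an identity the tests assert).

### Whitening

Whitening is per subject and per variable, over that subject's trials *and
conditions pooled* — pooling matters, since per-condition whitening would
erase the very difference under study. The standard deviation uses the
sample (n−1) denominator, the conventional estimator for a sample of
trials; `whiten()` retains the statistics so that reconstruction can return
to metric coordinates exactly (`unwhiten()` round-trips to 1e-10). A
zero-variance subject/variable cell is an error by default; an optional
mode zeroes such columns and records them, preserving the fixed column
layout.

### Classifiability gating

Both gates are one-sided binomial tests at α = 0.05 with chance probability
0.5: a held-out subject is classifiable when its correct-trial count
reaches the trial-level threshold; a rate is significant when the number of
classifiable subjects reaches the subject-level threshold. The exact
thresholds are 26 of 40 trials and 9 of 11 subjects. The historically
printed counts for this design are 25 of 40 and 8 of 11 — one below the
exact tail in both cases. Both conventions are implemented
(`classifiabilityRule("paper")` pins the printed counts for those n and is
the default, for continuity with the published analysis; `"exact"`
recomputes every threshold and is recommended for new data). The active
mode is stamped into every report, and the package makes no attempt to
decide which computation produced the printed counts.

### The SVM stage

The SVM uses a linear kernel — essential, because only then is the
discriminant itself a data-space vector (the weighted sum of support
vectors) that can seed an orthonormal basis. Numerical choices:

* **Box constraint** C = 1 by default. The SVM-space dimensionality is
  known to depend on solver parameters, so C is recorded in every result
  and exposed (`cost`).
* **No internal rescaling** (`scale = FALSE`): the data are already
  whitened; a second scaling would distort the discriminant.
* **Fold averaging**: the 11 fold directions are sign-aligned to the first
  fold by non-negative dot product and averaged; the mean is renormalized
  to unit length, since a basis vector must have unit norm. Fold-to-mean
  cosines are retained for diagnostics.
* **Re-orthogonalization**: each accepted direction is Gram–Schmidt-purged
  against the previously accepted ones (tolerance 1e-10) — analytically a
  no-op after deflation, numerically a drift guard.
* **Row-space reduction**: a linear kernel depends on trials only through
  their inner products, and the weight vector lies in the training row
  space, so when variables outnumber trials the LOSO fits run in thin-SVD
  coordinates and directions are mapped back. This is an exact
  reformulation, not an approximation, and makes the 3939-variable problem
  cost what a 429-dimensional one does.
* **Rank** is determined with a relative singular-value tolerance of 1e-10;
  the iteration can also end by rank exhaustion, which is recorded as the
  termination reason alongside the ordinary rate-drop.
* The final, rejected discriminant is logged (rate and per-subject counts)
  but never added to the basis.

Deflation is performed in the original coordinates (x → x − ⟨x,e⟩e) rather
than by reparameterizing into a complement basis; the two are equivalent up
to numerics and the former keeps every object in the same variable space.

### The 1-D assignment rule

PCA and ICA vectors are scored with a shared deterministic rule: the
decision threshold is the midpoint of the two training-condition mean
projections, oriented so the larger training mean is the positive side.
Degenerate training projections (equal means) fall back to chance
assignment with a warning. The rule is invariant under affine transforms
of the projections and under sign flips of the vector.

### The ICA stage

No ICA implementation is available among the package's dependencies, and
the subspace ICA is integral to the method, so the package implements a
batch extended-infomax algorithm (natural-gradient update with
kurtosis-sign switching between sub- and super-Gaussian nonlinearities)
plus a deflationary fastICA-style alternative with the logcosh contrast.
The extended update matters here: a condition effect makes the classifying
source *bimodal*, i.e. sub-Gaussian. Both engines run on
second-moment-whitened SVM-space coordinates (the coordinates have exactly
zero mean by construction of the whitening), are deterministic given the
recorded seed, and restore the caller's RNG state. ICA scale and order
indeterminacies are resolved by unit-normalizing the data-space vectors and
ordering by decreasing classification rate of the source coordinates, so
"the first ICA vector" is the discriminant whenever one exists; a data set
with no significant ICA vector reports an empty discriminant index, which
is a valid outcome, not an error. Uniqueness of the ICA discriminant is not
adjudicated: multi-seed stability can be inspected by rerunning with
different seeds, and the seed and algorithm are always recorded.

## Preprocessing

Raw trajectories pass through a fixed order: low-pass filter, stance crop,
time normalization, centering/scaling. Filtering precedes cropping so that
filter edge effects fall outside the analyzed segment (the original order
is not documented; this choice is asserted by the orchestrator).

* **Filter**: zero-phase low-pass Butterworth, cutoff 12 Hz, net order 4 at
  240 Hz sampling. Zero phase is realized as a forward–backward pass with
  the per-pass order halved, standard biomechanics practice; a single
  causal pass is available. The series is odd-reflection padded far enough
  for the start-up transient (set by the slowest filter pole) to decay
  below 1e-13 before the retained samples.
* **Stance**: vertical ground reaction force ≥ 15 N marks contact; toe-off
  is the end of the contiguous supra-threshold episode. Multiple episodes
  trigger a warning and the first is used. Force sampled faster than the
  kinematics is decimated to the frame clock by nearest-frame lookup.
* **Time normalization**: cubic-spline interpolation at 101 equidistant
  instants spanning contact to toe-off — deterministic and endpoint-exact
  (a polyphase resampler would be an alternative for fidelity studies; the
  spline's property of reproducing linear segments exactly is what the
  tests pin).
* **Centering/scaling**: horizontal coordinates are shifted by the pelvis
  marker-set centroid per frame (a per-trial-mean mode exists — whether the
  original centering was per frame or per trial is not documented, so both
  are provided and the choice is part of the call); the vertical coordinate
  is shifted so the lowest marker position of the trial defines floor
  level zero; all coordinates are divided by subject height, giving
  dimensionless data.

## The synthetic generator

`generateSynthetic()` emulates the study conditions: 11 subjects × 2
conditions × 20 trials, 13 markers, 101 time points (a 440 × 3939 matrix).
Each marker/axis has a smooth two-harmonic base waveform; subject random
effects *multiply* waveform amplitudes (SD 10%) so whitening does not
trivially remove them; trial noise is independent Gaussian per variable
(SD 0.01, i.e. 1 cm on meter-scale waveforms; a t(3) option exists for ICA
stress tests). The condition effect is a Gaussian bump in normalized time
on one marker/axis — by default marker 3, vertical axis, centered at 39% of
stance with width one tenth of the cycle, amplitude 10 × the noise SD
(signal-to-noise ratio 10), mirroring where the real analysis localized the
difference. Raw mode additionally emits frame-rate trajectories and a
half-sine force trace (peak ~1.5 kN) so the preprocessing chain can be
exercised end to end.

The generator returns the planted truth both on the raw scale and as unit
vectors in the whitened space, the latter computed from the realized
per-subject whitening statistics — at high SNR the whitening itself
compresses the effect (the per-variable SD absorbs the amplitude), so the
whitened effect direction is flatter than the raw bump, and it is the
whitened direction a recovered discriminant should align with.
`truthAlignment()` scores recovery as the |cosine| between a planted
direction and its projection onto the recovered subspace.

**What the generator does not emulate.** Real kinematic data gave a
27-dimensional SVM space; a single fixed planted effect gives an exactly
1-dimensional one. The reason is structural: after deflating the mean
discriminant, the per-subject residual effect components sum to
approximately zero across subjects, so no second direction can classify a
significant majority of held-out subjects (held-out folds on deflated
single-effect data in fact classify systematically *below* chance, because
each fold's training residual is anti-correlated with the held-out
subject's). Multi-dimensional SVM spaces require the kind of heterogeneous,
shared secondary structure present in real movements. Consequently the
redundancy property — discriminants separating the same dichotomy have
correlated projections — is exercised on the per-fold discriminants of one
LOSO round, and conditionally on basis pairs whenever a decomposition does
return several vectors. Passing tests therefore demonstrate correctness of
the machinery and recovery of planted structure, not that real gait data
would yield any particular dimensionality. Effect sizes on the synthetic
data are also far larger than published real-data values, because the
planted effect is exactly low-dimensional and the noise homogeneous.

## Problem sizes used by the statistical test suites

The Monte-Carlo acceptance suites keep the full cohort structure (11
subjects × 2 × 20 trials, 101 time points) but reduce the marker count to 4
(1212 variables) for the recovery and ICA-uniqueness suites, and use 8
subjects × 2 × 10 trials of 2 markers at 51 points for the null-termination
suite — sizes chosen so the suites probe the same estimation regime
(variables ≫ classifiable signal, trials per fold ≈ 400) while a full run
of the suite stays inexpensive. SNR (10), seed counts (20/50/20) and pass
fractions (90%/90%/80%) follow the package's acceptance contract. The
recovery criterion asks for |cos| ≥ 0.95 between the planted whitened
direction and its projection onto the recovered SVM space.

## Known limitations

* Linear kernels only; a nonlinear SVM discriminant would not live in the
  data space and the deflation geometry would not apply. No multi-class
  extension.
* No multiple-testing correction across base vectors (the gating procedure
  applies none); reports should be read accordingly.
* Input trials must be complete — no occlusion handling, gap filling, or
  marker relabeling; stance detection requires a force trace.
* The Lilliefors gate needs at least 5 values per group.
* ICA results depend on the random initialization for subspaces of
  dimension ≥ 2; the seed is part of the provenance for exactly this
  reason.
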