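---
title: "Deep Riemannian networks for EEG: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep Riemannian networks for EEG: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riemnet)
```

## The model

Motor-task EEG carries class information chiefly in the *band power* of
oscillations at particular electrodes: imagined movement modulates
sensorimotor rhythms (alpha ~8–13 Hz, beta ~13–30 Hz, and high-gamma
above ~60 Hz). The sample covariance matrix (SCM) of a band-limited trial
summarises exactly this spatial power structure, and SCMs of full-rank
trials are symmetric positive definite (SPD). `riemnet` classifies trials
by learning directly on the SPD manifold.

The end-to-end network is

filterbank → SCM pooling → `n_bire` × (BiMap → ReEig) → LogEig → Vect →
affine head,

with softmax cross-entropy on the head's output. The pieces:

* **Filterbank.** Either free convolution kernels or sinc-parameterised
  bandpass kernels (difference of two windowed sinc low-passes), applied
  per electrode with "valid" convolution. Width `nf` duplicates each
  electrode's signal `nf` times, so the pooled covariance has dimension
  `nf * ne` regardless of whether filters are shared across electrodes
  (channel-independent, ChInd) or tied to single electrodes
  (channel-specific, ChSpec). In ChInd mode the per-band SCMs can either
  be concatenated block-diagonally (no cross-band terms) or pooled as one
  big SCM of the band-stacked signal, whose off-diagonal blocks hold the
  *interband covariance* between electrodes of different bands.
* **BiMap** `Wᵀ C W` compresses the matrix, halving its dimension per
  layer (floor division at odd widths). `W` is constrained to the Stiefel
  manifold so a PD input stays PD.
* **ReEig** floors the spectrum at `reeig_eps`, preventing feature maps
  from approaching the singular boundary; it doubles as the package's
  regulariser for PSD matrices.
* **LogEig/Vect** flatten the manifold via the matrix logarithm and a
  norm-preserving half-vectorisation (√2 weights on off-diagonals), after
  which an affine map produces class scores.

The alternative "searched filterbank" pipeline replaces the learnable
front-end with static sinc filters selected by black-box optimisation of
cross-validated proxy-classifier accuracy (rMDM or tangent-space SVM under
AIRM or LEM), then trains the same SPDNet on the resulting covariances.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `nf` | filters per electrode duplication | 1 | pooled dimension is `nf*ne`; wider banks raise capacity and rank demands |
| `n_bire` | BiMap–ReEig pairs | 3 | halving depth; at small `ne` fewer pairs are usable (an 8-dim SCM halved three times is 1×1, so the worked examples use `n_bire = 1`) |
| `reeig_eps` | rectification threshold | 1e-4 | the value in common use in the SPDNet literature; spectra are floored exactly at it |
| `kernel_len` | filter length (samples) | `fs/4` rounded to odd | ~250 ms window resolving ≥4 Hz structure; odd so sinc kernels are exactly linear-phase |
| `learning_rate`, `weight_decay` | Adam settings | 1e-3, 1e-4 | tuned once on the synthetic fixtures; decay applies to conv kernels, BiMap weights and the affine weight, not to biases or sinc cutoffs (cutoffs are frequencies, not magnitudes to shrink) |
| `cv_folds` | proxy CV folds in the search | 5 | standard stratified choice |

Sinc cutoffs are internally parameterised as `(low, bandwidth)` through a
softplus with Nyquist clamping, so no gradient step or search proposal can
produce `low ≥ high`; bandwidth has a 1 Hz floor.

## Numerical choices

* **Backward through eigendecompositions.** ReEig and LogEig are spectral
  maps `U g(Σ) Uᵀ`; their gradients use the Daleckii–Krein (Loewner)
  quotient `(g(λi) − g(λj)) / (λi − λj)` with the analytic derivative
  substituted when eigenvalues coincide to within 1e-12 relative. The test
  suite verifies the full network gradient against central differences at
  1e-4 relative tolerance for both filter types.
* **Stiefel optimisation.** Riemannian Adam: ambient gradients are
  projected to the tangent space (`G − W sym(WᵀG)`), Adam moments run on
  tangent components, the step is retracted by sign-fixed QR, and the
  first moment is transported by projection at the new point. After any
  number of steps `‖WᵀW − I‖_F` stays below 1e-6 (audited in tests; in
  practice it sits at machine precision).
* **Symmetry policy.** Matrices are symmetrised as `(S + Sᵀ)/2` before
  eigendecomposition when relative asymmetry is below 1e-8; larger
  asymmetry raises an error rather than being silently averaged.
* **AIRM Fréchet mean.** Fixed-point iteration on the manifold with step
  halving on divergence, tolerance 1e-9 on the mean tangent displacement,
  200-iteration cap with an informative error on non-convergence. The LEM
  mean is the closed form `expm(mean(logm))`.
* **Ties and degeneracies.** rMDM breaks exact distance ties toward the
  lowest class index. Tangent features are not standardised before the
  SVM by default (exposed as a flag). Rank-deficient pooled covariances
  (possible when `nt' < nf*ne`) are admitted as PSD and flagged; the first
  BiMap–ReEig pair rectifies them inside the network, and analyses
  regularise explicitly via `regularize_spd()`.
* **Exact Wilcoxon test.** The two-sided signed-rank p-value is computed
  from the exact null distribution by convolution over doubled ranks
  (integral even under average-rank ties), with zero differences dropped
  before ranking. At the small n of paired model comparisons (7–8) a
  normal approximation would be badly wrong; all-same-sign differences
  give exactly `2·2^(−n)`.

## The synthetic generator

`generate_trials()` emulates the statistical structure the method
exploits: spatially mixed 1/f background noise (exponent 1, white floor
−20 dB, AR(1)-style electrode correlation 0.3) plus class-specific
narrowband oscillations planted at chosen electrodes and bands, scaled by
an `snr` amplitude factor. Oscillations are random-phase filtered noise,
not sinusoids, so the class signal lives in covariance rather than phase —
matching what covariance pooling can see. What it does *not* emulate:
volume-conduction forward models, artifacts (EMG, blinks), nonstationarity
across a session, or inter-subject variability. Passing tests therefore
show the machinery is correct and that band-power structure is recovered
when present; they do not certify decoding accuracy on real recordings.

Canonical fixtures (`make_fixture()`): `easy4` (four disjoint canonical
bands at distinct electrode pairs, snr 4), `hard4` (overlapping bands,
snr 1), `singleband` (one informative 10–20 Hz band; classes differ only
in which electrode carries it — the search-recovery target), and
`multiband` (one class with power in two disjoint bands, 8–14 and
40–50 Hz, so a single optimal filter must pass both).

## Design decisions where the design was open

* **SCM centering** is on by default (standard covariance semantics) with
  a flag to disable; all invariants hold either way.
* **Vectorisation length** is `n(n+1)/2` — the count of unique elements of
  a symmetric matrix — with √2 off-diagonal weights.
* **Band-major row order** (filter index outer, electrode inner) is fixed
  and enforced everywhere, so ChInd blocks are contiguous and the
  electrode index map is `rep(1:ne, nf)`.
* **Search backend.** Any black-box optimiser fits behind the
  propose/observe loop; the built-in one is a per-dimension
  Parzen-estimator density-ratio sampler (TPE-style) with a quarter-budget
  random initialisation and a 15% uniform-exploration floor thereafter —
  pure exploitation stalls when all incumbents sit in a flat region of the
  objective.
* **Gain spectra** use Welch-style averaged amplitude spectra
  (Hamming-windowed, half-overlapping segments, shared segment length for
  pre/post so the grids match), gain in `20·log10` dB. `-Inf` bins are
  linearly interpolated; spectra with more than 50% such bins are
  discarded, not errored.
* **Peak counting** smooths by a 2 Hz moving average, zeroes around the
  median, and requires peaks to clear both 25% of the smoothed maximum
  and an absolute 3 dB floor (the half-power convention) at ≥2 Hz width —
  without the absolute floor, flat ±1 dB ripple of an untrained or
  all-pass filter would count as passbands.
* **Relevance** uses raw class-score gradients at the pooled covariance
  (not gradient×input), summed across matrix rows, weighted by each
  filter's min–max-normalised gain spectrum, and averaged trials →
  filters; per-filter (rather than global) normalisation keeps weak
  filters comparable.
* **Layer-by-layer probes** are a LEM tangent-space SVM and a Euclidean
  SVM on vectorised maps, fitted on training maps only.
* **Serialisation** is plain text: JSON checkpoints and CSV/JSON trial
  containers, keeping artefacts diffable and portable.

## Problem sizes in the shipped experiments

The test suite and acceptance script run deliberately small cohorts: 8
electrodes × 400 samples at 200 Hz (easy cohort, 3 seeds, 30 epochs), 4
electrodes × 256 samples at 128 Hz for the search (10 runs × 100 scored
banks) and multiband (10 runs × 60 epochs per filter type) experiments,
and ≥100 randomized instances per algebraic invariant. These sizes were
chosen so a complete run finishes in minutes on one CPU while every
qualitative effect — planted-band recovery, conv-learns-multiband versus
sinc-cannot, zero below-threshold eigenvalues after rectification — is
still resolved with margin.

## Known limitations

* No GPU or batched BLAS path; the backward pass loops over trials (fine
  for research-scale matrices, slow for `nf*ne` in the hundreds).
* No shrinkage/robust covariance estimators — the plain SCM is the
  estimator of record here.
* The AIRM Fréchet mean is iterative; for very ill-conditioned inputs the
  iteration can hit its cap and errors rather than returning a bad mean.
* `n_bire = 0` sends the raw pooled covariance to LogEig, which requires
  strict positive definiteness; regularise first or use at least one
  BiMap–ReEig pair.
* The EDF/HDF5 containers used by some EEG toolchains are not read
  natively; trials enter through R matrices or the plain-text container.
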