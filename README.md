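# riemnet

Deep Riemannian networks for multichannel EEG decoding, in R.

Brain-computer interfaces decode imagined movement from the spatial
covariance of band-limited EEG. The covariance of a trial
`T ∈ R^(Ne×Nt)` (electrodes × samples),

    C = T Tᵀ / (Nt − 1),

is a symmetric positive-definite (SPD) matrix, and the set of SPD matrices
forms a curved Riemannian manifold. `riemnet` implements an end-to-end
deep network that operates on this manifold:

    trial → learnable filterbank (conv or sinc) → SCM pooling
          → NBiRe × (BiMap → ReEig) → LogEig → Vect → affine classifier

* **BiMap**: `C ↦ Wᵀ C W` with `W` constrained to the Stiefel manifold
  (orthonormal columns), the SPD analogue of a dense layer.
* **ReEig**: `C ↦ U max(εI, Σ) Uᵀ`, eigenvalue rectification — the SPD
  analogue of a ReLU, with ε = 1e-4 by default.
* **LogEig**: `C ↦ U log(Σ) Uᵀ`, mapping the manifold to a flat space
  before classification; **Vect** stacks the unique entries with √2 on
  off-diagonals so vector 2-norms equal Frobenius norms.

The filterbank front-end is learned jointly with the network (free
convolution kernels, or sinc-parameterised bandpass filters whose only
parameters are the cutoff frequencies), with channel-independent (each
filter applied to every electrode) or channel-specific (one filter per
electrode) modes and optional cross-band ("interband") covariance.
Training uses a Riemannian Adam scheme: Stiefel weights take
tangent-projected gradients with QR retraction every step; everything
else follows standard Adam. Backpropagation through the eigendecomposition
layers uses the Daleckii–Krein (Loewner) formula and is verified against
central differences in the test suite.

Alternatively, the filterbank can be chosen *before* training by a
budgeted black-box search (`fb_search()`): candidate sinc cutoff pairs are
scored by cross-validated accuracy of lightweight Riemannian proxy
classifiers — minimum distance to Riemannian mean (`rmdm_fit()`) or a
tangent-space SVM (`rsvm_fit()`), under the affine-invariant (AIRM) or
log-Euclidean (LEM) metric.

An analysis toolkit inspects trained models: frequency gain spectra
(`frequency_gain()`), multiband peak counting (`count_peaks()`),
layer-by-layer probe classification (`layer_by_layer()`), eigenvalue
threshold audits (`eig_below_threshold()`), first-layer BiMap gain maps
(`bimap_gain()`), and gradient-based electrode-frequency relevance
(`electrode_frequency_relevance()`). A synthetic EEG generator
(`generate_trials()`, `make_fixture()`) plants class-dependent band power
at chosen electrodes in 1/f background noise so the whole pipeline can be
exercised without real recordings. Exact Wilcoxon signed-rank p-values
for paired model comparisons come from `wilcoxon_exact()`.

## Worked example

```r
library(riemnet)

fx <- make_fixture("easy4", seed = 101)      # 4 planted bands, 8 electrodes
sp <- split_trials(fx$trials, 0.75, seed = 1)

cfg <- network_config(ne = 8, n_classes = 4, fs = 200,
                      nf = 1, n_bire = 1, kind = "conv", seed = 1)
fit <- spdnet_train(spdnet_init(cfg), sp$train,
                    train_config(epochs = 30, seed = 1))

tail(tidy(fit), 1)
#> # A tibble: 1 × 2
#>   epoch  loss
#>   <int> <dbl>
#> 1    30 0.604

spdnet_accuracy(fit, sp$test)
#> [1] 100
```

The loss is the softmax cross-entropy on the training split (chance level
for 4 classes is `log 4 ≈ 1.39`); the accuracy is percent correct on the
unseen test split. `autoplot(frequency_gain(fit, sp$train))` then shows
which frequency regions the learned filter amplifies, and
`layer_by_layer(fit, sp$train, sp$test)` compares each internal stage
against Euclidean and Riemannian probes.

Filterbank search on a cohort whose class information lives in a single
band:

```r
fx <- make_fixture("singleband", seed = 207)
res <- fb_search(fx$trials, search_config(nf = 1, metric = "lem",
                                          proxy = "rmdm", max_trials = 100,
                                          seed = 7))
res
#> <fb_search_result> 100 trials, best CV accuracy 100.0%
#>   filter 1: 7.6-10.8 Hz
```

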