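# safpn

Per-pixel crop classification from multispectral satellite image time
series with a **(3+2)D Split-Attention Feature Pyramid Network** — and the
full desk-scale workflow around it: synthetic scene generation, raster
time-series i/o, leakage-free patch-level dataset splits, training,
accuracy assessment, temporal class-activation analysis, and planted-area
statistics.

## Who this is for

Remote-sensing researchers who want a self-contained, CPU-scale, fully
testable implementation of a hybrid 3D/2D crop-mapping architecture:
every layer's forward *and* backward pass is written out in R (convolutions
run as per-kernel-offset BLAS products with small C++ gather kernels), so
the method is inspectable end to end and verifiable against
finite-difference gradients — no deep-learning framework required.

## The model

An input patch is a stack of T acquisitions × B spectral bands × H × W
pixels. A 3D convolutional stem extracts a spatiotemporal feature volume;
after temporal collapse, a four-stage 2D encoder produces maps c2…c5 which
a feature pyramid fuses top-down with lateral connections, applying a
**split-attention** block at every level: channels are split into *r*
branches, summed, squeezed through a pooled dense bottleneck, and
reweighted per channel with a softmax across branches (*r*-softmax,
Σᵢ Aᵢ = 1), the output being the convex combination Σᵢ Aᵢ⊙Xᵢ. Two heads
finish the network: per-pixel class logits, and a per-date NDVI regression
trained against the observed series
NDVI = (NIR − RED)/(NIR + RED).

The objective couples a **focal loss** −αₜ(1−pₜ)^γ log pₜ (γ = 2, per-class
α vector emphasising rare crops) with the NDVI mean-squared error.
Accuracy is assessed through confusion matrices: overall accuracy
OA = Σaᵢᵢ/N, per-class precision aᵢᵢ/a₊ᵢ, recall aᵢᵢ/aᵢ₊, F1, chance
agreement p_c = Σ(aᵢ₊·a₊ᵢ)/N², and Cohen's kappa (OA − p_c)/(1 − p_c).

## Worked example

```r
library(safpn)

# synthetic eight-class scene: double-logistic phenologies, parcel labels,
# strong class imbalance, inter-row mixed-cropping confusion
recipe <- talhu_recipe(noise_sd = 0.05, seed = 1)
train  <- render_patch_set(recipe, 60, patch_size = 24, seed = 1)
val    <- render_patch_set(recipe, 15, patch_size = 24, seed = 2001)

cfg <- safpn_config(stage_channels = c(16, 32, 64, 64), pyramid_channels = 16,
                    n_classes = 8, n_dates = 20, n_bands = 4, patch_size = 24,
                    stem_channels = 8)
fit <- safpn_train(train, val, cfg, loss_config(focal_weight = 6),
                   train_config(epochs = 8, batch_size = 8, lr = 0.05,
                                lr_schedule = "step", lr_step = 6,
                                lr_gamma = 0.2, seed = 1))
fit
#> (3+2)D SAFPN: plain stages 16-32-64-64, pyramid 16, 8 classes, T=20, 167041 params
#> trained 8 epoch(s) on 60 patches; best val OA 0.5939 at epoch 8

ev <- evaluate_model(fit, render_patch_set(recipe, 15, 24, seed = 4001))
round(c(OA = ev$metrics$oa, kappa = ev$metrics$kappa), 3)
#>    OA kappa
#> 0.606 0.516
```

Eight epochs on 60 patches is only a smoke run; `run_learning_experiment()`
is the packaged benchmark (200/60/60 patches, wider network, longer
schedule) and exceeds 0.90 held-out overall accuracy. The printed OA is
the fraction of correctly labelled pixels on held-out patches; kappa
corrects it for chance agreement between the marginal class
distributions.

Planted-area statistics convert predicted pixel counts to hectares
(10 m pixels → 100 m² each):

```r
area_from_counts(c(maize = 890951), resolution_m = 10)
#>   class pixel_count  area_m2 area_ha
#> 1 maize      890951 89095100 8909.51
```

A command-line pipeline (`simulate | split | train | evaluate | predict |
map-area | cai`) is exposed through `safpn_cli()` and the thin wrapper
script `inst/cli/safpn`, driven by one YAML config.

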