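# octseg

Segmentation of sub-retinal layers in OCT B-scans with a hybrid attention
U-Net, implemented end-to-end in R.

## The problem

Optical coherence tomography (OCT) images the retina in cross-section;
clinicians read disease from the geometry of its layered bands.  `octseg`
assigns every pixel of a B-scan to one of five ordered regions — above the
ILM, ILM–IPL/INL, IPL/INL–RPE, RPE–BM, and under BM — a task where boundary
fidelity matters as much as region overlap, because bands like RPE–BM are
only a few pixels thick.  The package is for researchers who need a
transparent, dependency-light reference implementation of this architecture
family, with every numerical piece (network, optimiser, statistics)
testable against independent oracles.

## The model

A five-level encoder–decoder U-Net with three modifications:

* **Residual skips** — max pooling sends each window's maximum
  `p = max(W)` down the encoder and the skip carries the complement: the
  feature map with that argmax pixel zeroed, so scatter(pooled) + residual
  reconstructs the input exactly.
* **Edge attention (EA)** on the two shallowest skips — per channel
  `F = x * K_t + x * K_l` (true convolution with the 3×3 Sobel
  transverse/longitudinal pair), fused additively with the skip, then gated
  by additive attention `α = σ(ψ(ReLU(W_s·s + W_g·g))) ∈ [0,1]`.
* **Spatial attention (SA)** on the three deepest skips —
  `α = (σ(maxpool_c(X)) + σ(avgpool_c(X)))/2` from channel-wise max/average
  maps, applied per pixel.

Training follows a fixed protocol: composite loss with weights (1, 0, 1)
over cross-entropy, Dice loss and boundary-band cross-entropy; AdaBound
(lr 0.001 → bounds converging to 0.1); ×0.1 plateau reduction after 5
stagnant epochs; early stop after 10; checkpoint restoration each 100
epochs; batch size 4; 6-fold cross-validation.  Evaluation reports
per-class precision/recall/F1/Dice (`Dice = 2TP/(2TP+FN+FP)`), boundary
IoU, and chance-corrected agreement statistics (Cohen's κ, Bennett S,
Bangdiwala B, adjusted Rand index, Hamming loss, χ² degrees of freedom).

No deep-learning framework is used: convolutions (im2col + BLAS GEMM),
batch norm, transposed convolutions, both attention blocks, and the
AdaBound optimiser are implemented in the package (R + Rcpp/Armadillo),
with an end-to-end finite-difference test on every layer's gradient.

## A worked example

Synthetic layered B-scans (five bands, smooth non-crossing boundaries,
multiplicative speckle) stand in for clinical data, so everything runs
without a download:

```r
library(octseg)
cfg   <- synth_config(height = 64, width = 32, seed = 1)
ds    <- generate_dataset(cfg, 60)$pairs
model <- build_model(model_config(depth = 5, base_channels = 8,
                                  input_shape = c(64L, 32L)))
fit   <- train_model(model, ds, train_config(max_epochs = 6, seed = 11),
                     verbose = TRUE)
#> epoch   1  train 3.4709  val 3.0591  dice 0.2797  lr 0.001
#> ...
#> epoch   6  train 1.5996  val 1.4635  dice 0.6988  lr 0.001
report <- evaluate_model(fit, ds[fit$val_idx])
print(report)
#> Segmentation report over 12 image(s)
#>  class precision recall     f1   dice   biou
#>      0    0.5753 0.9438 0.7149 0.7149 0.2439
#>      1    0.5249 0.3803 0.4410 0.4410 0.3944
#>      2    0.8622 0.9390 0.8990 0.8990 0.6909
#>      3    0.9069 0.9442 0.9252 0.9252 0.8177
#>      4    0.7268 0.3977 0.5141 0.5141 0.2591
#> mean Dice 0.6988 | mean BIoU 0.4812 | accuracy 0.7168
#> kappa 0.6466 (Substantial) | Bennett S 0.6459 (Substantial) | Bangdiwala B 0.5869 (Moderate)
#> ARI 0.5110 (Intermediate to Good) | Hamming loss 0.2832 | chi-squared DF 16
```

(Numbers above are from a 6-epoch demonstration run; the acceptance
configuration below trains longer on more data and reaches mean Dice
above 0.99 on held-out synthetic scans.)  A thin CLI wraps the same
functions: `exec/octseg synth|preprocess|augment|train|crossval|evaluate|predict`.

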