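# fishseg

Attention-augmented pyramid scene parsing for underwater fish segmentation —
a CPU-only, dependency-light R implementation.

## What this is for

Segmenting fish from underwater imagery is hard because the images are
blurred, colour-distorted and low-contrast: a fish often differs from the
water behind it by little more than a soft edge. `fishseg` implements a
PSPNet-style binary segmentation model (dilated ResNet50 encoder at output
stride 8 + pyramid pooling module) together with three additions aimed at
that regime, and everything needed to study them without a GPU or an external
dataset:

* **iAFF** — iterative attentional feature fusion replacing the residual sum
  `X + Y` in every backbone block:
  `Z = M(X ⊎ Y) ⊗ X + (1 − M(X ⊎ Y)) ⊗ Y`, where the initial integration
  `X ⊎ Y = M(X+Y) ⊗ X + (1−M(X+Y)) ⊗ Y` and `M(·) ∈ (0,1)` is a multi-scale
  channel attention module (MS-CAM: global-pooled + per-pixel 1×1 bottleneck,
  sigmoid). Every output is an elementwise convex combination of `X` and `Y`.
* **SoftPool** — softmax-of-activations weighted pooling,
  `ã = Σᵢ e^{aᵢ}·aᵢ / Σⱼ e^{aⱼ}` over each window: parameter-free, bounded
  between average and max pooling, full gradient flow.
* **Triplet attention (TA)** — Z-pool (`(C,H,W) → (2,H,W)` max‖mean) feeding a
  7×7 conv + sigmoid gate on three rotated views, averaged; one parameter set
  (~300 weights) shared across all four pyramid scales.

The four ablation variants — `PSPNet`, `I-PSPNet`, `IS-PSPNet`, `IST-PSPNet`
— toggle these additions cumulatively (`model_variants()`).

Because no deep-learning framework is available in the target environment,
the package ships a minimal reverse-mode autograd (R arrays + Rcpp kernels +
BLAS); gradients are verified against finite differences in the tests.

## Worked example

```r
library(fishseg)

## synthetic low-contrast fixtures with exact masks
recs <- generate_fixtures(fixture_config(n_samples = 16, seed = 11))
prep <- lapply(recs, function(r) preprocess(r$image, r$mask, target = 96))

## 5-epoch smoke training of the full model at fixture scale
set.seed(101)
model <- build_model("IST-PSPNet")
fit <- train_model(model, prep,
                   config = train_config(epochs = 5, batch_size = 2,
                                         image_size = 96, seed = 1))
round(fit$history$train_loss, 4)
#> [1] 2.9718 0.3723 0.2716 0.2386 0.2352
```

The mean training loss falls from 2.97 to 0.24 in five epochs (~5 CPU
minutes): the full 53 M-parameter model optimises end to end on a laptop-class
CPU. Predictions come back in source geometry:

```r
mask <- predict_mask(model, recs[[1]]$image, image_size = 96)
table(mask)   # pixel counts per class, 0 = background, 1 = fish
```

The architecture audit reproduces the published budget table where a faithful
reconstruction can (analytic counting, no forward pass):

```r
audit_variants()
#>      variant params_M gflops_G
#>       PSPNet    46.71    46.09
#>     I-PSPNet    53.17    49.47
#>    IS-PSPNet    53.17    49.47
#>   IST-PSPNet    53.17    49.47
attributes(audit_variants())[c("input_size", "convention")]
#> $input_size [1] 256   $convention [1] "mac"
```

Baseline 46.71 M / 46.09 G vs printed 46.70 M / 45.93 G; iAFF +6.46 M vs
printed +6.4 M; TA +300 parameters (0.00 M) under sharing. The printed
IS/IST budgets (46.48 M / 40.27 G) attribute a 6.62 M saving to the
parameter-free SoftPool swap and are not reproducible; `audit_variants()`
carries the caveat in its `note` attribute and the vignette analyses it.

## Command line

```sh
inst/cli/fishseg fixtures --out fx --n 16 --seed 1      # synthetic dataset
inst/cli/fishseg train --data fx --out run --epochs 5 --image-size 96 --batch-size 2
inst/cli/fishseg eval --data fx --checkpoint run/checkpoint.rds --split test --image-size 96
inst/cli/fishseg predict --checkpoint run/checkpoint.rds --image fx/images/sample_0001.png --out mask.png --image-size 96
inst/cli/fishseg audit --out audit.csv                  # parameter/FLOP budget report
```

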