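# virtualstain

Virtual staining of label-free microscopy: `virtualstain` trains a
conditional generative adversarial network (cGAN) that translates a
multi-slice bright-field z-stack of cells into three virtually stained
fluorescence channels — lipid droplets, cytoplasm and nuclei — and then
quantifies the result the way a cell-profiling pipeline would quantify a
chemical stain. It is aimed at microscopists and image-analysis
developers who want to study, test or prototype label-free staining
workflows on a single CPU, with a built-in synthetic phantom generator
providing paired data and exact ground truth.

## The model

The generator G maps a normalized bright-field stack
x ∈ [0, 1]^(H×W×7) to a stained image ŷ = G(x) ∈ [0, 1]^(H×W×3)
(U-Net: 3×3 convolutions, ReLU, 2×2 max pooling, skip connections,
sigmoid output). A conditional patch discriminator D scores (x, y) pairs.
Training alternates Adam updates of

    ℓ_disc = BCE(D(x, y), 1) + BCE(D(x, G(x)), 0)
    ℓ_gen  = BCE(D(x, G(x)), 1) + λ · mean|G(x) − y|,   λ = 100

(pix2pix convention; a perfectly confused discriminator sits at 2·ln 2).
A single-channel U-Net baseline trained with MSE under the same
configuration is included: as a conditional-mean estimator it blurs
whatever the bright-field stack underdetermines, whereas the adversarial
model commits to a plausible mode — the package demonstrates both
behaviours on a one-to-many toy problem in its test suite.

Downstream, predictions and targets are evaluated with nMAE_px
(mean absolute error normalized by the target mean), SSIM and PSNR;
segmented with a CellProfiler-equivalent pipeline (nuclei first by
adaptive-threshold + shape declumping, cytoplasm as secondary objects by
seeded propagation, lipid droplets by two size-targeted global-threshold
passes with intensity declumping); summarized as five features per
structure (count, mean area, integrated intensity, mean intensity, sd of
mean intensities); and compared with per-image normalized errors
(nMAE_cp), Pearson correlations with Fisher-z 95% confidence intervals,
and two-tailed Student t tests with significance stars.

## Worked example

Train on 200 synthetic 64-px fields (one adipocyte-like cell each, 7
defocus slices) for 200 epochs, then evaluate on 15 held-out fields —
about 15 minutes on one CPU:

```r
library(virtualstain)

train <- phantom_pairs(200, seed = 1000)
val   <- phantom_pairs(15,  seed = 5000)

fit <- fit_cgan(train, val,
                config = train_config(epochs = 200, val_every = 10, seed = 1))
print(fit)
#> Conditional GAN virtual-staining model
#>   generator: depth 3, width 8, 7 -> 3 channels (42723 parameters)
#>   discriminator: depth 3, width 8 (6569 parameters)
#>   trained 200 epochs, lambda = 100; best epoch 200 (mean val nMAE_px 0.535)

preds   <- predict(fit, val)
metrics <- evaluate_set(preds, lapply(val, `[[`, "y"))
print(metrics)
#> Image-quality metrics over 15 image(s):
#>     channel nmae_mean nmae_sd ssim_mean ssim_sd psnr_mean psnr_sd
#> 1  droplets     0.305  0.0376     0.939  0.0173      33.2   2.671
#> 2 cytoplasm     0.445  0.0951     0.859  0.0411      34.4   2.296
#> 3    nuclei     0.775  0.0185     0.915  0.0074      29.3   0.681
```

Lipid droplets — clearly visible in bright-field thanks to their high
refractive index — are reproduced best (nMAE_px 0.31, SSIM 0.94).
Nuclei have zero optical contrast in the phantom's bright-field stack,
so every nucleus pixel must be inferred from context; their structure is
still largely recovered (SSIM 0.92) even though absolute intensities are
not (nMAE_px 0.78).

Profiling the virtual stains like chemical ones:

```r
pp <- profiling_params(nucleus_diameter = c(8, 40))  # 64-px field scale
prof_t <- do.call(rbind, lapply(seq_along(val), function(i)
  profile_image(val[[i]]$y, pp, image_id = paste0("v", i))$features))
prof_p <- do.call(rbind, lapply(seq_along(val), function(i)
  profile_image(preds[[i]], pp, image_id = paste0("v", i))$features))
report <- build_report(prof_p, prof_t)
print(report)
#>      class              feature target_mean pred_mean      mae nmae_pct     rho stars
#>   droplets                count    4.27e+00  4.00e+00 2.67e-01     6.67  0.8554    ns
#>   droplets            mean_area    5.81e+01  5.39e+01 8.80e+00    14.96  0.5469    ns
#>   droplets integrated_intensity    6.78e+01  5.39e+01 1.39e+01    20.10  0.9656    ns
#>   droplets       mean_intensity    2.66e-01  2.47e-01 1.96e-02     7.14  0.6610    ns
#>   ...
```

The droplet count is recovered with a 6.7% per-image error and a
correlation of 0.86 between virtual and chemical measurements — the
pattern that matters for comparative biology: deviations are systematic,
so between-sample comparisons survive, which is exactly what the high
integrated-intensity correlation (0.97) shows.

The same workflow is available from the shell via the thin CLI at
`inst/cli/virtualstain.R` (`simulate`, `train-cgan`, `train-unet`,
`predict`, `evaluate`, `profile`, `report`, `run`), and end-to-end via
`run_pipeline(run_config())`, which writes TIFFs, CSV tables and a
manifest.

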