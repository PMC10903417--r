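---
title: "Virtual staining from bright-field stacks: models, phantom and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual staining from bright-field stacks: models, phantom and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Fluorescence staining is the standard route to quantitative measurements of
cell structures — in adipocytes, typically lipid droplets, cytoplasm and
nuclei — but chemical dyes are invasive, phototoxic, expensive, and consume
spectral channels. Bright-field images are cheap and harmless, and a
defocus z-stack carries substantial (if implicit) information about the
same structures: lipid droplets have a high refractive index and are
clearly visible, the cytoplasm is faint, and nuclei are essentially
invisible because their refractive index matches the surrounding
cytoplasm.

`virtualstain` learns the mapping from a multi-slice bright-field stack to
the three fluorescence channels with a conditional generative adversarial
network (cGAN), and then treats the generated images exactly like real
stains: it segments the structures, extracts per-structure features, and
compares virtually and chemically stained feature tables statistically.

# The models

## Generator

The generator is a fully convolutional U-Net: an encoder of 3×3
convolutions with ReLU activations and 2×2 max pooling, a bottleneck, and
a decoder of nearest-neighbour upsamplings, skip concatenations and 3×3
convolutions, finishing in a 1×1 convolution with a sigmoid. The sigmoid
bounds every prediction to the normalized intensity range [0, 1], the
same range in which inputs and targets live (raw 16-bit values divided by
the fixed constant 65535 — never per-image min–max, so intensity features
remain comparable across images; targets are deliberately *not* z-scored).

Defaults are `depth = 3`, base `width = 8`, doubling per stage with the
bottleneck held at the deepest encoder width. These are deliberately
small: the package targets single-CPU experimentation, and on the
synthetic phantom the small generator already learns the visible
structures well while keeping a 200-epoch run on 200 fields in the
minutes range. Depth and width are free parameters of
`generator_config()`; fields must be divisible by `2^depth`.

Convolutions use zero padding. One consequence worth knowing: a constant
input does not map to an exactly constant output near the field border
(a band of roughly one receptive-field radius is perturbed), and tiled
inference can only approximate whole-field inference. `predict_tiled()`
therefore blends overlapping tiles with a Hann window, which gives the
(zero-pad-affected) tile borders near-zero weight; with tiles well beyond
the receptive field (128 px tiles, 64 px overlap for the default depth)
the stitched prediction agrees with whole-field inference to about 1e-2
maximum and 1e-3 mean absolute difference even for a random-weight
network, and seams are not detectable above that level.

## Discriminator

The discriminator is conditional and patch-based: it sees the bright-field
stack concatenated with a candidate fluorescence image and applies a stack
of stride-2 3×3 convolutions with leaky-ReLU (0.2) activations and a final
1×1 convolution, producing a spatial map of unbounded logits — one
realism judgement per receptive-field patch. With `depth = 3` a 64 px
field yields an 8×8 score map.

## Losses and training

Training follows the pix2pix convention. Per batch:

* discriminator: `BCE(D(x, y), 1) + BCE(D(x, G(x)), 0)`, with the
  generator detached. A perfectly confused discriminator (probability 0.5
  everywhere) sits at `2 ln 2` per real/fake pair — a useful anchor when
  reading training curves.
* generator: the non-saturating adversarial term `BCE(D(x, G(x)), 1)`
  plus `lambda` times the mean absolute (L1) reconstruction error,
  `lambda = 100` by default. L1 was chosen over L2 because the package's
  headline evaluation metric is an absolute-error metric (nMAE).

Both networks use Adam with learning rate 2e-4 and moments (0.5, 0.999),
the standard stable-GAN setting. Training crops (default 48 px) are
sampled randomly per step with 90° rotations and flips only — geometric
augmentations that do not distort intensities, which matter downstream.
48 px crops were chosen over 64 px after measuring identical validation
quality at roughly 60 % of the compute; the receptive field still covers
the crop. Batch size is 8. Validation nMAE_px per channel is computed at
`val_every` epochs and the generator with the lowest mean validation
nMAE_px is kept as the fitted model.

`train_config()` exposes one non-standard knob, `disc_input_noise`:
Gaussian instance noise added to both real and generated images before
the discriminator. It is 0 by default and irrelevant for normal datasets.
On degenerate training sets with very few distinct targets (such as the
two-image toy below) the discriminator memorizes the real images and the
generator's gradient field collapses; instance noise smooths the decision
landscape and restores learning.

## The U-Net baseline

`fit_unet()` trains the same encoder–decoder with a single output channel
under a pure MSE objective, one instance per fluorescence channel, under
the *same* `train_config()`. The contrast between the two estimators is
the scientific point: an MSE regressor approximates the per-pixel
conditional mean of the target distribution, so wherever the bright-field
stack underdetermines the stain (nuclei, irreproducible cytoplasm
texture) it predicts a blur "between" the possibilities. The adversarial
model is pushed toward outputs that look like *some* real staining — a
mode of the conditional distribution rather than its mean.

The package demonstrates this mechanism on a one-to-many toy mapping: a
fixed input whose target is, with equal probability, a uniformly bright
or a uniformly dark image. The MSE model converges to the mid-grey mean;
the cGAN, trained with `lambda = 0` and `disc_input_noise = 0.3`, commits
to one of the two modes. Two toy-specific choices deserve explanation.
First, `lambda = 0`: between the two modes every output has *identical*
expected L1 error, so the reconstruction term contains no mode
information at all — it contributes only mean-reverting gradient noise
from finite batches, which at this tiny scale swamps the weak
symmetry-breaking adversarial signal. Second, the instance noise: with
only two distinct real images the discriminator otherwise memorizes them
and digs a flat-gradient well around the generator's current output,
freezing it near the mean.

# The phantom

`phantom_params()` / `sample_scene()` / `render_fluorescence()` /
`render_brightfield()` generate paired data with exact ground truth. The
phantom reproduces the *statistical structure* the method rests on, not
the optics:

* Geometry: a few cells per field; each has a smooth star-convex
  cytoplasm blob (Fourier-perturbed radius) guaranteed to contain an
  elliptical nucleus; nucleus centres are rejection-sampled to be at
  least one mean nucleus diameter apart; lipid droplets are placed inside
  the cytoplasm, outside the nucleus, and by default without mutual
  overlap. Droplet radii come from two log-normal populations (medians
  4 px and 15 px at the default 256 px field scale), motivating the
  two-pass droplet segmentation.
* Fluorescence: per-channel foreground levels (droplets 20 000,
  cytoplasm 4 000, nuclei 15 000 counts on the 16-bit scale) over small
  backgrounds; a multiplicative low-pass texture on the cytoplasm
  emulates uneven dye reaction — deliberately seeded noise that no
  predictor can recover, mirroring the irreproducible component of real
  cytoplasm stains; large droplets optionally carry a darker interior
  dip; a small Gaussian point-spread blur; camera noise with a read
  (Gaussian) and a shot (variance ∝ signal) component.
* Bright-field: a defocus stack in which each droplet is a
  difference-of-Gaussians ring whose signed central contrast varies
  linearly with slice defocus and flips polarity across the stack — a
  cheap, monotone stand-in for through-focus contrast inversion, enough
  to give the stack non-trivial axial information. The cytoplasm adds a
  weak textured offset; nuclei have zero contrast weight by default, so
  their pixels are statistically indistinguishable from the surrounding
  cytoplasm and any successful nucleus prediction must come from
  context. A per-field linear regression confirms the stack explains far
  more variance of the droplet channel than of the nucleus channel.

What the phantom does **not** emulate: physical light propagation,
3-D sectioning, stain spectra, cell-to-cell biological variability,
imaging artefacts (vignetting, drift, debris). Passing tests on the
phantom therefore show that the pipeline's machinery is correct and that
the adversarial model behaves as designed — not that any particular
accuracy will be reached on real microscope data.

All phantom outputs are bit-reproducible given a seed, and
`make_dataset()` writes them as uncompressed multi-page 16-bit TIFFs
(bright-field slices in z-order; fluorescence channels ordered droplets,
cytoplasm, nuclei; ground-truth label maps) with a JSON index.

# Evaluation metrics

* `nmae_px(pred, target)` = mean |difference| divided by the mean of the
  target image. This normalization is the one consistent with published
  per-channel MAE/target pairs (an MAE of 150 counts on a target of mean
  1300 counts is 12 %), and it is invariant under joint rescaling, so it
  does not matter whether it is computed on raw 16-bit or normalized
  data. A zero-mean target is an error, not a silent NaN.
* `ssim()` uses the canonical constants: Gaussian window 11 px, sigma
  1.5, K1 = 0.01, K2 = 0.03, declared dynamic range (1 for normalized
  images); local statistics use edge-replication padding; the SSIM map is
  averaged over all pixels. The test suite pins it against an independent
  direct-convolution reference to 1e-6.
* `psnr()` = 20·log10(MAX) − 10·log10(MSE), `Inf` for identical images.
* `evaluate_set()` aggregates each metric as mean ± sample standard
  deviation over the validation images (a single pair reports sd 0).

# Profiling (CellProfiler-equivalent)

Segmentation follows the cell-profiling convention, re-implemented on
EBImage primitives rather than calling CellProfiler:

1. **Nuclei first**: adaptive threshold (block-wise Otsu on a 50 px
   window, bilinearly interpolated to a per-pixel threshold surface, with
   block thresholds clipped to [0.7, 1.5]× the global Otsu value so
   background-only blocks cannot hallucinate foreground), hole filling,
   then *shape* declumping — watershed on the distance transform, which
   splits clumps at necks. A wide diameter range is accepted.
2. **Cytoplasm as secondary objects**: one object per nucleus seed, grown
   by constrained propagation (`EBImage::propagate`, the same algorithm
   CellProfiler uses) over a foreground obtained with a *larger* adaptive
   window (200 px). Secondary objects are supersets of their seeds and
   inherit seed labels, so their count always equals the nucleus count.
3. **Droplets independently, in two passes**: global Otsu thresholds with
   *intensity* declumping (watershed on smoothed intensity, splitting at
   saddle points — droplets are consistently round, so shape carries no
   declumping information, but clumped droplets differ in peak
   intensity). A small-diameter pass and a large-diameter pass are
   merged: every large-pass object is kept, and a small-pass object is
   added unless more than 50 % of its area overlaps a large-pass object.
   With identical parameter sets the merge reduces exactly to a single
   pass.

Numerical details that matter: pre-smoothing sigmas default to 1 px
(calibrated on noiseless phantoms so that Otsu-thresholded masks
reproduce true object areas to within a few percent — heavier smoothing
dilates objects at a fixed threshold); watershed tolerances default to
1 px of distance-map depth (shape) and 0.03 intensity units (intensity);
the minimum-seed-separation neighbourhood is a quarter of the minimum
expected diameter; labels are relabelled contiguously after size
filtering; coordinates are pixel-centre, row-major, 0-based. An
all-background image yields an empty label map (a warning, not an error,
when an adaptive threshold is undefined on a constant image).

`extract_features()` computes the five features per structure class:
count, mean area (px), integrated intensity (sum over all object pixels),
mean intensity (mean over objects of per-object means) and the standard
deviation of the per-object mean intensities. Intensities are measured on
[0, 1]-rescaled images. Two conventions are deliberate and documented:
the **population** (n) standard deviation is used for the per-object
spread — "the standard deviation of their mean intensity" is genuinely
ambiguous (it could also mean the within-object intensity sd averaged
over objects) and the table-level aggregates cannot disambiguate it; and
an empty label map reports count 0 with `NA` for the remaining features.

# Comparison statistics

`nmae_cp()` normalizes per image — `|pred_i − target_i| / target_i`,
aggregated as mean ± sd in percent — exactly the per-image definition,
with the ratio-of-aggregates reported alongside as a diagnostic.
Zero-target images are excluded with a warning and counted.
`pearson_ci()` gives the sample correlation with a Fisher-z interval
(degenerate `[rho, rho]` at |rho| = 1). `ttest_stars()` is the
equal-variance two-tailed Student t test ("Student", not Welch, is the
declared test), with stars mapped ns / * / ** / *** / **** at 0.05, 0.01,
0.001, 0.0001, always choosing the most significant applicable category.
All "± sd" aggregates use the sample (n−1) convention; the per-object
spread inside `extract_features()` is the only population-sd quantity.
No multiple-testing correction is applied across features, matching the
reporting convention the package follows.

The package's central statistical argument is checked by construction: a
constant multiplicative bias on a predicted feature produces high Pearson
correlation with nonzero nMAE_cp — systematic deviations preserve
between-sample comparisons, which is what most biological experiments
need.

# Problem sizes

The shipped experiments are sized for a single CPU: the training smoke
experiment uses 200 training and 15 validation fields of 64 px (one
adipocyte-like cell, droplets scaled to the field) for 200 epochs;
segmentation recovery uses 50 fields of 96 px at noise equal to 10 % of
foreground contrast; the toy one-to-many experiment uses 16 px images;
statistical calibration uses 1000 Monte-Carlo replicates at n = 15. The
acceptance script repeats the pipeline end-to-end at 120 fields / 120
epochs. Larger fields, deeper networks and longer schedules are purely
configuration.

# Known limitations

* The phantom's optics are phenomenological; no claim transfers to real
  data without retraining and recalibration of the segmentation ranges.
* Zero padding makes predictions near field borders (and, without
  generous overlap, tile seams) slightly inconsistent; use
  `tile >> 2^depth · receptive field` and the default Hann blending.
* The engine is single-threaded CPU code (single-precision GEMM-based
  convolutions with analytic backpropagation); it is meant for method
  study and desk-scale data, not for 2560×2160 production training.
* Adaptive thresholds use block-wise Otsu with bilinear interpolation;
  extremely uneven illumination between block centres is smoothed, not
  tracked exactly.
* The discriminator is patch-based; whether a global discriminator would
  behave differently on real data is untested here.
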