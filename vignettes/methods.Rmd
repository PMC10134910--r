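---
title: "Content-style disentanglement for semi-supervised cardiac segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Content-style disentanglement for semi-supervised cardiac segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardisent)
```

## The problem

Expert segmentation of short-axis cine cardiac MR is expensive, while
unlabeled cine stacks are plentiful. Images acquired on different scanners
(field strengths, coils, sequences) share the same anatomy but differ in
intensity, contrast and shading. `cardisent` exploits exactly this
structure: it decomposes every 2-D slice into

* a **spatial (anatomy) factor** `f_SK` — an 8-channel, near-binary,
  image-sized map that should look the same no matter which scanner produced
  the slice, and
* a **non-spatial (style) factor** — a low-dimensional Gaussian latent code
  `z` capturing intensity, contrast and shading.

Segmentation is read off the spatial factor alone, so masks can be learned
from very few labeled subjects while the unlabeled pool teaches the
decomposition. The package trains the whole system end to end on
synthetically generated, fully ground-truthed cardiac phantoms.

## Model

Five trainable components cooperate:

1. **Skeleton encoder.** A nested-skip convolutional encoder (U-Net++-style
   dense skip pathways) whose skip connections are replaced by *normalized
   projections*: an EvoNorm-style normalization dividing each feature by the
   square root of the sum of its batch-level and instance-level variance (no
   explicit activation), a per-channel affine, a 1x1 convolution and
   multiplicative Gaussian dropout. Eight lightweight decoders attached at
   the bottleneck each emit one sigmoid channel; the eight channels form the
   soft spatial factor, binarized by straight-through rounding (hard 0/1
   forward, identity gradient).
2. **Style (sentiency) encoder.** A strided convolutional VAE encoder that
   sees the image *and* the hard spatial factor and emits `mu`, `logvar`;
   `z = mu + exp(logvar/2) * eps` during training, `z = mu` at evaluation.
3. **FiLM decoder.** Four 3x3 convolutions (8 channels each, batch norm +
   leaky ReLU) over the spatial factor whose per-channel scale/shift are
   predicted from `z` (feature-wise linear modulation), then a final 3x3
   convolution to one channel. Its penultimate features feed the
   **segmentor** (three 3x3 convolutions, softmax over background / RV /
   myocardium / LV); its final features feed the reconstructor.
4. **SPADE decoder.** `z` is broadcast over a coarse grid and repeatedly
   upsampled through shape-aware normalization blocks: features are
   instance-normalized, rescaled per channel from `z`, then denormalized by
   spatial maps `gamma(f_SK)`, `beta(f_SK)` computed by three convolutions on
   the nearest-neighbor-interpolated factor (nearest-neighbor so the factor
   stays binary at the SPADE input).
5. **Reconstructor.** Channel concatenation of the two decoder outputs,
   one 1x1 fusion convolution, sigmoid.

Two DCGAN-style least-squares discriminators score segmentation
probability maps against one-hot reference masks — one for the labeled
stream, one for the unlabeled stream — and a 3-layer perceptron statistic
network estimates the mutual information between the pooled soft factor and
`z` (Donsker–Varadhan bound).

## Losses

* **WSBF** (supervised): a focal, class-weighted cross-entropy
  `(alpha0 + y(alpha1 - alpha0)) |y - p|^gamma w CE(y, p)` averaged over
  pixels and classes, plus a background-aware focal dice term
  `sum_c [2 - dice(y_c, p_c) - dice(1 - y_c, 1 - p_c)]^(1/gamma)`.
  Defaults `alpha0 = 0.25`, `alpha1 = 0.75`, `gamma = 2` follow the focal-loss
  convention; the per-pixel weight map `w` is the normalized inverse batch
  frequency of the pixel's true class (mean 1), targeting the
  foreground–background imbalance. Probabilities are clamped to
  `[1e-7, 1 - 1e-7]`.
* **Adversarial Geman–McClure**: the least-squares GAN residual `N` is passed
  through `N / (2*beta + N)` with `beta = 0.5`, saturating in `[0, 1)` so
  outlier residuals cannot dominate.
* **VAE KL**: closed-form Gaussian KL to the standard-normal prior, averaged
  over the batch (computed on both streams).
* **SL2SIM**: `1 - SSIM + alpha * MSE` with a 7x7 Gaussian-window SSIM
  (`k1 = 0.01`, `k2 = 0.03`, dynamic range 1) and `alpha = 1`. The mean (not
  the sum) is used for the squared-error term so the loss is invariant to
  image size. The 7-pixel window suits the 64-pixel desk-scale slices.
* **MIM**: the Donsker–Varadhan bound
  `mean(T(joint)) - log(mean(exp(T(marginal))))`, marginals formed by an
  in-batch shuffle of `z`; the `log` argument is floored at `1e-8` and the
  statistic values clamped at ±30 before exponentiation. The statistic
  network *maximizes* the bound on detached factors; the encoders *minimize*
  it through their own update.
* **Total**: `lambda_seg*seg + lambda_advGM*(adv_lab + adv_unlab) +
  lambda_vae*KL + lambda_SL2SIM*(rec_lab + rec_unlab) + lambda_MIM*MI` with
  `lambda_vae = 0.01`, `lambda_seg = 10`, `lambda_advGM = 10`,
  `lambda_SL2SIM = 0.01`, `lambda_MIM = 1`.

## Training procedure

Each step runs, in order: (1) one update per discriminator on detached
generator outputs (the labeled discriminator contrasts labeled predictions
with one-hot ground truth; the unlabeled discriminator contrasts unlabeled
predictions with the same real masks — the only real masks that exist);
(2) `mineRatio` statistic-network ascent steps on detached factors (the
phantom experiments use 4: a tighter Donsker–Varadhan bound hands the
encoders a much cleaner minimization gradient, which measurably sharpens
the separation of scanner style from subject identity in `z`); (3) one main
update of all encoders/decoders minimizing the variant's total objective.
Discriminators, statistic network and the main players never share an
optimizer step. Adam is used throughout (conventional moment parameters);
the labeled stream cycles when shorter than the unlabeled stream, and the
best-on-validation (mean Dice over RV, myocardium, LV) checkpoint is kept.

Three choices were genuinely open and are worth recording:

* **Warm-up.** The adversarial and mutual-information weights ramp linearly
  from zero over the first `warmupEpochs` (default 2; the phantom
  experiments use 6). At desk scale the segmentor needs a brief supervised
  phase before min-max pressure is useful; without it the adversarial
  gradient (an order of magnitude larger than the supervised one at
  initialization) dominates every step.
* **Gradient clipping.** A global-norm clip of 50 rather than a very tight
  clip: with a tight clip the adversarial term's larger norm rescales the
  whole update and effectively freezes the supervised signal.
* **Identity-start conditioning.** The FiLM gamma/beta predictors, the SPADE
  gamma/beta heads and z-modulation, and the VAE `logvar` head are
  zero-initialized (He-normal everywhere else), so all conditioning starts
  at the identity and the posterior starts tight. This prevents the
  uninformative early style code from destabilizing the decoders.

Ablation variants isolate each ingredient: `noFocalCE` drops the focal CE
term (keeps the focal dice), `plainAdv` uses the raw least-squares
adversarial residual instead of its Geman–McClure saturation, `diceCE`
replaces WSBF by plain dice + cross-entropy, `noMIM` drops the MI
minimizer, `ganOnly` keeps only the adversarial path (no VAE, no
reconstruction, `z = 0`), `ganRec` adds reconstruction but no MI term, and
`supervised` trains the labeled segmentation loss alone.

## The phantom study

`generateStudy()` emulates the statistical structure of a multi-scanner
cine-MR cohort without any download:

* **Anatomy**: per slice, the LV blood pool is a disk, the myocardium an
  annulus, the RV a crescent (an offset disk minus the epicardial disk).
  Radii shrink linearly base-to-apex (taper drawn from U(0.35, 0.5)) and
  from ED to ES (LV inner radius factor U(0.55, 0.75), giving ejection
  fractions of roughly 45–70%; the epicardial radius is fixed over the
  cycle, so the wall thickens at ES). Geometry is drawn per subject (LV
  radius 10–15% of the image side, wall 4–5.5%, center jitter ±3%; the
  ranges guarantee the worst-case extent fits inside the frame).
* **Ground truth**: every structure has a closed-form cross-sectional area
  (disk, annulus, circle-minus-lens), so EDV/ESV/SV/EF and myocardial volume
  are computed analytically from the continuous geometry — not from the
  rasterized masks. Simpson volumetry of the masks converges to these values
  as resolution grows (within ~5% for the LV at 192 px), which is exactly
  what the clinical-index tests check.
* **Two scanner domains** differ in class mean intensities, gamma contrast
  (1.0 vs 1.5) and the amplitude of a smooth random second-order polynomial
  bias field (15% vs 30%), emulating 1.5 T-like vs 3 T-like appearance. The
  anatomy generator never sees the domain.
* **Labeling**: `round(labelFraction * nSubjects)` subjects are labeled; the
  study design points are 1, 10, 20, 30, 50 and 90%. Labeled subjects are
  placed in the training partition, mirroring the convention that the
  labeled fraction refers to the training pool; the remaining subjects are
  split 70/15/15 at the subject level.
* **Augmentation** applies, each with probability 0.5, rotations up to 90°,
  zooms up to 20%, shifts up to 20%, horizontal/vertical flips and additive
  noise; geometric transforms hit image (bilinear) and mask
  (nearest-neighbor) identically.

What the phantoms deliberately do *not* emulate: MR physics (no k-space or
Rician noise), pathology subgroups, papillary muscles, trabeculation,
through-plane motion, or full cine temporal resolution (two frames, ED and
ES, suffice for volumetric indices). Passing the phantom tests therefore
demonstrates that the optimization and the disentanglement mechanics work —
not that the trained weights transfer to clinical data.

## Numerical choices

* Probabilities clamped at `1e-7`; dice smoothing `epsilon = 1e-6`; the
  `(2 - d1 - d2)^(1/gamma)` base is clamped to `[0, 2]` and its gradient
  guarded at the origin (exact forward value, bounded derivative).
* Instance/batch variances are floored at `1e-5` inside every normalization.
* Slice normalization subtracts the slice mean, divides by the intensity
  range, then rescales affinely to `[0, 1]` (the mean/range standardization
  alone can be negative; the rescale restores the unit range exactly, and a
  constant slice maps to zeros).
* Mask resampling interpolates each label's indicator bilinearly and takes
  the argmax — labels cannot be invented and boundaries stay sub-pixel
  accurate, which nearest-neighbor index sampling does not guarantee.
* Hausdorff distances use the full bidirectional maximum over boundary
  pixels (4-neighborhood boundary, image border counts as outside) via a
  Euclidean distance transform; per-slice 2-D by default.
* Empty-vs-empty overlap conventions: Dice, Jaccard, precision and recall
  are all 1 when both masks are empty, so apical slices with absent
  structures average cleanly.

## Problem sizes

The shipped experiments run on one CPU core. The phantom study used by the
tests and the acceptance script is 100 subjects x 2 phases x 3 slices at
64 x 64 (1% labeled -> exactly one labeled subject), with a 16-filter,
depth-2 encoder, a 32-channel segmentation head, batch size 4 per stream,
learning rate 2.5e-3 and 20 epochs of 10 capped steps (the unlabeled pool
is subsampled each epoch). Clinical-index recovery is verified at 192 px.
These sizes are the package's desk-scale operating point; all of them are
configuration parameters, and `netConfig(baseFilters = 64, depth = 3)` at
192 px reproduces the full-scale architecture width.

## Known limitations

* The optimization is a three-player min-max game at small batch size; the
  loss trajectory is not monotone, which is why model selection is by
  validation Dice, not by training loss.
* The mutual-information estimate at batch size 8 is extremely noisy; it
  acts as a regularizer, while quantitative MI accuracy is only claimed (and
  tested) for the dedicated estimator on large samples.
* The unlabeled discriminator reuses the labeled subjects' masks as its
  "real" distribution; with a single labeled subject this prior is narrow,
  which is visible as a mild shape bias at very low labeled fractions.
* Checkpoints serialize the full parameter set with optimizer state via
  `saveRDS`; they are R-specific artifacts, not an interchange format.
* Per-slice normalization removes global brightness, and the phantom's bias
  fields are drawn per slice, so within-domain style variation is genuine
  and substantial. `styleSwap()` therefore defaults to subject-level style
  codes (the mean of a subject's slice codes) when contrasting scanner
  domains: slice-level swaps shift reconstructions almost as much within a
  domain as across domains, which is the correct behavior of a style
  encoder that captures per-slice shading, but it blurs the scanner
  signature one usually wants to isolate.
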