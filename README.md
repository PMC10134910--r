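# cardisent

Semi-supervised segmentation and reconstruction of short-axis cine cardiac
MR by content-style disentanglement, in pure R.

Expert contours for cardiac MR are scarce; unlabeled cine stacks are not.
`cardisent` decomposes every slice into a domain-invariant **spatial
(anatomy) factor** — an 8-channel near-binary map `f_SK` produced by a
nested-skip convolutional encoder — and a **non-spatial (style) factor** — a
Gaussian latent code `z` from a variational encoder that captures scanner
intensity, contrast and shading. A segmentation head reads masks
(background / RV / myocardium / LV blood pool) off the spatial factor via a
FiLM-conditioned decoder, a SPADE-conditioned decoder re-paints the anatomy
in the style of `z`, and a fusion layer reconstructs the input. Training
mixes, per step,

* a weighted soft background focal loss (focal class-weighted cross-entropy
  plus a background-aware focal dice term) on labeled slices,
* least-squares adversarial losses on labeled and unlabeled predictions,
  each saturated by a Geman-McClure function `N / (2*beta + N)`,
* a Gaussian KL term for the style posterior,
* an SSIM-plus-L2 reconstruction loss (`1 - SSIM + alpha * MSE`), and
* a neural mutual-information estimate (Donsker-Varadhan bound) between the
  two factors, minimized through the encoders to enforce disentanglement,

with weights `lambda_vae = 0.01, lambda_seg = 10, lambda_advGM = 10,
lambda_SL2SIM = 0.01, lambda_MIM = 1`. Everything — including a small
reverse-mode autodiff engine with Rcpp/Armadillo convolution kernels — lives
in this package; no deep-learning framework is required.

Because the method is exercised without any external dataset, the package
ships a multi-domain **cardiac phantom generator**: procedural LV disk /
myocardial annulus / RV crescent anatomy with analytic ground-truth
volumetry (EDV, ESV, SV, EF, myocardial mass), two "scanner" intensity
domains, and configurable labeled fractions (1-90%).

## Worked example

```r
library(cardisent)

# a two-domain study: 100 subjects, 3 slices x 2 phases, 1% labeled
study <- generateStudy(phantomConfig(imageSize = 64, nSubjects = 100,
                                     nSlices = 3, labelFraction = 0.01,
                                     seed = 42))
study
#> PhantomStudy: 100 subjects, 3 slices x 2 phases, 64 x 64 px
#>   domains: 2 | labeled subjects: 1 (fraction 0.01)
#>   spacing: 1.37 mm/px, slice thickness: 10 mm

tc <- trainConfig(epochs = 20, batchSize = 4, lr = 2.5e-3, variant = "full",
                  seed = 7, net = netConfig(baseFilters = 16,
                                            segChannels = 32, depth = 2),
                  stepsPerEpoch = 10, valEvery = 2, warmupEpochs = 6,
                  valSubjects = 8, mineRatio = 4)
ck <- fitModel(study, tc)                   # ~10 min on one CPU core
ck$bestValDice
#> [1] 0.8886607

model <- restoreModel(ck)
slices <- studyImages(study, ck$split$test[1])$ED
for (k in 1:3) slices[, , k] <- normalizeSlice(slices[, , k])
p <- predictSlices(model, slices)
table(p$masks)            # predicted label counts per class 0-3
#>     0     1     2     3
#> 11390   261   365   272

# swap style codes across scanner domains: reconstructions change intensity,
# argmax masks stay put
sw <- styleSwap(model, slices, normalizeSlice(studyImages(study, 2)$ED[, , 1]))
```

Held-out evaluation of a trained model (Dice, Jaccard, Hausdorff,
precision/recall per structure; PSNR/CC for reconstructions; EDV/ESV/SV/EF
and myocardial mass by Simpson's method):

```r
preds <- predictStudy(model, study, ck$split$test)
rep <- evaluateSegmentation(lapply(as.character(ck$split$test), \(s) preds[[s]]$masks),
                            lapply(ck$split$test, \(s) studyMasks(study, s)),
                            spacing = 1.37, thickness = 10)
rep
#> MetricsReport over 15 subjects
#>   LV          Dice 0.920  Jaccard 0.867  HD 2.39 mm
#>   myocardium  Dice 0.671  Jaccard 0.547  HD 7.17 mm
#>   RV          Dice 0.886  Jaccard 0.810  HD 6.93 mm
```

A command-line interface wraps the same functions:

```sh
Rscript inst/scripts/cardisent generate --out study/ --n-subjects 100 --label-fraction 0.01 --seed 42
Rscript inst/scripts/cardisent train --study study/ --out run/ --variant full --seed 7
Rscript inst/scripts/cardisent evaluate --study study/ --checkpoint run/checkpoint.rds --out metrics/
```

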