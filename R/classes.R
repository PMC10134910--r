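# Central S4 data containers: a phantom study, a preprocessed slab batch,
# and a metrics report. Label convention throughout the package:
# 0 = background, 1 = RV blood pool, 2 = LV myocardium, 3 = LV blood pool.

LABEL_LEVELS <- c(background = 0L, RV = 1L, myocardium = 2L, LV = 3L)
STRUCTURES <- c("RV", "myocardium", "LV")

#' @import methods
NULL

#' PhantomStudy: a multi-domain synthetic cardiac study
#'
#' Images and integer label masks for `nSubjects` subjects, two cardiac
#' phases (ED, ES) and `nSlices` short-axis slices each, together with the
#' analytic ground-truth volumetry of the generating geometry.
#'
#' @slot images list (one per subject) of lists with elements `ED` and `ES`,
#'   each an `(H, W, nSlices)` array in `[0, 1]`.
#' @slot masks like `images` but integer label maps in `{0, 1, 2, 3}`.
#' @slot subjects data.frame with `subject`, `domain`, `labeled`.
#' @slot truth data.frame of per-subject analytic volumes (mm^3) and indices:
#'   `edv`, `esv`, `sv`, `ef`, `myoVolume`, `rvEdv`, `rvEsv`.
#' @slot config the generating [phantomConfig()] list.
#' @export
setClass("PhantomStudy", representation(
  images = "list", masks = "list", subjects = "data.frame",
  truth = "data.frame", config = "list"))

setValidity("PhantomStudy", function(object) {
  msgs <- character()
  n <- nrow(object@subjects)
  if (length(object@images) != n || length(object@masks) != n)
    msgs <- c(msgs, "images/masks length must equal the number of subjects")
  labs <- unique(unlist(lapply(object@masks, function(s) lapply(s, unique))))
  if (length(labs) && !all(labs %in% 0:3))
    msgs <- c(msgs, "mask labels must lie in {0, 1, 2, 3}")
  if (nrow(object@truth) && any(object@truth$edv <= object@truth$esv))
    msgs <- c(msgs, "EDV must exceed ESV for every subject")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PhantomStudy", function(object) {
  cfg <- object@config
  cat("PhantomStudy:", nrow(object@subjects), "subjects,",
      cfg$nSlices, "slices x 2 phases,",
      cfg$imageSize, "x", cfg$imageSize, "px\n")
  cat("  domains:", length(cfg$domains),
      "| labeled subjects:", sum(object@subjects$labeled),
      sprintf("(fraction %.2f)\n", cfg$labelFraction))
  cat("  spacing:", cfg$pixelSpacing, "mm/px, slice thickness:",
      cfg$sliceThickness, "mm\n")
})

#' @describeIn PhantomStudy number of subjects
#' @param object,x a `PhantomStudy`
#' @export
nSubjects <- function(x) nrow(x@subjects)

#' Accessors for PhantomStudy
#'
#' `studyImages()`/`studyMasks()` return one subject's slice arrays,
#' `subjectTable()` the subject metadata, `truthTable()` the analytic
#' ground-truth volumetry.
#'
#' @param x A `PhantomStudy`.
#' @param subject Subject index.
#' @export
studyImages <- function(x, subject) x@images[[subject]]

#' @rdname studyImages
#' @export
studyMasks <- function(x, subject) x@masks[[subject]]

#' @rdname studyImages
#' @export
subjectTable <- function(x) x@subjects

#' @rdname studyImages
#' @export
truthTable <- function(x) x@truth

#' SlabBatch: a preprocessed batch of 2-D slices
#'
#' @slot images `(H, W, B)` array in `[0, 1]`.
#' @slot masks optional `(H, W, B)` integer array (empty when unlabeled).
#' @slot onehot optional `(H, W, L, B)` one-hot encoding of the masks.
#' @slot provenance data.frame with `subject`, `frame`, `slice` per item.
#' @export
setClass("SlabBatch", representation(
  images = "array", masks = "array", onehot = "array", provenance = "data.frame"))

setValidity("SlabBatch", function(object) {
  d <- dim(object@images)
  msgs <- character()
  if (length(d) != 3L || d[1] != d[2])
    msgs <- c(msgs, "images must be a square (H, W, B) array")
  if (length(object@onehot)) {
    s <- apply(object@onehot, c(1, 2, 4), sum)
    if (max(abs(s - 1)) > 1e-8)
      msgs <- c(msgs, "one-hot channels must sum to 1 at every pixel")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SlabBatch", function(object) {
  d <- dim(object@images)
  cat("SlabBatch:", d[3], "slices of", d[1], "x", d[2],
      if (length(object@masks)) "(labeled)\n" else "(unlabeled)\n")
})

#' MetricsReport: segmentation, image-quality and clinical evaluation
#'
#' @slot perStructure per subject x structure overlap/distance metrics.
#' @slot quality per subject image-quality metrics (PSNR dB, Pearson CC).
#' @slot clinical per subject clinical indices (mL, g, percent).
#' @slot summary mean and sd rows over subjects for every metric.
#' @export
setClass("MetricsReport", representation(
  perStructure = "data.frame", quality = "data.frame",
  clinical = "data.frame", summary = "data.frame"))

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", length(unique(object@perStructure$subject)), "subjects\n")
  s <- object@summary
  for (st in unique(s$structure)) {
    r <- s[s$structure == st & s$stat == "mean", ]
    if (!nrow(r)) next
    cat(sprintf("  %-11s Dice %.3f  Jaccard %.3f  HD %.2f mm\n",
                st, r$dice, r$jaccard, r$hausdorff_mm))
  }
  if (nrow(object@quality))
    cat(sprintf("  reconstruction: PSNR %.2f dB, CC %.3f\n",
                mean(object@quality$psnr_db[is.finite(object@quality$psnr_db)]),
                mean(object@quality$cc, na.rm = TRUE)))
})
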