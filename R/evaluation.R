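# Segmentation, image-quality and clinical evaluation.
#
# Overlap metrics use the convention that two empty masks agree perfectly
# (Dice = Jaccard = precision = recall = 1), so per-slice averaging over
# apical slices with absent structures stays well-defined. The Hausdorff
# distance is the full (not percentile) bidirectional maximum over boundary
# pixels, computed with a distance transform and scaled to millimetres.

checkMaskPair <- function(T1, P1) {
  if (!all(dim(T1) == dim(P1))) stop("mask shapes differ")
  list(t = T1 != 0, p = P1 != 0)
}

#' Dice similarity coefficient
#'
#' `2|T∩P| / (|T| + |P|)`; defined as 1 when both masks are empty.
#' @param T1,P1 Binary masks (any nonzero entry counts as foreground).
#' @export
diceCoef <- function(T1, P1) {
  m <- checkMaskPair(T1, P1)
  den <- sum(m$t) + sum(m$p)
  if (den == 0) return(1)
  2 * sum(m$t & m$p) / den
}

#' Jaccard index
#'
#' `|T∩P| / |T∪P|`; defined as 1 when both masks are empty.
#' @inheritParams diceCoef
#' @export
jaccardIndex <- function(T1, P1) {
  m <- checkMaskPair(T1, P1)
  u <- sum(m$t | m$p)
  if (u == 0) return(1)
  sum(m$t & m$p) / u
}

#' Pixel-level precision and recall
#'
#' Empty denominators yield 1 when both masks are empty, otherwise 0.
#' @inheritParams diceCoef
#' @return Named vector `c(precision, recall)`.
#' @export
precisionRecall <- function(T1, P1) {
  m <- checkMaskPair(T1, P1)
  tp <- sum(m$t & m$p); fp <- sum(!m$t & m$p); fn <- sum(m$t & !m$p)
  bothEmpty <- sum(m$t) == 0 && sum(m$p) == 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else if (bothEmpty) 1 else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else if (bothEmpty) 1 else 0
  c(precision = prec, recall = rec)
}

maskBoundary <- function(m) {
  # mask pixels with at least one non-mask 4-neighbor (outside counts as non-mask)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
           pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  m & !inner
}

#' Hausdorff distance between two mask boundaries
#'
#' Maximum over both directions of the minimum Euclidean boundary-to-boundary
#' distance, scaled by the pixel spacing. Errors on an empty mask (the
#' surface is undefined).
#'
#' @inheritParams diceCoef
#' @param spacing mm per pixel.
#' @export
hausdorffDistance <- function(T1, P1, spacing = 1) {
  m <- checkMaskPair(T1, P1)
  if (sum(m$t) == 0 || sum(m$p) == 0)
    stop("Hausdorff distance is undefined for an empty mask")
  bt <- maskBoundary(m$t); bp <- maskBoundary(m$p)
  # distance transform: distance from every pixel to the nearest boundary pixel
  dToP <- EBImage::distmap(1 - bp, metric = "euclidean")
  dToT <- EBImage::distmap(1 - bt, metric = "euclidean")
  max(max(dToP[bt]), max(dToT[bp])) * spacing
}

#' Peak signal-to-noise ratio and Pearson correlation
#'
#' PSNR uses `MAX = 1` (images in `[0, 1]`); identical images give `Inf`.
#' A zero-variance image makes the correlation undefined (`NA`).
#'
#' @param x,xHat Numeric arrays of identical shape, `x` in `[0, 1]`.
#' @return Named vector `c(psnr_db, cc)`.
#' @export
psnrCc <- function(x, xHat) {
  stopifnot(all(dim(x) == dim(xHat)))
  mse <- mean((x - xHat)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(1 / mse)
  cc <- if (stats::sd(x) == 0 || stats::sd(xHat) == 0) NA_real_
        else stats::cor(as.vector(x), as.vector(xHat))
  c(psnr_db = psnr, cc = cc)
}

#' Simpson's-method volume of a binary mask stack
#'
#' Sum over slices of pixel count x pixel area x slice thickness.
#'
#' @param maskVolume `(H, W, S)` binary array (nonzero = inside).
#' @param pixelSpacing mm/pixel in-plane.
#' @param sliceThickness mm.
#' @return Volume in mm^3.
#' @export
simpsonVolume <- function(maskVolume, pixelSpacing, sliceThickness) {
  stopifnot(pixelSpacing > 0, sliceThickness > 0)
  sum(maskVolume != 0) * pixelSpacing^2 * sliceThickness
}

#' Clinical indices from ED/ES segmentations
#'
#' LV and RV volumes by Simpson's method, myocardial mass as myocardial
#' volume (cm^3) times 1.06 g/cm^3, stroke volume `SV = EDV - ESV` and
#' ejection fraction `EF = SV / EDV * 100` (percent).
#'
#' @param edMasks,esMasks `(H, W, S)` integer label arrays (0-3) at
#'   end-diastole and end-systole.
#' @param spacing mm/pixel; `thickness` mm.
#' @return Named list with `lvv_ml`, `rvv_ml`, `myo_mass_g`, `sv_ml`,
#'   `ef_percent` (LV), plus `rv_sv_ml`, `rv_ef_percent`.
#' @export
clinicalIndices <- function(edMasks, esMasks, spacing, thickness) {
  vol <- function(m, lab) simpsonVolume(m == lab, spacing, thickness)
  edv <- vol(edMasks, LABEL_LEVELS[["LV"]]); esv <- vol(esMasks, LABEL_LEVELS[["LV"]])
  rvEdv <- vol(edMasks, LABEL_LEVELS[["RV"]]); rvEsv <- vol(esMasks, LABEL_LEVELS[["RV"]])
  myoVol <- vol(edMasks, LABEL_LEVELS[["myocardium"]])
  if (edv == 0) stop("EDV is zero: ejection fraction undefined")
  list(lvv_ml = edv / 1000, rvv_ml = rvEdv / 1000,
       myo_mass_g = myoVol / 1000 * 1.06,
       sv_ml = (edv - esv) / 1000,
       ef_percent = (edv - esv) / edv * 100,
       rv_sv_ml = (rvEdv - rvEsv) / 1000,
       rv_ef_percent = if (rvEdv > 0) (rvEdv - rvEsv) / rvEdv * 100 else NA_real_)
}

#' Evaluate predicted segmentations against reference masks
#'
#' Per-structure metrics are computed per slice, then averaged over slices
#' and subjects; clinical indices are computed per subject from the full
#' ED/ES stacks. Slices where a structure is absent from both masks count as
#' perfect agreement; Hausdorff is skipped (NA) when either boundary is
#' empty.
#'
#' @param pred,ref Lists (per subject) of lists with `ED`/`ES` label arrays.
#' @param spacing,thickness Geometry in mm.
#' @param recon,images Optional lists of reconstructed and original image
#'   arrays for image-quality metrics.
#' @param subjects Optional subject ids (defaults to `seq_along(pred)`).
#' @return A [MetricsReport-class].
#' @export
evaluateSegmentation <- function(pred, ref, spacing, thickness,
                                 recon = NULL, images = NULL, subjects = NULL) {
  subjects <- subjects %||% seq_along(pred)
  rowsS <- list(); rowsC <- list(); rowsQ <- list()
  for (i in seq_along(pred)) {
    sid <- subjects[i]
    for (st in STRUCTURES) {
      lab <- LABEL_LEVELS[[st]]
      dv <- jv <- hv <- pv <- rv <- c()
      for (fr in c("ED", "ES")) {
        S <- dim(ref[[i]][[fr]])[3]
        for (k in seq_len(S)) {
          tm <- ref[[i]][[fr]][, , k] == lab
          pm <- pred[[i]][[fr]][, , k] == lab
          dv <- c(dv, diceCoef(tm, pm)); jv <- c(jv, jaccardIndex(tm, pm))
          pr <- precisionRecall(tm, pm)
          pv <- c(pv, pr[1]); rv <- c(rv, pr[2])
          if (sum(tm) > 0 && sum(pm) > 0)
            hv <- c(hv, hausdorffDistance(tm, pm, spacing))
        }
      }
      rowsS[[length(rowsS) + 1L]] <- data.frame(
        subject = sid, structure = st, dice = mean(dv), jaccard = mean(jv),
        hausdorff_mm = if (length(hv)) mean(hv) else NA_real_,
        precision = mean(pv), recall = mean(rv))
    }
    ci <- clinicalIndices(pred[[i]]$ED, pred[[i]]$ES, spacing, thickness)
    rowsC[[length(rowsC) + 1L]] <- data.frame(subject = sid, as.data.frame(ci))
    if (!is.null(recon)) {
      q <- psnrCc(images[[i]], recon[[i]])
      rowsQ[[length(rowsQ) + 1L]] <- data.frame(subject = sid,
                                                psnr_db = q[1], cc = q[2])
    }
  }
  per <- do.call(rbind, rowsS)
  cli <- do.call(rbind, rowsC)
  qua <- if (length(rowsQ)) do.call(rbind, rowsQ) else data.frame()
  sm <- do.call(rbind, lapply(split(per, per$structure), function(d) {
    rbind(data.frame(structure = d$structure[1], stat = "mean",
                     t(colMeans(d[, 3:7], na.rm = TRUE))),
          data.frame(structure = d$structure[1], stat = "sd",
                     t(apply(d[, 3:7], 2, stats::sd, na.rm = TRUE))))
  }))
  rownames(sm) <- NULL
  methods::new("MetricsReport", perStructure = per, quality = qua,
               clinical = cli, summary = sm)
}
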