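# Multi-domain cardiac phantom generator.
#
# Anatomy is procedural: per short-axis slice the LV blood pool is a centered
# disk, the myocardium an annulus around it, and the RV a crescent abutting
# the annulus (a laterally offset disk minus the epicardial disk). Radii
# shrink from base to apex and from end-diastole (ED) to end-systole (ES),
# so every structure has an analytic cross-sectional area and hence an
# analytic volume -- the ground truth that Simpson volumetry of the rasterized
# masks must recover as resolution grows. Two "scanner" domains differ in
# class mean intensities, gamma contrast and a smooth polynomial bias field,
# emulating multi-scanner non-spatial variation; the anatomy generation is
# domain-independent.

#' Intensity style of one acquisition domain
#'
#' @param classMeans Named numeric vector in `[0, 1]` with entries
#'   `background`, `RV`, `myocardium`, `LV` (pairwise distinct).
#' @param contrastGamma Positive gamma-correction exponent applied to the
#'   class means.
#' @param biasFieldAmplitude Peak fractional intensity modulation of the
#'   smooth multiplicative bias field.
#' @param biasFieldOrder Polynomial order of the bias field.
#' @export
domainStyle <- function(classMeans = c(background = 0.15, RV = 0.55,
                                       myocardium = 0.35, LV = 0.75),
                        contrastGamma = 1.0, biasFieldAmplitude = 0.15,
                        biasFieldOrder = 2L) {
  stopifnot(contrastGamma > 0,
            all(c("background", "RV", "myocardium", "LV") %in% names(classMeans)),
            anyDuplicated(classMeans) == 0)
  structure(list(classMeans = classMeans, contrastGamma = contrastGamma,
                 biasFieldAmplitude = biasFieldAmplitude,
                 biasFieldOrder = as.integer(biasFieldOrder)),
            class = "domainStyle")
}

defaultDomains <- function() {
  list(
    # lower-field-like: moderate contrast, mild bias field
    domainStyle(c(background = 0.15, RV = 0.55, myocardium = 0.35, LV = 0.75),
                contrastGamma = 1.0, biasFieldAmplitude = 0.15, biasFieldOrder = 2L),
    # higher-field-like: brighter, higher contrast, stronger bias field
    domainStyle(c(background = 0.25, RV = 0.70, myocardium = 0.45, LV = 0.92),
                contrastGamma = 1.5, biasFieldAmplitude = 0.30, biasFieldOrder = 2L))
}

#' Phantom study configuration
#'
#' @param imageSize Pixels per (square) side; >= 32. 64 suits desk-scale
#'   experiments, 192 mirrors full-resolution short-axis crops.
#' @param nSubjects Number of subjects.
#' @param nSlices Short-axis slices per volume, base to apex (>= 3).
#' @param pixelSpacing In-plane spacing, mm/pixel.
#' @param sliceThickness Through-plane thickness, mm.
#' @param domains List of [domainStyle()] objects.
#' @param labelFraction Proportion of labeled subjects, in (0, 1); the study
#'   design points are 0.01, 0.1, 0.2, 0.3, 0.5 and 0.9.
#' @param noiseSigma Additive Gaussian intensity noise (image units).
#' @param seed Integer seed making the study reproducible.
#' @export
phantomConfig <- function(imageSize = 64L, nSubjects = 10L, nSlices = 5L,
                          pixelSpacing = 1.37, sliceThickness = 10,
                          domains = defaultDomains(), labelFraction = 0.1,
                          noiseSigma = 0.03, seed = 1L) {
  stopifnot(imageSize >= 32L, nSlices >= 3L, labelFraction > 0, labelFraction < 1,
            pixelSpacing > 0, sliceThickness > 0, length(domains) >= 1L)
  structure(list(imageSize = as.integer(imageSize), nSubjects = as.integer(nSubjects),
                 nSlices = as.integer(nSlices), pixelSpacing = pixelSpacing,
                 sliceThickness = sliceThickness, domains = domains,
                 labelFraction = labelFraction, noiseSigma = noiseSigma,
                 seed = as.integer(seed)),
            class = "phantomConfig")
}

# per-slice, per-frame continuous radii (pixels) of one subject's geometry
sliceGeometry <- function(geom, sliceIndex, frame, nSlices) {
  fs <- 1 - (1 - geom$apexShrink) * (sliceIndex - 1) / (nSlices - 1)
  es <- frame == "ES"
  rOut <- geom$lvRadius * fs + geom$myoThickness   # epicardial radius, fixed over the cycle
  rLv <- geom$lvRadius * fs * (if (es) geom$esFactor else 1)
  rRv <- geom$rvRadius * fs * (if (es) geom$rvEsFactor else 1)
  list(rLv = rLv, rOut = rOut, rRv = rRv,
       rvOffset = geom$rvOffsetFactor * rOut)
}

#' Rasterize one slice's anatomy into a label mask
#'
#' @param geom Subject geometry list (see [generateStudy()]); fields
#'   `cx`, `cy`, `lvRadius`, `myoThickness`, `rvRadius`, `rvOffsetFactor`,
#'   `apexShrink`, `esFactor`, `rvEsFactor`.
#' @param sliceIndex Slice number, 1 (base) to `nSlices` (apex).
#' @param frame `"ED"` or `"ES"`.
#' @param imageSize Grid side length in pixels.
#' @param nSlices Total slice count.
#' @return Integer matrix with labels 0-3 (pixel-center-in-region test).
#' @export
generateAnatomy <- function(geom, sliceIndex, frame = c("ED", "ES"),
                            imageSize, nSlices) {
  frame <- match.arg(frame)
  stopifnot(sliceIndex >= 1, sliceIndex <= nSlices)
  g <- sliceGeometry(geom, sliceIndex, frame, nSlices)
  if (geom$cx - g$rvOffset - g$rRv < 1 || geom$cx + g$rOut > imageSize ||
      geom$cy - g$rOut < 1 || geom$cy + g$rOut > imageSize)
    stop("phantom geometry exceeds the image frame; reduce radii or enlarge imageSize")
  xs <- seq_len(imageSize)
  dx2 <- outer((xs - geom$cx)^2, rep(1, imageSize))
  dy2 <- outer(rep(1, imageSize), (xs - geom$cy)^2)
  dc <- sqrt(dx2 + dy2)                              # distance to LV center
  drv <- sqrt(outer((xs - (geom$cx - g$rvOffset))^2, rep(1, imageSize)) + dy2)
  mask <- matrix(0L, imageSize, imageSize)
  if (g$rRv > 0) mask[drv <= g$rRv & dc > g$rOut] <- LABEL_LEVELS[["RV"]]
  if (g$rOut > 0) mask[dc <= g$rOut & dc > g$rLv] <- LABEL_LEVELS[["myocardium"]]
  if (g$rLv > 0) mask[dc <= g$rLv] <- LABEL_LEVELS[["LV"]]
  mask
}

# area of the intersection of two disks (lens formula), radii r1, r2, center
# distance d
lensArea <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

# analytic per-slice areas (px^2) of LV pool, myocardium, RV crescent
sliceAreas <- function(geom, sliceIndex, frame, nSlices) {
  g <- sliceGeometry(geom, sliceIndex, frame, nSlices)
  c(lv = pi * g$rLv^2,
    myo = pi * (g$rOut^2 - g$rLv^2),
    rv = pi * g$rRv^2 - lensArea(g$rRv, g$rOut, g$rvOffset))
}

#' Render a label mask into an intensity image for one domain
#'
#' Pixel values are the gamma-adjusted class means, multiplied by a smooth
#' random polynomial bias field (`1 + amplitude * P(x, y)`, `max|P| = 1`),
#' plus Gaussian noise, clipped to `[0, 1]`. Uses the current RNG state.
#'
#' @param mask Integer label matrix (0-3).
#' @param style A [domainStyle()].
#' @param noiseSigma Additive noise standard deviation.
#' @export
renderIntensity <- function(mask, style, noiseSigma = 0) {
  means <- style$classMeans[c("background", "RV", "myocardium", "LV")]
  lut <- means^style$contrastGamma
  img <- matrix(lut[mask + 1L], nrow(mask), ncol(mask))
  if (style$biasFieldAmplitude > 0) {
    img <- img * (1 + style$biasFieldAmplitude * biasField(nrow(mask), style$biasFieldOrder))
  }
  if (noiseSigma > 0) img <- img + matrix(stats::rnorm(length(img), sd = noiseSigma),
                                          nrow(mask))
  pmin(pmax(img, 0), 1)
}

biasField <- function(n, order) {
  u <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, n)
  for (i in 0:order) for (j in 0:(order - i)) {
    if (i == 0 && j == 0) next
    P <- P + stats::rnorm(1) * outer(u^i, u^j)
  }
  m <- max(abs(P))
  if (m > 0) P / m else P
}

#' Generate a reproducible multi-domain phantom study
#'
#' Draws per-subject geometry (LV radius, wall thickness, RV size, apex
#' taper, systolic contraction factors, center jitter), assigns each subject
#' a domain, renders images for both cardiac phases and all slices, marks
#' `round(labelFraction * nSubjects)` subjects as labeled, and tabulates the
#' analytic ground-truth volumes from the continuous generating geometry
#' (not from the rasterized masks).
#'
#' @param config A [phantomConfig()].
#' @return A [PhantomStudy-class] object.
#' @export
generateStudy <- function(config = phantomConfig()) {
  stopifnot(inherits(config, "phantomConfig"))
  nLab <- round(config$labelFraction * config$nSubjects)
  if (config$labelFraction * config$nSubjects < 1)
    stop("labelFraction x nSubjects < 1: raise nSubjects so at least one ",
         "subject can be labeled")
  set.seed(config$seed)
  n <- config$nSubjects; S <- config$nSlices; sz <- config$imageSize
  images <- masks <- vector("list", n)
  domain <- sample.int(length(config$domains), n, replace = TRUE)
  if (length(config$domains) > 1 && length(unique(domain)) == 1L)
    domain[1] <- (domain[1] %% length(config$domains)) + 1L
  labeled <- rep(FALSE, n)
  labeled[sample.int(n, nLab)] <- TRUE
  truth <- vector("list", n)
  for (s in seq_len(n)) {
    # ranges chosen so that the worst-case extent (epicardial radius plus
    # lateral RV offset plus RV radius) always fits inside the frame
    geom <- list(
      cx = sz / 2 + stats::runif(1, -0.03, 0.03) * sz,
      cy = sz / 2 + stats::runif(1, -0.03, 0.03) * sz,
      lvRadius = stats::runif(1, 0.10, 0.15) * sz,
      myoThickness = stats::runif(1, 0.04, 0.055) * sz,
      rvOffsetFactor = stats::runif(1, 1.0, 1.15),
      apexShrink = stats::runif(1, 0.35, 0.5),
      esFactor = stats::runif(1, 0.55, 0.75),
      rvEsFactor = stats::runif(1, 0.7, 0.85))
    geom$rvRadius <- (geom$lvRadius + geom$myoThickness) * stats::runif(1, 0.8, 0.95)
    sty <- config$domains[[domain[s]]]
    im <- list(ED = array(0, c(sz, sz, S)), ES = array(0, c(sz, sz, S)))
    mk <- list(ED = array(0L, c(sz, sz, S)), ES = array(0L, c(sz, sz, S)))
    areas <- list(ED = matrix(0, S, 3), ES = matrix(0, S, 3))
    for (fr in c("ED", "ES")) for (k in seq_len(S)) {
      m <- generateAnatomy(geom, k, fr, sz, S)
      mk[[fr]][, , k] <- m
      im[[fr]][, , k] <- renderIntensity(m, sty, config$noiseSigma)
      areas[[fr]][k, ] <- sliceAreas(geom, k, fr, S)
    }
    images[[s]] <- im; masks[[s]] <- mk
    vox <- config$pixelSpacing^2 * config$sliceThickness
    volED <- colSums(areas$ED) * vox       # mm^3, analytic
    volES <- colSums(areas$ES) * vox
    truth[[s]] <- data.frame(
      subject = s,
      edv = volED[1], esv = volES[1], sv = volED[1] - volES[1],
      ef = (volED[1] - volES[1]) / volED[1] * 100,
      myoVolume = volED[2], rvEdv = volED[3], rvEsv = volES[3])
  }
  methods::new("PhantomStudy",
               images = images, masks = masks,
               subjects = data.frame(subject = seq_len(n), domain = domain,
                                     labeled = labeled),
               truth = do.call(rbind, truth),
               config = unclass(config))
}

#' On-the-fly augmentation of an image/mask pair
#'
#' Applies, each with independent probability 0.5: a rotation up to 90
#' degrees, a zoom up to 20 percent, horizontal/vertical shifts up to 20
#' percent, horizontal and vertical flips, and additive Gaussian noise.
#' Geometric transforms are applied identically to the image (bilinear) and
#' the mask (nearest-neighbor); noise only touches the image. Uses the
#' current RNG state.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Integer label matrix of the same shape (may be `NULL`).
#' @param noiseSigma Scale of the additive-noise component.
#' @return List with transformed `image` and `mask`.
#' @export
augmentPair <- function(image, mask = NULL, noiseSigma = 0.03) {
  stopifnot(is.null(mask) || all(dim(image) == dim(mask)))
  H <- nrow(image); W <- ncol(image)
  gates <- stats::runif(6) < 0.5
  both <- function(fImg, fMask) {
    image <<- fImg(image)
    if (!is.null(mask)) mask <<- fMask(mask)
  }
  if (gates[1]) {                          # rotation <= 90 degrees
    ang <- stats::runif(1, -90, 90)
    both(function(x) EBImage::rotate(x, ang, filter = "bilinear",
                                     output.dim = c(H, W), bg.col = 0),
         function(x) EBImage::rotate(x, ang, filter = "none",
                                     output.dim = c(H, W), bg.col = 0))
  }
  if (gates[2]) {                          # zoom <= 20%
    f <- stats::runif(1, 0.8, 1.2)
    nh <- max(2L, round(H * f)); nw <- max(2L, round(W * f))
    both(function(x) cropOrPad(EBImage::resize(x, w = nh, h = nw,
                                               filter = "bilinear"), H),
         function(x) cropOrPad(EBImage::resize(x, w = nh, h = nw,
                                               filter = "none"), H))
  }
  if (gates[3]) {                          # shifts <= 20% (integer pixels)
    v <- round(stats::runif(2, -0.2, 0.2) * c(H, W))
    both(function(x) as.matrix(EBImage::translate(x, v = v, bg.col = 0)),
         function(x) as.matrix(EBImage::translate(x, v = v, bg.col = 0)))
  }
  if (gates[4]) both(EBImage::flip, EBImage::flip)
  if (gates[5]) both(EBImage::flop, EBImage::flop)
  if (gates[6]) {                          # noise, image only
    image <- pmin(pmax(image + matrix(stats::rnorm(H * W, sd = noiseSigma), H), 0), 1)
  }
  if (!is.null(mask)) storage.mode(mask) <- "integer"
  list(image = as.matrix(image), mask = if (is.null(mask)) NULL else as.matrix(mask))
}

## ---- on-disk representation -------------------------------------------------

#' Write a phantom study to disk
#'
#' One NIfTI-1 image and mask volume per subject and phase (pixel spacing and
#' slice thickness in the header), optional per-slice PNGs, and a study
#' manifest CSV (subject, domain, labeled flag, truth volumes).
#'
#' @param study A [PhantomStudy-class].
#' @param dir Output directory (created if needed).
#' @param png Also write per-slice PNG files.
#' @export
writeStudy <- function(study, dir, png = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study@config
  for (s in seq_len(nSubjects(study))) {
    for (fr in c("ED", "ES")) {
      base <- file.path(dir, sprintf("subject%03d_%s", s, fr))
      writeNiftiVolume(study@images[[s]][[fr]], paste0(base, ".nii.gz"), cfg)
      writeNiftiVolume(study@masks[[s]][[fr]], paste0(base, "_mask.nii.gz"), cfg)
      if (png) {
        for (k in seq_len(cfg$nSlices)) {
          png::writePNG(t(study@images[[s]][[fr]][, , k]),
                        sprintf("%s_slice%02d.png", base, k))
          png::writePNG(t(study@masks[[s]][[fr]][, , k]) / 3,
                        sprintf("%s_slice%02d_mask.png", base, k))
        }
      }
    }
  }
  man <- merge(study@subjects, study@truth, by = "subject")
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  scalars <- cfg[c("imageSize", "nSubjects", "nSlices", "pixelSpacing",
                   "sliceThickness", "labelFraction", "noiseSigma", "seed")]
  writeLines(jsonlite::toJSON(scalars, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "study_config.json"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Rebuild a PhantomStudy from a directory written by [writeStudy()]
#'
#' @param dir Study directory.
#' @return A [PhantomStudy-class] (domain styles are not round-tripped; the
#'   rendered images already carry them).
#' @export
studyFromDir <- function(dir) {
  raw <- readStudy(dir)
  cfgFile <- file.path(dir, "study_config.json")
  if (!file.exists(cfgFile)) stop("missing study_config.json in ", dir)
  sc <- jsonlite::fromJSON(cfgFile)
  man <- raw$manifest
  cfg <- phantomConfig(imageSize = sc$imageSize, nSubjects = sc$nSubjects,
                       nSlices = sc$nSlices, pixelSpacing = sc$pixelSpacing,
                       sliceThickness = sc$sliceThickness,
                       labelFraction = sc$labelFraction,
                       noiseSigma = sc$noiseSigma, seed = sc$seed)
  methods::new("PhantomStudy",
               images = raw$images, masks = raw$masks,
               subjects = data.frame(subject = man$subject, domain = man$domain,
                                     labeled = as.logical(man$labeled)),
               truth = man[, c("subject", "edv", "esv", "sv", "ef",
                               "myoVolume", "rvEdv", "rvEsv")],
               config = unclass(cfg))
}

writeNiftiVolume <- function(arr, file, cfg) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(cfg$pixelSpacing, cfg$pixelSpacing,
                                   cfg$sliceThickness))
  RNifti::writeNifti(img, file)
}

#' Read a study directory written by [writeStudy()]
#'
#' @param dir Study directory containing `manifest.csv` and NIfTI volumes.
#' @return A list with `images`, `masks` (as in a `PhantomStudy`) and the
#'   manifest data.frame.
#' @export
readStudy <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  n <- nrow(man)
  images <- masks <- vector("list", n)
  for (s in seq_len(n)) {
    images[[s]] <- list(); masks[[s]] <- list()
    for (fr in c("ED", "ES")) {
      base <- file.path(dir, sprintf("subject%03d_%s", s, fr))
      im <- RNifti::readNifti(paste0(base, ".nii.gz"))
      images[[s]][[fr]] <- array(as.numeric(im), dim(im))
      m <- RNifti::readNifti(paste0(base, "_mask.nii.gz"))
      masks[[s]][[fr]] <- array(as.integer(m), dim(m))
    }
  }
  list(images = images, masks = masks, manifest = man)
}
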