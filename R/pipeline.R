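# Preprocessing pipeline: slice-wise normalization, in-plane resampling,
# center crop / symmetric pad, subject-level splits and batch assembly.

#' Slice-wise intensity normalization
#'
#' Subtracts the mean slice intensity and divides by the slice intensity
#' range, then rescales the result affinely to `[0, 1]`. A constant slice
#' maps to all zeros (guarded division).
#'
#' @param slice 2-D numeric matrix with finite values.
#' @export
normalizeSlice <- function(slice) {
  if (!all(is.finite(slice))) stop("slice contains non-finite values")
  rng <- max(slice) - min(slice)
  if (rng == 0) return(matrix(0, nrow(slice), ncol(slice)))
  y <- (slice - mean(slice)) / rng
  y - min(y)                               # range of y is exactly 1
}

#' In-plane resampling to a target pixel spacing
#'
#' Bilinear for images; label maps are resampled by bilinear interpolation of
#' each label's indicator followed by an argmax (a label can never be
#' invented, and boundaries stay put to sub-pixel accuracy). The
#' through-plane direction is never resampled.
#'
#' @param slice 2-D matrix (or `(H, W, S)` array resampled slice-wise).
#' @param sourceSpacing,targetSpacing mm/pixel (default target 1.37).
#' @param mask Treat the slice as an integer label map.
#' @export
resampleSlice <- function(slice, sourceSpacing, targetSpacing = 1.37,
                          mask = FALSE) {
  stopifnot(sourceSpacing > 0, targetSpacing > 0)
  if (sourceSpacing == targetSpacing) return(slice)
  f <- sourceSpacing / targetSpacing
  resample1 <- function(m) {
    w <- max(2L, round(nrow(m) * f)); h <- max(2L, round(ncol(m) * f))
    if (!mask) return(as.matrix(EBImage::resize(m, w = w, h = h,
                                                filter = "bilinear")))
    labs <- sort(unique(as.vector(m)))
    best <- matrix(-Inf, w, h); out <- matrix(labs[1], w, h)
    for (l in labs) {
      sc <- as.matrix(EBImage::resize((m == l) * 1, w = w, h = h,
                                      filter = "bilinear"))
      sel <- sc > best
      out[sel] <- l; best[sel] <- sc[sel]
    }
    storage.mode(out) <- "integer"
    out
  }
  if (length(dim(slice)) == 3L) {
    first <- resample1(slice[, , 1])
    out <- array(if (mask) 0L else 0, c(dim(first), dim(slice)[3]))
    out[, , 1] <- first
    for (k in seq_len(dim(slice)[3])[-1]) out[, , k] <- resample1(slice[, , k])
    out
  } else resample1(slice)
}

#' Center crop or symmetric zero-pad to a square size
#'
#' Uses the 0-based half-open convention: cropping an `n`-side slice to
#' `size` keeps indices `[floor((n - size)/2), floor((n - size)/2) + size)`.
#'
#' @param slice 2-D matrix.
#' @param size Target side length (even).
#' @export
cropOrPad <- function(slice, size) {
  stopifnot(size %% 2L == 0L)
  out <- slice
  for (axis in 1:2) {
    n <- dim(out)[axis]
    if (n > size) {
      start <- (n - size) %/% 2L           # 0-based
      idx <- (start + 1L):(start + size)
      out <- if (axis == 1L) out[idx, , drop = FALSE] else out[, idx, drop = FALSE]
    } else if (n < size) {
      pad1 <- (size - n) %/% 2L
      padded <- if (axis == 1L) matrix(0, size, ncol(out)) else matrix(0, nrow(out), size)
      if (is.integer(out)) storage.mode(padded) <- "integer"
      if (axis == 1L) padded[(pad1 + 1L):(pad1 + n), ] <- out
      else padded[, (pad1 + 1L):(pad1 + n)] <- out
      out <- padded
    }
  }
  out
}

#' Subject-level train/validation/test split
#'
#' Splits subjects (never slices) into three partitions. Validation and test
#' sizes are `floor(fraction * n)`; the remainder goes to training. Labeled
#' subjects are assigned to the training partition first, so the labeled
#' fraction refers to the training pool, then the remaining subjects are
#' shuffled deterministically under the seed.
#'
#' @param study A [PhantomStudy-class].
#' @param fractions Length-3 numeric summing to 1 (train, val, test).
#' @param seed Integer seed.
#' @return List of integer subject-id vectors `train`, `val`, `test`.
#' @export
splitStudy <- function(study, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  n <- nSubjects(study)
  nVal <- floor(fractions[2] * n); nTest <- floor(fractions[3] * n)
  nTrain <- n - nVal - nTest
  if (nTrain < 1 || nVal < 1 || nTest < 1)
    stop("split would leave an empty partition; adjust fractions or subjects")
  lab <- study@subjects$subject[study@subjects$labeled]
  if (length(lab) > nTrain) stop("more labeled subjects than training slots")
  rest <- setdiff(study@subjects$subject, lab)
  set.seed(seed)
  rest <- sample(rest)
  nExtra <- nTrain - length(lab)
  train <- c(lab, if (nExtra > 0) rest[seq_len(nExtra)] else integer(0))
  remaining <- if (nExtra > 0) rest[-seq_len(nExtra)] else rest
  list(train = sort(train),
       val = sort(remaining[seq_len(nVal)]),
       test = sort(remaining[nVal + seq_len(nTest)]))
}

#' One-hot encode integer masks
#'
#' @param masks `(H, W, B)` integer array with labels `0:(L-1)`.
#' @param L Number of classes.
#' @return `(H, W, L, B)` array.
#' @export
oneHotMasks <- function(masks, L = 4L) {
  d <- dim(masks)
  if (length(d) == 2L) { masks <- array(masks, c(d, 1L)); d <- dim(masks) }
  out <- array(0, c(d[1], d[2], L, d[3]))
  for (c in seq_len(L)) out[, , c, ] <- (masks == c - 1L) * 1
  out
}

#' Assemble a preprocessed slice batch from a study
#'
#' Normalizes every slice and stacks the requested subjects/frames into a
#' [SlabBatch-class]; masks and their one-hot encoding are attached when
#' `labeled = TRUE`.
#'
#' @param study A [PhantomStudy-class].
#' @param subjects Subject ids to include.
#' @param labeled Attach masks.
#' @param frames Phases to include.
#' @export
slabBatch <- function(study, subjects, labeled = FALSE, frames = c("ED", "ES")) {
  cfg <- study@config
  sz <- cfg$imageSize
  prov <- list(); imgs <- list(); mks <- list()
  for (s in subjects) for (fr in frames) for (k in seq_len(cfg$nSlices)) {
    imgs[[length(imgs) + 1L]] <- normalizeSlice(study@images[[s]][[fr]][, , k])
    if (labeled) mks[[length(mks) + 1L]] <- study@masks[[s]][[fr]][, , k]
    prov[[length(prov) + 1L]] <- data.frame(subject = s, frame = fr, slice = k)
  }
  B <- length(imgs)
  ia <- array(unlist(imgs), c(sz, sz, B))
  if (labeled) {
    ma <- array(as.integer(unlist(mks)), c(sz, sz, B))
    methods::new("SlabBatch", images = ia, masks = ma,
                 onehot = oneHotMasks(ma), provenance = do.call(rbind, prov))
  } else {
    methods::new("SlabBatch", images = ia, masks = array(integer(0)),
                 onehot = array(numeric(0)), provenance = do.call(rbind, prov))
  }
}
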