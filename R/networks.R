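# Network architectures.
#
# The model couples: (1) a nested-skip ("U-Net++"-style) skeleton encoder with
# normalized-projection skip connections, whose eight lightweight bottleneck
# decoders emit the 8-channel near-binary spatial factor f_SK; (2) a
# variational style ("sentiency") encoder producing a latent code z from the
# image plus f_SK; (3) a FiLM-conditioned decoder (content pathway, feeds the
# segmentor) and a SPADE-conditioned decoder (style pathway); (4) a fusion
# reconstructor; (5) a softmax segmentation head; (6) two DCGAN-style
# least-squares discriminators (labeled / unlabeled streams); and (7) an MLP
# statistic network for neural mutual-information estimation.

#' Network configuration
#'
#' @param baseFilters First-level channel width; deeper levels double it.
#'   16 is the desk-scale default; 64 mirrors the full-scale setting.
#' @param depth Number of 2x downsamplings in the skeleton encoder. Input
#'   images must be divisible by `2^depth`.
#' @param latent Width of the style latent code z.
#' @param dropout Gaussian-dropout rate inside the normalized-projection
#'   skip connections.
#' @param segChannels Width of the segmentation head's two hidden layers.
#' @param nClasses Number of segmentation categories (background, RV,
#'   myocardium, LV).
#' @param decoderChannels Channel width of the eight lightweight spatial-factor
#'   decoders and of the FiLM decoder stack.
#' @param leakSlope Negative slope of the leaky rectifier.
#' @return A list of class `netConfig`.
#' @export
netConfig <- function(baseFilters = 16L, depth = 3L, latent = 8L,
                      dropout = 0.1, segChannels = 64L, nClasses = 4L,
                      decoderChannels = 8L, leakSlope = 0.2) {
  stopifnot(baseFilters >= 4L, depth >= 2L, latent >= 2L, segChannels >= 4L)
  structure(list(baseFilters = as.integer(baseFilters), depth = as.integer(depth),
                 latent = as.integer(latent), dropout = dropout,
                 segChannels = as.integer(segChannels), nClasses = as.integer(nClasses),
                 decoderChannels = as.integer(decoderChannels), leakSlope = leakSlope),
            class = "netConfig")
}

## ---- skeleton encoder (nested skips + 8 bottleneck decoders) ---------------

newSkeletonEncoder <- function(cfg) {
  e <- new.env(parent = emptyenv())
  f <- cfg$baseFilters * 2L^(0:cfg$depth)
  L <- cfg$depth
  e$cfg <- cfg
  e$backbone <- vector("list", L + 1L)
  e$backbone[[1]] <- newConv(1L, f[1])
  for (i in seq_len(L)) e$backbone[[i + 1]] <- newConv(f[i], f[i + 1])
  # nested nodes X[i][j], i = scale (0-based), j = 1..L-i; dense skips are
  # passed through normalized-projection layers (one per source node)
  e$nested <- list(); e$proj <- list()
  for (i in 0:(L - 1L)) {
    for (j in 1:(L - i)) {
      cin <- f[i + 2L] + j * f[i + 1L]
      e$nested[[paste(i, j)]] <- newConv(cin, f[i + 1L])
    }
    for (j in 0:(L - i - 1L)) {
      e$proj[[paste(i, j)]] <- newEvonormProjection(f[i + 1L], f[i + 1L], cfg$dropout)
    }
  }
  # eight lightweight decoders from the bottleneck; the skip coming into each
  # scale is compressed once by a shared 1x1 convolution and reused by all
  # eight decoders
  dch <- cfg$decoderChannels
  e$skipComp <- lapply(0:(L - 1L), function(i)
    newConv(f[i + 1L], dch, k = 1L, pad = 0L))
  e$dec <- vector("list", 8L)
  for (d in 1:8) {
    convs <- vector("list", L)
    prev <- f[L + 1L]
    for (i in (L - 1L):0) {
      convs[[L - i]] <- newConv(prev + dch, dch)
      prev <- dch
    }
    e$dec[[d]] <- list(convs = convs, head = newConv(dch, 1L, k = 1L, pad = 0L))
  }
  e$params <- layerParams0(c(e$backbone, unname(e$nested), unname(e$proj),
                             e$skipComp,
                             lapply(e$dec, function(d) c(d$convs, list(d$head)))))
  e
}

fwdSkeleton <- function(e, x, train = TRUE) {
  cfg <- e$cfg; L <- cfg$depth; slope <- cfg$leakSlope
  d <- dim(x$value)
  if (d[1] %% 2L^L != 0L || d[2] %% 2L^L != 0L)
    stop("image size must be divisible by 2^depth = ", 2L^L)
  X <- list()
  h <- tdLeakyRelu(e$backbone[[1]]$fwd(x), slope)
  X[["0 0"]] <- h
  for (i in seq_len(L)) {
    h <- tdLeakyRelu(e$backbone[[i + 1]]$fwd(tdAvgPool2(h)), slope)
    X[[paste(i, 0)]] <- h
  }
  for (j in 1:L) {
    for (i in 0:(L - j)) {
      ins <- list(tdUpsample2(X[[paste(i + 1L, j - 1L)]]))
      for (jp in 0:(j - 1L)) {
        ins[[length(ins) + 1L]] <- e$proj[[paste(i, jp)]]$fwd(X[[paste(i, jp)]], train)
      }
      X[[paste(i, j)]] <- tdLeakyRelu(e$nested[[paste(i, j)]]$fwd(tdConcatC(ins)), slope)
    }
  }
  skipC <- lapply(0:(L - 1L), function(i)
    tdLeakyRelu(e$skipComp[[i + 1L]]$fwd(X[[paste(i, L - i)]]), slope))
  chans <- vector("list", 8L)
  for (d8 in 1:8) {
    dec <- e$dec[[d8]]
    h <- X[[paste(L, 0)]]
    for (i in (L - 1L):0) {
      h <- tdConcatC(list(tdUpsample2(h), skipC[[i + 1L]]))
      h <- tdLeakyRelu(dec$convs[[L - i]]$fwd(h), slope)
    }
    chans[[d8]] <- tdSigmoid(dec$head$fwd(h))
  }
  soft <- tdConcatC(chans)
  list(soft = soft, hard = tdSTRound(soft))
}

## ---- sentiency (style) encoder ---------------------------------------------

newSentiencyEncoder <- function(cfg) {
  e <- new.env(parent = emptyenv())
  f0 <- cfg$baseFilters; f1 <- 2L * f0
  e$cfg <- cfg
  e$c1 <- newConv(1L + 8L, f0, stride = 2L)
  e$c2 <- newConv(f0, f1, stride = 2L)
  e$c3 <- newConv(f1, f1, stride = 2L)
  e$mu <- newDense(f1, cfg$latent)
  e$lv <- newDense(f1, cfg$latent, init = "zero")
  e$lv$b$value <- rep(-2, cfg$latent)      # start with a tight posterior
  e$params <- layerParams(e$c1, e$c2, e$c3, e$mu, e$lv)
  e
}

fwdSentiency <- function(e, x, fsk, train = TRUE, eps = NULL) {
  slope <- e$cfg$leakSlope
  h <- tdConcatC(list(x, fsk))
  h <- tdLeakyRelu(e$c1$fwd(h), slope)
  h <- tdLeakyRelu(e$c2$fwd(h), slope)
  h <- tdLeakyRelu(e$c3$fwd(h), slope)
  g <- tdInstMean(h)                       # global average pool -> (C, B)
  mu <- e$mu$fwd(g)
  logvar <- e$lv$fwd(g)
  if (train) {
    if (is.null(eps)) eps <- matrix(stats::rnorm(length(mu$value)), nrow(mu$value))
    z <- tdAdd(mu, tdMul(tdExp(tdMul(logvar, 0.5)), tdConst(eps)))
  } else {
    eps <- matrix(0, nrow(mu$value), ncol(mu$value))
    z <- mu
  }
  list(mu = mu, logvar = logvar, z = z, eps = eps)
}

## ---- FiLM decoder -----------------------------------------------------------

newFilmDecoder <- function(cfg) {
  e <- new.env(parent = emptyenv())
  dch <- cfg$decoderChannels
  e$cfg <- cfg
  e$convs <- list(newConv(8L, dch), newConv(dch, dch), newConv(dch, dch), newConv(dch, dch))
  e$final <- newConv(dch, 1L)
  e$bns <- lapply(1:4, function(i) newBatchNorm(dch))
  # zero-initialized predictors: conditioning starts at the identity
  # (gamma = 1, beta = 0) and ramps up as the style code becomes informative
  e$gb <- lapply(1:4, function(i) newDense(cfg$latent, 2L * dch, init = "zero"))
  e$params <- layerParams0(c(e$convs, list(e$final), e$bns, e$gb))
  e
}

fwdFilm <- function(e, fsk, z, train = TRUE) {
  cfg <- e$cfg; dch <- cfg$decoderChannels; slope <- cfg$leakSlope
  h <- fsk
  for (i in 1:4) {
    h <- e$convs[[i]]$fwd(h)
    h <- e$bns[[i]]$fwd(h, train)
    gb <- e$gb[[i]]$fwd(z)                 # (2*dch, B)
    gamma <- tdAdd(tdRowSlice(gb, seq_len(dch)), 1)   # centred at identity
    beta <- tdRowSlice(gb, dch + seq_len(dch))
    d <- dim(h$value)
    h <- tdAdd(tdMul(h, tdBcInst(gamma, d)), tdBcInst(beta, d))
    h <- tdLeakyRelu(h, slope)
  }
  list(features = e$final$fwd(h), penult = h)
}

## ---- SPADE blocks and decoder ----------------------------------------------

newSpadeBlock <- function(cfg, c) {
  e <- new.env(parent = emptyenv())
  hidden <- 16L
  e$cfg <- cfg; e$c <- c
  e$enc <- newConv(8L, hidden)             # encodes the interpolated factor
  e$gconv <- newConv(hidden, c, init = "zero")  # spatial gamma head (identity start)
  e$bconv <- newConv(hidden, c, init = "zero")  # spatial beta head
  e$zmod <- newDense(cfg$latent, 2L * c, init = "zero")
  e$params <- layerParams(e$enc, e$gconv, e$bconv, e$zmod)
  e
}

fwdSpadeBlock <- function(e, Fin, fskDown, z, eps = 1e-5) {
  c <- e$c; slope <- e$cfg$leakSlope
  h <- tInstanceNorm(Fin, eps)
  zc <- e$zmod$fwd(z)
  gz <- tdAdd(tdRowSlice(zc, seq_len(c)), 1)
  bz <- tdRowSlice(zc, c + seq_len(c))
  d <- dim(h$value)
  h <- tdAdd(tdMul(h, tdBcInst(gz, d)), tdBcInst(bz, d))
  enc <- tdLeakyRelu(e$enc$fwd(fskDown), slope)
  gmap <- tdAdd(e$gconv$fwd(enc), 1)       # effective gamma(f_SK), identity-centred
  bmap <- e$bconv$fwd(enc)
  tdAdd(tdMul(h, gmap), bmap)
}

newSpadeDecoder <- function(cfg) {
  e <- new.env(parent = emptyenv())
  e$cfg <- cfg
  e$entry <- newConv(cfg$latent, 16L)
  e$blocks <- list(newSpadeBlock(cfg, 16L), newSpadeBlock(cfg, 16L), newSpadeBlock(cfg, 8L))
  e$convs <- list(newConv(16L, 16L), newConv(16L, 8L), newConv(8L, 8L))
  e$params <- layerParams0(c(list(e$entry), e$blocks, e$convs))
  e
}

fwdSpade <- function(e, z, fsk, train = TRUE) {
  cfg <- e$cfg; slope <- cfg$leakSlope
  dfs <- dim(fsk$value)
  H <- dfs[1]; W <- dfs[2]
  h <- tdBcSpatial(z, H %/% 4L, W %/% 4L)  # z broadcast to a coarse grid
  h <- tdLeakyRelu(e$entry$fwd(h), slope)
  facs <- c(4L, 2L, 1L)
  for (i in 1:3) {
    fd <- tdDownNearest(fsk, facs[i])
    h <- fwdSpadeBlock(e$blocks[[i]], h, fd, z)
    h <- tdLeakyRelu(e$convs[[i]]$fwd(h), slope)
    if (i < 3) h <- tdUpsample2(h)
  }
  h
}

## ---- reconstructor, segmentor, discriminator, MINE -------------------------

newReconstructor <- function(cfg) {
  e <- new.env(parent = emptyenv())
  e$fuse <- newConv(1L + 8L, 1L, k = 1L, pad = 0L)
  e$params <- e$fuse$params
  e
}

fwdReconstruct <- function(e, filmFeat, spadeFeat) {
  tdSigmoid(e$fuse$fwd(tdConcatC(list(filmFeat, spadeFeat))))
}

newSegmentor <- function(cfg) {
  e <- new.env(parent = emptyenv())
  s <- cfg$segChannels
  e$cfg <- cfg
  e$c1 <- newConv(cfg$decoderChannels, s)
  e$c2 <- newConv(s, s)
  e$c3 <- newConv(s, cfg$nClasses)
  e$b1 <- newBatchNorm(s); e$b2 <- newBatchNorm(s)
  e$params <- layerParams(e$c1, e$c2, e$c3, e$b1, e$b2)
  e
}

fwdSegment <- function(e, feat, train = TRUE) {
  slope <- e$cfg$leakSlope
  h <- tdLeakyRelu(e$b1$fwd(e$c1$fwd(feat), train), slope)
  h <- tdLeakyRelu(e$b2$fwd(e$c2$fwd(h), train), slope)
  tdSoftmaxC(e$c3$fwd(h))
}

newDiscriminator <- function(cfg, imageSize) {
  e <- new.env(parent = emptyenv())
  f0 <- cfg$baseFilters
  e$cfg <- cfg
  e$c1 <- newConv(cfg$nClasses, f0, stride = 2L)
  e$c2 <- newConv(f0, 2L * f0, stride = 2L)
  e$c3 <- newConv(2L * f0, 4L * f0, stride = 2L)
  e$b2 <- newBatchNorm(2L * f0); e$b3 <- newBatchNorm(4L * f0)
  e$head <- newDense((imageSize %/% 8L)^2 * 4L * f0, 1L)
  e$params <- layerParams(e$c1, e$c2, e$c3, e$b2, e$b3, e$head)
  e
}

fwdDiscriminate <- function(e, probs, train = TRUE) {
  slope <- e$cfg$leakSlope
  h <- tdLeakyRelu(e$c1$fwd(probs), slope)
  h <- tdLeakyRelu(e$b2$fwd(e$c2$fwd(h), train), slope)
  h <- tdLeakyRelu(e$b3$fwd(e$c3$fwd(h), train), slope)
  e$head$fwd(tdFlatten(h))                 # (1, B) unbounded scores
}

newMineNet <- function(cfg) {
  e <- new.env(parent = emptyenv())
  din <- 8L + cfg$latent
  e$cfg <- cfg
  e$d1 <- newDense(din, 64L); e$d2 <- newDense(64L, 64L); e$d3 <- newDense(64L, 1L)
  e$params <- layerParams(e$d1, e$d2, e$d3)
  e
}

fwdMineStat <- function(e, fskSummary, z) {
  h <- tdRbind(fskSummary, z)
  h <- tdLeakyRelu(e$d1$fwd(h), 0.2)
  h <- tdLeakyRelu(e$d2$fwd(h), 0.2)
  e$d3$fwd(h)
}

## ---- model container --------------------------------------------------------

#' Build all sub-networks of the disentanglement model
#'
#' @param cfg A [netConfig()].
#' @param imageSize Side length of the (square) input slices; must be
#'   divisible by `2^depth`.
#' @return An environment holding every sub-network and its parameter groups.
#' @export
buildModel <- function(cfg = netConfig(), imageSize = 64L) {
  stopifnot(inherits(cfg, "netConfig"), imageSize %% 2L^cfg$depth == 0L)
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg; m$imageSize <- as.integer(imageSize)
  m$variant <- "full"
  m$enc <- newSkeletonEncoder(cfg)
  m$senc <- newSentiencyEncoder(cfg)
  m$film <- newFilmDecoder(cfg)
  m$spade <- newSpadeDecoder(cfg)
  m$recon <- newReconstructor(cfg)
  m$seg <- newSegmentor(cfg)
  m$dI <- newDiscriminator(cfg, imageSize)
  m$dIu <- newDiscriminator(cfg, imageSize)
  m$mine <- newMineNet(cfg)
  m$mainParams <- c(m$enc$params, m$senc$params, m$film$params, m$spade$params,
                    m$recon$params, m$seg$params)
  class(m) <- "cdModel"
  m
}

asBatchArray <- function(images) {
  d <- dim(images)
  if (length(d) == 2L) array(images, c(d, 1L, 1L))
  else if (length(d) == 3L) array(images, c(d[1], d[2], 1L, d[3]))
  else images
}

#' Encode images into the 8-channel spatial (anatomy) factor
#'
#' @param model A model from [buildModel()].
#' @param images `(H, W, B)` or `(H, W, 1, B)` array of normalized slices.
#' @param train Logical; training mode enables dropout and batch statistics.
#' @return A list with `soft` (values in `[0,1]`) and `hard` (binarized by
#'   straight-through rounding at 0.5) arrays of shape `(H, W, 8, B)`.
#' @export
skeletonEncode <- function(model, images, train = FALSE) {
  f <- fwdSkeleton(model$enc, tdConst(asBatchArray(images)), train)
  list(soft = f$soft$value, hard = f$hard$value)
}

#' Encode the style ("sentiency") latent code
#'
#' @inheritParams skeletonEncode
#' @param factor The hard spatial factor, `(H, W, 8, B)`.
#' @param eps Optional pre-drawn standard-normal noise (latent x B) for the
#'   reparameterization; ignored when `train = FALSE` (then `z = mu`).
#' @return List with `mu`, `logvar`, `z` (latent x B matrices) and `eps`.
#' @export
sentiencyEncode <- function(model, images, factor, train = FALSE, eps = NULL) {
  s <- fwdSentiency(model$senc, tdConst(asBatchArray(images)), tdConst(factor),
                    train, eps)
  list(mu = s$mu$value, logvar = s$logvar$value, z = s$z$value, eps = s$eps)
}

#' Feature-wise linear modulation
#'
#' Applies `gamma * feature + beta` per channel.
#'
#' @param feature `(H, W, C, B)` array.
#' @param gamma,beta Either length-C vectors or `(C, B)` matrices.
#' @return Modulated array of the same shape.
#' @export
filmModulate <- function(feature, gamma, beta) {
  d <- dim(feature)
  if (is.null(d) || length(d) != 4L) stop("feature must be a (H, W, C, B) array")
  expand <- function(v) {
    if (is.matrix(v)) {
      if (!all(dim(v) == d[3:4])) stop("modulation shape mismatch")
      array(rep(as.vector(v), each = d[1] * d[2]), dim = d)
    } else {
      if (length(v) != d[3]) stop("modulation shape mismatch")
      array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
    }
  }
  expand(gamma) * feature + expand(beta)
}

#' Shape-aware (SPADE) normalization
#'
#' Instance-normalizes `Fin`, optionally rescales the normalized map by a
#' per-channel scale/shift derived from the style code, then denormalizes it
#' with spatial maps `gammaMap`/`betaMap` derived from the spatial factor:
#' `Fout = IN(Fin) * gammaMap + betaMap`.
#'
#' @param Fin `(H, W, C, B)` feature array.
#' @param gammaMap,betaMap Spatial modulation maps of the same shape as `Fin`
#'   (in the trained decoder these are produced by convolutions over the
#'   nearest-neighbor-interpolated spatial factor).
#' @param zScale,zShift Optional per-channel (`C` vector or `C x B` matrix)
#'   modulation of the instance-normalized map; identity when omitted.
#' @param eps Variance floor.
#' @return Array of the same shape as `Fin`.
#' @export
spadeNormalize <- function(Fin, gammaMap, betaMap, zScale = NULL, zShift = NULL,
                           eps = 1e-5) {
  h <- tInstanceNorm(tdConst(Fin), eps)$value
  if (!is.null(zScale) || !is.null(zShift)) {
    d <- dim(Fin)
    zScale <- zScale %||% rep(1, d[3]); zShift <- zShift %||% rep(0, d[3])
    h <- filmModulate(h, zScale, zShift)
  }
  h * gammaMap + betaMap
}

#' Apply a normalized-projection layer
#'
#' EvoNorm-style normalization (batch + instance variance, no explicit
#' activation), per-channel affine, 1x1 convolution, Gaussian dropout.
#'
#' @param feature `(H, W, C, B)` array.
#' @param layer A layer created by `newEvonormProjection()`; created on the
#'   fly (identity-sized) when omitted.
#' @param train Training mode (enables dropout and batch-statistic updates).
#' @export
evonormProjection <- function(feature, layer = NULL, train = FALSE) {
  d <- dim(feature)
  if (is.null(layer)) layer <- newEvonormProjection(d[3], d[3], dropout = 0)
  layer$fwd(tdConst(feature), train)$value
}
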