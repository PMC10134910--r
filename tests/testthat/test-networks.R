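ns <- asNamespace("cardisent")

smallModel <- function(seed = 31L) {
  set.seed(seed)
  buildModel(netConfig(baseFilters = 4, segChannels = 8, depth = 2,
                       dropout = 0.1), imageSize = 32L)
}

test_that("the skeleton factor is eight-channel, near-binary and image-sized", {
  m <- smallModel()
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  f <- skeletonEncode(m, x)
  expect_equal(dim(f$soft), c(32L, 32L, 8L, 2L))
  expect_true(all(f$hard %in% c(0, 1)))
  expect_true(all(f$soft >= 0 & f$soft <= 1))
  expect_identical(f$hard, (f$soft > 0.5) * 1)
  expect_error(skeletonEncode(m, array(runif(30 * 30), c(30, 30, 1))),
               "divisible")
})

test_that("the style encoder follows the reparameterization identities", {
  m <- smallModel()
  x <- array(runif(32 * 32), c(32, 32, 1))
  f <- skeletonEncode(m, x)
  eps0 <- matrix(0, 8, 1)
  s0 <- sentiencyEncode(m, x, f$hard, train = TRUE, eps = eps0)
  expect_equal(s0$z, s0$mu)                          # eps = 0 -> z = mu
  eps1 <- matrix(1, 8, 1)
  s1 <- sentiencyEncode(m, x, f$hard, train = TRUE, eps = eps1)
  expect_equal(s1$z, s1$mu + exp(s1$logvar / 2), tolerance = 1e-12)
  e1 <- sentiencyEncode(m, x, f$hard, train = FALSE)
  e2 <- sentiencyEncode(m, x, f$hard, train = FALSE)
  expect_identical(e1$z, e2$z)                       # eval determinism
})

test_that("FiLM modulation is the per-channel affine map", {
  set.seed(32)
  feat <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  expect_equal(filmModulate(feat, rep(1, 3), rep(0, 3)), feat)
  expect_equal(filmModulate(feat, rep(0, 3), rep(2, 3)),
               array(2, dim(feat)))
  expect_equal(filmModulate(array(0.5, c(2, 2, 1, 1)), 2, -1),
               array(0, c(2, 2, 1, 1)))
  gm <- matrix(rnorm(6), 3, 2)
  out <- filmModulate(feat, gm, 0 * gm)
  expect_equal(out[1, 1, 2, 2], feat[1, 1, 2, 2] * gm[2, 2])
  expect_error(filmModulate(feat, rep(1, 4), rep(0, 4)), "mismatch")
})

test_that("SPADE with unit modulation is instance normalization", {
  set.seed(33)
  Fin <- array(rnorm(8 * 8 * 3 * 2, mean = 2, sd = 3), c(8, 8, 3, 2))
  ones <- array(1, dim(Fin)); zeros <- array(0, dim(Fin))
  out <- spadeNormalize(Fin, gammaMap = ones, betaMap = zeros)
  inorm <- ns$tInstanceNorm(ns$tdConst(Fin))$value
  expect_equal(out, inorm, tolerance = 1e-12)
  # per-(channel, sample) mean 0, sd ~ 1
  mu <- apply(out, c(3, 4), mean)
  expect_true(all(abs(mu) < 1e-10))
  # constant input collapses to the beta map
  Fc <- array(5, dim(Fin))
  beta <- array(rnorm(length(Fin)), dim(Fin))
  expect_equal(spadeNormalize(Fc, gammaMap = ones, betaMap = beta), beta,
               tolerance = 1e-9)
})

test_that("the trained SPADE block is sensitive to factor channel permutation", {
  set.seed(34)
  blk <- ns$newSpadeBlock(netConfig(baseFilters = 4), 4L)
  # exit the zero-init identity regime so the heads respond to the factor
  for (p in c(blk$gconv$params, blk$bconv$params))
    p$value[] <- rnorm(length(p$value), sd = 0.3)
  Fin <- ns$tdConst(array(rnorm(8 * 8 * 4 * 1), c(8, 8, 4, 1)))
  fsk <- array((runif(8 * 8 * 8) > 0.5) * 1, c(8, 8, 8, 1))
  z <- ns$tdConst(matrix(0, 8, 1))
  o1 <- ns$fwdSpadeBlock(blk, Fin, ns$tdConst(fsk), z)$value
  o2 <- ns$fwdSpadeBlock(blk, Fin, ns$tdConst(fsk[, , 8:1, , drop = FALSE]), z)$value
  expect_gt(mean(abs(o1 - o2)), 1e-6)
})

test_that("normalized projection is deterministic without dropout", {
  set.seed(35)
  layer <- ns$newEvonormProjection(3, 3, dropout = 0)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  tr <- evonormProjection(x, layer, train = TRUE)
  ev <- evonormProjection(x, layer, train = FALSE)
  expect_equal(dim(tr), dim(x))
  e2 <- evonormProjection(x, layer, train = FALSE)
  expect_identical(ev, e2)                           # eval determinism
  const <- array(1, c(8, 8, 3, 2))
  expect_true(all(is.finite(evonormProjection(const, layer, train = TRUE))))
})

test_that("segmentation head emits per-pixel probability simplices", {
  m <- smallModel()
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  f <- ns$genForward(m, ns$tdConst(ns$asBatchArray(x)), FALSE,
                     ns$variantFlags("full"))
  pv <- f$probs$value
  expect_equal(dim(pv), c(32L, 32L, 4L, 2L))
  s <- apply(pv, c(1, 2, 4), sum)
  expect_true(all(abs(s - 1) < 1e-9))
  expect_true(all(ns$argmaxMasks(pv) %in% 0:3))
  # uniform logits give probability 1/4 per class
  u <- ns$tdSoftmaxC(ns$tdConst(array(0.7, c(4, 4, 4, 1))))
  expect_true(all(abs(u$value - 0.25) < 1e-12))
})

test_that("discriminators score one unbounded scalar per sample", {
  m <- smallModel()
  probs <- randomProbs(32, 32, 4, 3)
  s1 <- ns$fwdDiscriminate(m$dI, ns$tdConst(probs), FALSE)$value
  expect_equal(dim(s1), c(1L, 3L))
  s2 <- ns$fwdDiscriminate(m$dI, ns$tdConst(probs), FALSE)$value
  expect_identical(s1, s2)                           # eval determinism
})

test_that("reconstruction output lies in [0, 1] at image size", {
  m <- smallModel()
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  f <- ns$genForward(m, ns$tdConst(ns$asBatchArray(x)), FALSE,
                     ns$variantFlags("full"))
  rv <- f$rec$value
  expect_equal(dim(rv), c(32L, 32L, 1L, 2L))
  expect_true(all(rv >= 0 & rv <= 1))
  # style sensitivity: two z draws, same factor, different reconstructions
  sp1 <- ns$fwdSpade(m$spade, ns$tdConst(matrix(2, 8, 2)), f$fsk$hard, FALSE)
  sp2 <- ns$fwdSpade(m$spade, ns$tdConst(matrix(-2, 8, 2)), f$fsk$hard, FALSE)
  expect_gt(mean(abs(sp1$value - sp2$value)), 0)
})

test_that("every loss term reaches its trainable parameters", {
  set.seed(36)
  m <- smallModel()
  m$allParams <- c(m$mainParams, m$dI$params, m$dIu$params, m$mine$params)
  st <- tinyStudy(nSubjects = 4L, labelFraction = 0.5, seed = 37L)
  # shrink to 32 px by cropping normalized slices
  img <- cropOrPad(normalizeSlice(studyImages(st, 1)$ED[, , 1]), 32)
  msk <- cropOrPad(studyMasks(st, 1)$ED[, , 1], 32)
  x <- array(img, c(32, 32, 1, 1)); y <- oneHotMasks(array(msk, c(32, 32, 1)))
  tc <- trainConfig(net = m$cfg, batchSize = 1)
  flags <- ns$variantFlags("full")
  fl <- ns$genForward(m, ns$tdConst(x), TRUE, flags)
  total <- ns$tdAdd(
    ns$tdAdd(ns$segSupLoss(y, fl$probs, flags, tc),
             ns$tSl2sim(ns$tdConst(x), fl$rec, tc$recon)),
    ns$tdAdd(ns$tKlGaussian(fl$sent$mu, fl$sent$logvar),
             ns$tMine(m$mine, ns$tdInstMean(fl$fsk$soft), fl$sent$z, 1)))
  ns$tdBackward(total)
  gnorm <- function(ps) sqrt(sum(sapply(ps, function(p)
    if (is.null(p$grad)) 0 else sum(p$grad^2))))
  expect_gt(gnorm(m$enc$params), 0)
  expect_gt(gnorm(m$senc$params), 0)
  expect_gt(gnorm(m$film$params), 0)
  expect_gt(gnorm(m$spade$params), 0)
  expect_gt(gnorm(m$recon$params), 0)
  expect_gt(gnorm(m$seg$params), 0)
  expect_gt(gnorm(m$mine$params), 0)
  expect_true(is.finite(total$value))
})
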