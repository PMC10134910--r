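# Finite-difference validation of the reverse-mode engine. Each case builds a
# scalar loss through a representative chain of primitives and compares every
# parameter gradient against central differences.

ns <- asNamespace("cardisent")

fdExpect <- function(makeLoss, params, h = 1e-5, tol = 2e-3) {
  loss <- makeLoss()
  ns$tdBackward(loss)
  for (p in params) {
    g <- p$grad
    expect_false(is.null(g))
    idx <- sample(length(p$value), min(3, length(p$value)))
    for (i in idx) {
      v0 <- p$value[i]
      p$value[i] <- v0 + h; lp <- makeLoss()$value
      p$value[i] <- v0 - h; lm <- makeLoss()$value
      p$value[i] <- v0
      fd <- (lp - lm) / (2 * h)
      expect_equal(unname(g[i]), fd, tolerance = tol * max(1, abs(fd)))
    }
    p$grad <- NULL
  }
}

test_that("conv / pooling / normalization chain backpropagates correctly", {
  set.seed(21)
  cv <- ns$newConv(2, 3)
  bn <- ns$newBatchNorm(3)
  ep <- ns$newEvonormProjection(3, 3, dropout = 0)
  xa <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  fdExpect(function() {
    h <- cv$fwd(ns$tdConst(xa))
    h <- ns$tdLeakyRelu(bn$fwd(h, TRUE), 0.2)
    h <- ep$fwd(h, TRUE)
    h <- ns$tdUpsample2(ns$tdAvgPool2(h))
    ns$tdMeanAll(ns$tdSquare(h))
  }, c(cv$params, bn$params, ep$params))
})

test_that("softmax head with focal and dice losses backpropagates correctly", {
  set.seed(22)
  cv <- ns$newConv(2, 4)
  xa <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  y <- randomOnehot(8, 8, 4, 2)
  fdExpect(function() {
    p <- ns$tdSoftmaxC(cv$fwd(ns$tdConst(xa)))
    ns$tdAdd(ns$tWeightedSoftFocal(ns$tdConst(y), p, focalParams()),
             ns$tBackgroundFocalDice(ns$tdConst(y), p, 2, 1e-6))
  }, cv$params)
})

test_that("SSIM reconstruction loss and KL backpropagate correctly", {
  set.seed(23)
  cv <- ns$newConv(1, 1)
  xb <- array(runif(12 * 12), c(12, 12, 1, 1))
  fdExpect(function() {
    ns$tSl2sim(ns$tdConst(xb), ns$tdSigmoid(cv$fwd(ns$tdConst(xb))), reconParams())
  }, cv$params)
  dmu <- ns$newDense(3, 4); dlv <- ns$newDense(3, 4)
  zin <- matrix(rnorm(6), 3, 2)
  fdExpect(function() {
    ns$tKlGaussian(dmu$fwd(ns$tdConst(zin)), dlv$fwd(ns$tdConst(zin)))
  }, c(dmu$params, dlv$params))
})

test_that("the MI statistic path backpropagates into both inputs", {
  set.seed(24)
  sn <- newStatNet(3, 2, hidden = 8)
  sA <- matrix(rnorm(30), 3, 10)
  din <- ns$newDense(3, 2)
  fdExpect(function() {
    zt <- din$fwd(ns$tdConst(sA))
    ns$tMine(sn, ns$tdConst(sA), zt, c(2:10, 1))
  }, c(sn$params, din$params))
})

test_that("straight-through rounding is hard forward, identity backward", {
  set.seed(25)
  x <- ns$tdParam(matrix(runif(16), 4))
  h <- ns$tdSTRound(ns$tdSigmoid(ns$tdMul(x, 2)))
  expect_true(all(h$value %in% c(0, 1)))
  loss <- ns$tdMeanAll(ns$tdSquare(h))
  ns$tdBackward(loss)
  expect_false(is.null(x$grad))
  expect_gt(sum(abs(x$grad)), 0)                     # gradients pass through
})

test_that("Adam with global clipping updates and zeroes gradients", {
  set.seed(26)
  p <- ns$tdParam(rep(1, 4))
  opt <- ns$newAdam(list(p), lr = 0.1, clip = 1e-3)  # force clipping
  loss <- ns$tdMeanAll(ns$tdSquare(p))
  ns$tdBackward(loss)
  gn <- ns$adamStep(opt)
  expect_gt(gn, 1e-3)                                # clip engaged
  expect_null(p$grad)
  expect_true(all(p$value < 1))                      # moved downhill
})
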