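test_that("weighted soft focal loss matches its closed forms and oracle", {
  # gamma -> 0, alpha0 = alpha1 = 1, uniform weights reduces to plain CE
  y <- array(1, c(1, 1, 1, 1)); p <- array(0.5, c(1, 1, 1, 1))
  fp <- suppressWarnings(focalParams(1, 1, gamma = 0, wMap = "uniform"))
  expect_equal(weightedSoftFocal(y, p, fp), -log(0.5), tolerance = 1e-9)
  # printed-precision example: y=1, p=0.9, gamma=2, alpha=(0.25, 0.75)
  p9 <- array(0.9, c(1, 1, 1, 1))
  fp2 <- focalParams(0.25, 0.75, 2, wMap = "uniform")
  expect_equal(weightedSoftFocal(y, p9, fp2), 0.75 * 0.01 * -log(0.9),
               tolerance = 1e-9)
  # perfect prediction vanishes
  y4 <- randomOnehot(4, 4)
  expect_lt(weightedSoftFocal(y4, pmin(pmax(y4, 1e-7), 1 - 1e-7), fp2), 1e-5)
  # 4x4 brute-force oracle, uniform weights
  set.seed(2)
  p4 <- randomProbs(4, 4)
  expect_equal(weightedSoftFocal(y4, p4, fp2),
               oracleWSFL(y4, p4, 0.25, 0.75, 2), tolerance = 1e-6)
  # inverse-frequency weights agree with an explicitly constructed map
  fp3 <- focalParams(0.25, 0.75, 2, wMap = "inverse_freq")
  w <- cardisent:::wsbfWeightMap(y4, fp3)
  expect_equal(mean(w[, , 1, ][y4[, , 1, , drop = FALSE] >= 0]), mean(w[, , 1, ]))
  expect_equal(weightedSoftFocal(y4, p4, fp3),
               oracleWSFL(y4, p4, 0.25, 0.75, 2, w), tolerance = 1e-6)
})

test_that("background focal dice matches direct summation", {
  y <- randomOnehot(4, 4)
  expect_lt(backgroundFocalDice(y, y, 2, 1e-6), 1e-9)   # perfect overlap
  set.seed(5)
  p <- randomProbs(4, 4)
  expect_equal(backgroundFocalDice(y, p, 2, 1e-6),
               oracleBFD(y, p, 2, 1e-6), tolerance = 1e-6)
  # 2x2 toy from a single class column
  y2 <- array(0, c(2, 2, 2, 1)); y2[, , 1, ][1:2] <- 1; y2[, , 2, ] <- 1 - y2[, , 1, ]
  p2 <- array(0, c(2, 2, 2, 1)); p2[, , 1, ] <- c(0.8, 0.6, 0.3, 0.1)
  p2[, , 2, ] <- 1 - p2[, , 1, ]
  expect_equal(backgroundFocalDice(y2, p2, 2, 1e-6),
               oracleBFD(y2, p2, 2, 1e-6), tolerance = 1e-6)
  # empty-class guard: all-background truth, zero prediction for that class
  y0 <- array(0, c(3, 3, 2, 1)); y0[, , 1, ] <- 1
  p0 <- y0
  expect_lt(backgroundFocalDice(y0, p0, 2, 1e-6), 1e-9)
})

test_that("Geman-McClure saturation has the stated fixed points", {
  expect_equal(advGM(0), 0)
  expect_equal(advGM(1, gmParams(0.5)), 0.5)
  expect_gte(advGM(1e6), 0.999)
  expect_error(gmParams(1.5))
  set.seed(1)
  for (N in rexp(20, 0.5)) {
    v <- advGM(N)
    expect_gte(v, 0); expect_lt(v, 1)                # range [0, 1)
  }
})

test_that("Gaussian KL has its closed form and is non-negative", {
  expect_equal(klGaussian(0, 0), 0)
  expect_equal(klGaussian(1, 0), 0.5)                # 1/2 (mu^2 + 1 - 1 - 0)
  set.seed(6)
  for (i in 1:20) {
    mu <- matrix(rnorm(8), 4); lv <- matrix(rnorm(8, sd = 0.5), 4)
    kl <- klGaussian(mu, lv)
    expect_gte(kl, 0)
    direct <- mean(colSums(0.5 * (mu^2 + exp(lv) - 1 - lv)))
    expect_equal(kl, direct, tolerance = 1e-9)
  }
})

test_that("SL2SIM combines windowed SSIM and mean squared error", {
  set.seed(7)
  x <- matrix(runif(16^2, 0.1, 0.9), 16)
  expect_equal(sl2sim(x, x), 0, tolerance = 1e-9)
  expect_gt(sl2sim(x, 1 - x), 1)                     # SSIM can be negative
  # constant images: L2 part exact, SSIM part against the windowed oracle
  xc <- matrix(0.5, 16, 16); yc <- matrix(0.25, 16, 16)
  expect_equal(sl2sim(xc, yc, reconParams(alphaL2 = 1)),
               1 - oracleSSIM(xc, yc) + 0.0625, tolerance = 1e-9)
  # random-image oracle agreement
  y <- matrix(runif(16^2, 0.1, 0.9), 16)
  expect_equal(sl2sim(x, y, reconParams(alphaL2 = 0.5)),
               1 - oracleSSIM(x, y) + 0.5 * mean((x - y)^2), tolerance = 1e-6)
})

test_that("a constant MINE statistic gives exactly zero information", {
  net <- newStatNet(2, 2, hidden = 8)
  for (p in net$params) p$value[] <- 0
  net$d3$b$value <- 3.7                              # T == 3.7 everywhere
  x <- matrix(rnorm(40), 2); y <- matrix(rnorm(40), 2)
  expect_equal(mineEstimate(net, x, y, perm = c(2:20, 1)), 0, tolerance = 1e-12)
  expect_error(mineEstimate(net, x[, 1, drop = FALSE], y[, 1, drop = FALSE]),
               "at least 2")
})

test_that("the total objective is the stated weighted sum", {
  comps <- list(seg = 0, advLabeled = 0, advUnlabeled = 0, vae = 0,
                reconLabeled = 0, reconUnlabeled = 0, mim = 0)
  expect_equal(totalLoss(comps), 0)
  ones <- list(seg = 1, advLabeled = 1, advUnlabeled = 0, vae = 1,
               reconLabeled = 1, reconUnlabeled = 0, mim = 1)
  expect_equal(totalLoss(ones), 10 + 10 + 0.01 + 0.01 + 1)  # = 21.02
  w2 <- lossWeights(lambdaSeg = 20)
  expect_equal(totalLoss(ones, w2) - totalLoss(ones), 10)  # linear in lambda_seg
  bad <- ones; bad$vae <- -1
  expect_error(totalLoss(bad), "non-negative")
  expect_error(totalLoss(ones[-1]), "missing components")
})

test_that("losses stay finite on clamped probability extremes", {
  y <- randomOnehot(4, 4)
  pExtreme <- y                                       # exact 0/1 before clamping
  expect_true(is.finite(weightedSoftFocal(y, pExtreme)))
  expect_true(is.finite(backgroundFocalDice(y, pExtreme)))
  expect_true(is.finite(sl2sim(matrix(0, 8, 8), matrix(1, 8, 8))))
})
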