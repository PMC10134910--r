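ns <- asNamespace("cardisent")

tinyTC <- function(variant = "full", epochs = 1L, seed = 41L) {
  trainConfig(epochs = epochs, batchSize = 2L, lr = 1e-3, variant = variant,
              seed = seed, net = netConfig(baseFilters = 4, segChannels = 8,
                                           depth = 2, dropout = 0),
              stepsPerEpoch = 2L, valEvery = 1L,
              splitFractions = c(0.5, 0.25, 0.25), warmupEpochs = 0L)
}

test_that("zero-epoch fits return an initialized, restorable checkpoint", {
  st <- tinyStudy(nSubjects = 4L, labelFraction = 0.5, seed = 43L)
  ck <- fitModel(st, tinyTC(epochs = 0L))
  expect_s3_class(ck, "cdCheckpoint")
  expect_equal(nrow(ck$log), 0L)
  m <- restoreModel(ck)
  p <- predictSlices(m, array(0.5, c(64, 64, 1)))
  expect_true(all(p$masks %in% 0:3))
})

test_that("identical seeds give identical loss trajectories", {
  st <- tinyStudy(nSubjects = 4L, labelFraction = 0.5, seed = 43L)
  ck1 <- fitModel(st, tinyTC())
  ck2 <- fitModel(st, tinyTC())
  expect_identical(ck1$log, ck2$log)
  expect_identical(ck1$split, ck2$split)
})

test_that("training reduces the objective on a tiny seeded run", {
  st <- tinyStudy(nSubjects = 4L, labelFraction = 0.5, seed = 44L)
  tc <- tinyTC(epochs = 5L)
  tc$stepsPerEpoch <- 4L
  ck <- fitModel(st, tc)
  expect_lt(ck$history$meanTotal[5], ck$history$meanTotal[1])
})

test_that("disabled variant losses contribute no updates to their networks", {
  st <- tinyStudy(nSubjects = 4L, labelFraction = 0.5, seed = 45L)
  # an untouched parameter keeps zero Adam moments; an updated one does not
  momentNorm <- function(m, ps) sum(sapply(ps, function(p) sum(abs(p$m))))
  ck4 <- fitModel(st, tinyTC(variant = "noMIM"))
  m4 <- restoreModel(ck4)
  expect_equal(momentNorm(m4, m4$mine$params), 0)    # MI net never stepped
  expect_gt(momentNorm(m4, m4$seg$params), 0)
  ck1 <- fitModel(st, tinyTC(variant = "ganOnly"))
  m1 <- restoreModel(ck1)
  expect_equal(momentNorm(m1, m1$senc$params), 0)    # no style encoder updates
  expect_equal(momentNorm(m1, m1$spade$params), 0)
  expect_equal(momentNorm(m1, m1$recon$params), 0)
  expect_equal(momentNorm(m1, m1$mine$params), 0)
  expect_gt(momentNorm(m1, m1$dI$params), 0)         # adversarial path active
  cks <- fitModel(st, tinyTC(variant = "supervised"))
  ms <- restoreModel(cks)
  expect_equal(momentNorm(ms, ms$dI$params), 0)      # no discriminator updates
  expect_gt(momentNorm(ms, ms$enc$params), 0)
})

test_that("checkpoints round-trip bit-identically through save and restore", {
  st <- tinyStudy(nSubjects = 4L, labelFraction = 0.5, seed = 46L)
  ck <- fitModel(st, tinyTC(epochs = 2L))
  m1 <- restoreModel(ck)
  img <- array(runif(64 * 64 * 2), c(64, 64, 2))
  p1 <- predictSlices(m1, img)
  f <- tempfile(fileext = ".rds")
  saveRDS(ck, f)
  m2 <- restoreModel(readRDS(f))
  p2 <- predictSlices(m2, img)
  expect_identical(p1$masks, p2$masks)
  expect_identical(p1$recon, p2$recon)
  expect_identical(p1$code$z, p2$code$z)
  expect_identical(p1$masks, predictSlices(m1, img)$masks)  # determinism
  unlink(f)
})

test_that("fitting requires a labeled subject and matching image sizes", {
  st <- tinyStudy(nSubjects = 4L, labelFraction = 0.5, seed = 47L)
  st@subjects$labeled[] <- FALSE
  expect_error(fitModel(st, tinyTC()), "no labeled subject")
  ck <- fitModel(tinyStudy(nSubjects = 4L, labelFraction = 0.5, seed = 47L),
                 tinyTC(epochs = 0L))
  m <- restoreModel(ck)
  expect_error(predictSlices(m, array(0.1, c(32, 32, 1))), "image size")
})
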