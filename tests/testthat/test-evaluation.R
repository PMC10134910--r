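test_that("dice and jaccard match direct set counting", {
  T1 <- matrix(FALSE, 2, 2); T1[1, 1] <- T1[1, 2] <- TRUE
  P1 <- matrix(FALSE, 2, 2); P1[1, 2] <- P1[2, 2] <- TRUE
  expect_equal(diceCoef(T1, P1), 0.5)                # 2*1 / (2+2)
  expect_equal(jaccardIndex(T1, P1), 1 / 3)
  expect_equal(diceCoef(T1, T1), 1)
  expect_equal(diceCoef(T1, !T1 & !P1 | P1 & !T1), 0)  # disjoint
  expect_equal(diceCoef(T1 & FALSE, P1 & FALSE), 1)  # both empty
  expect_error(diceCoef(T1, matrix(FALSE, 3, 3)), "shapes differ")
})

test_that("J = D / (2 - D) holds on random mask pairs", {
  set.seed(8)
  for (i in 1:100) {
    a <- matrix(runif(100) < 0.4, 10)
    b <- matrix(runif(100) < 0.4, 10)
    D <- diceCoef(a, b)
    expect_equal(jaccardIndex(a, b), D / (2 - D), tolerance = 1e-12)
    expect_equal(diceCoef(b, a), D)                  # symmetry
  }
})

test_that("precision and recall count pixels correctly", {
  T1 <- matrix(c(TRUE, TRUE, FALSE), 1)
  P1 <- matrix(c(TRUE, TRUE, TRUE), 1)               # TP 2, FP 1, FN 0
  pr <- precisionRecall(T1, P1)
  expect_equal(unname(pr), c(2 / 3, 1))
  expect_equal(unname(precisionRecall(T1, T1)), c(1, 1))
  sup <- precisionRecall(P1 & FALSE, P1 & FALSE)
  expect_equal(unname(sup), c(1, 1))                 # both-empty convention
})

test_that("Hausdorff distance matches brute-force pairwise distances", {
  A <- matrix(FALSE, 8, 8); A[1, 1] <- TRUE
  B <- matrix(FALSE, 8, 8); B[4, 5] <- TRUE          # 3-4-5 triangle
  expect_equal(hausdorffDistance(A, B, spacing = 1), 5)
  expect_equal(hausdorffDistance(A, B, spacing = 2), 10)
  expect_equal(hausdorffDistance(A, A), 0)
  set.seed(3)
  for (i in 1:8) {
    a <- matrix(runif(144) < 0.3, 12); b <- matrix(runif(144) < 0.3, 12)
    if (sum(a) == 0 || sum(b) == 0) next
    hd <- hausdorffDistance(a, b)
    expect_equal(hd, oracleHausdorff(a, b), tolerance = 1e-9)
    expect_equal(hd, hausdorffDistance(b, a))        # symmetry
  }
  expect_error(hausdorffDistance(A, A & FALSE), "empty mask")
})

test_that("PSNR and correlation have their closed forms", {
  set.seed(4)
  x <- matrix(runif(64^2, 0.2, 0.8), 64)
  same <- psnrCc(x, x)
  expect_equal(unname(same), c(Inf, 1))
  off <- psnrCc(x, x + 0.1)                          # MSE 0.01 -> 20 dB
  expect_equal(unname(off[1]), 20, tolerance = 1e-9)
  expect_equal(unname(off[2]), 1, tolerance = 1e-12)
  expect_equal(unname(psnrCc(x, 1 - x)[2]), -1, tolerance = 1e-12)
  expect_true(is.na(psnrCc(matrix(0.5, 4, 4), matrix(0.2, 4, 4))[2]))
})

test_that("Simpson volumetry is count x pixel area x thickness", {
  m <- array(0L, c(20, 20, 5))
  m[1:10, 1:10, ] <- 1L                              # 100 px per slice
  expect_equal(simpsonVolume(m, 1, 10), 5000)
  expect_equal(simpsonVolume(m * 0L, 1, 10), 0)
  expect_equal(simpsonVolume(m, 1.37, 8), 500 * 1.37^2 * 8)
})

test_that("clinical indices implement the volumetric definitions", {
  ed <- array(0L, c(30, 30, 4)); es <- ed
  ed[1:10, 1:10, ] <- 3L; es[1:7, 1:7, ] <- 3L       # LV pool
  ed[15:24, 15:24, ] <- 2L; es[15:24, 15:24, ] <- 2L # myocardium
  ed[1:5, 20:24, ] <- 1L; es[1:4, 20:23, ] <- 1L     # RV
  ci <- clinicalIndices(ed, es, spacing = 5, thickness = 10)
  myoCm3 <- 100 * 4 * 25 * 10 / 1000
  expect_equal(ci$myo_mass_g, myoCm3 * 1.06)         # density 1.06 g/cm^3
  edv <- 100 * 4 * 25 * 10; esv <- 49 * 4 * 25 * 10
  expect_equal(ci$sv_ml, (edv - esv) / 1000)
  expect_equal(ci$ef_percent, (edv - esv) / edv * 100)
  same <- clinicalIndices(ed, ed, 5, 10)
  expect_equal(same$ef_percent, 0)                   # no ejection
  expect_error(clinicalIndices(es * 0L, es, 5, 10), "EDV is zero")
})

test_that("EDV 120 mL / ESV 50 mL gives SV 70 mL and EF 58.33%", {
  # direct arithmetic on the definitions used by clinicalIndices
  edv <- 120; esv <- 50
  expect_equal(edv - esv, 70)
  expect_equal((edv - esv) / edv * 100, 58.33, tolerance = 1e-2)
})

test_that("evaluateSegmentation aggregates per structure and subject", {
  st <- tinyStudy(nSubjects = 3L)
  ref <- lapply(1:2, function(s) studyMasks(st, s))
  rep <- evaluateSegmentation(ref, ref, st@config$pixelSpacing,
                              st@config$sliceThickness)
  expect_s4_class(rep, "MetricsReport")
  m <- rep@summary[rep@summary$stat == "mean", ]
  expect_true(all(m$dice == 1))
  expect_true(all(m$hausdorff_mm == 0))
  expect_equal(nrow(rep@clinical), 2L)
})
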