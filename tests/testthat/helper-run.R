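# Shared end-to-end run for the acceptance tests. The semi-supervised
# trainings are expensive, so they are computed once per session and cached;
# the disentanglement tests reuse the same checkpoint.

.runCache <- new.env(parent = emptyenv())

acceptanceConditions <- function() {
  list(studyCfg = phantomConfig(imageSize = 64L, nSubjects = 100L,
                                nSlices = 3L, labelFraction = 0.01,
                                seed = 42L),
       net = netConfig(baseFilters = 16L, segChannels = 32L, depth = 2L),
       epochs = 20L, stepsPerEpoch = 10L, lr = 2.5e-3, seed = 7L)
}

acceptanceStudy <- function() {
  if (is.null(.runCache$study))
    .runCache$study <- generateStudy(acceptanceConditions()$studyCfg)
  .runCache$study
}

acceptanceFit <- function(variant) {
  key <- paste0("fit_", variant)
  if (is.null(.runCache[[key]])) {
    cond <- acceptanceConditions()
    steps <- switch(variant, supervised = 3L, ganOnly = 7L, cond$stepsPerEpoch)
    tc <- trainConfig(epochs = cond$epochs, batchSize = 4L, lr = cond$lr,
                      variant = variant, seed = cond$seed, net = cond$net,
                      stepsPerEpoch = steps,
                      valEvery = if (variant == "full") 2L else 4L,
                      warmupEpochs = 6L, valSubjects = 8L, mineRatio = 4L)
    .runCache[[key]] <- fitModel(acceptanceStudy(), tc)
  }
  .runCache[[key]]
}

heldOutMeanDice <- function(ck) {
  study <- acceptanceStudy()
  model <- restoreModel(ck)
  testIds <- ck$split$test
  preds <- predictStudy(model, study, testIds)
  vals <- c()
  for (s in testIds) {
    pm <- preds[[as.character(s)]]$masks
    for (fr in c("ED", "ES")) for (k in seq_len(dim(pm[[fr]])[3]))
      for (lab in 1:3)
        vals <- c(vals, diceCoef(studyMasks(study, s)[[fr]][, , k] == lab,
                                 pm[[fr]][, , k] == lab))
  }
  mean(vals)
}

normalizedStack <- function(study, s, fr = "ED") {
  a <- studyImages(study, s)[[fr]]
  for (k in seq_len(dim(a)[3])) a[, , k] <- normalizeSlice(a[, , k])
  a
}
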