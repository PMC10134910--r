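# Semi-supervised optimization loop.
#
# Each step performs, in order: (1) discriminator updates for the labeled
# and unlabeled mask discriminators (least-squares residuals, Geman-McClure
# saturated, on detached generator outputs); (2) a statistic-network update
# ascending the mutual-information bound on detached factors; (3) the main
# update of encoders, decoders, reconstructor and segmentor minimizing the
# weighted total objective of the active variant. The adversarial players
# never share an optimizer step with the generator.

VARIANTS <- c("full", "noFocalCE", "plainAdv", "diceCE", "noMIM",
              "ganOnly", "ganRec", "supervised")

variantFlags <- function(variant) {
  v <- match.arg(variant, VARIANTS)
  list(
    segLoss = switch(v, noFocalCE = "bfdOnly", diceCE = "diceCE", "wsbf"),
    advMode = switch(v, plainAdv = "ls", supervised = "none", "gm"),
    useRecon = !(v %in% c("ganOnly", "supervised")),
    useVae = !(v %in% c("ganOnly", "supervised")),
    useMim = v %in% c("full", "noFocalCE", "plainAdv", "diceCE"),
    useZ = !(v %in% c("ganOnly", "supervised")),
    variant = v)
}

#' Training configuration
#'
#' @param epochs Training epochs (full-scale default 100).
#' @param batchSize Slices per stream per step.
#' @param lr Adam learning rate.
#' @param variant Model/ablation variant: `"full"` (all losses),
#'   `"noFocalCE"` (drops the weighted soft focal CE term, keeps the focal
#'   dice), `"plainAdv"` (raw least-squares adversarial loss instead of the
#'   Geman-McClure saturation), `"diceCE"` (plain dice + cross-entropy
#'   supervised loss), `"noMIM"` (without the mutual-information minimizer),
#'   `"ganOnly"` (adversarial path only: no style code, reconstruction or MI
#'   term), `"ganRec"` (adversarial + reconstruction, no MI term),
#'   `"supervised"` (labeled segmentation loss only).
#' @param seed Seed for all randomness in a run.
#' @param weights,focal,gm,recon Loss parameter bundles.
#' @param net A [netConfig()].
#' @param stepsPerEpoch Cap on optimizer steps per epoch (NULL = one pass
#'   over the unlabeled pool).
#' @param augment Apply on-the-fly augmentation to training slices.
#' @param splitFractions Subject-level train/val/test fractions.
#' @param valEvery Validate (and checkpoint on improvement) every k epochs.
#' @param valSubjects Cap on the number of validation subjects scored per
#'   validation pass (model selection only; final evaluation always uses the
#'   full test partition).
#' @param mineRatio Statistic-network ascent steps per main step (a tighter
#'   Donsker-Varadhan bound gives the encoders a cleaner minimization
#'   gradient).
#' @param clip Global gradient-norm clip.
#' @param warmupEpochs Epochs over which the adversarial and
#'   mutual-information weights ramp linearly from 0 to their configured
#'   values (the supervised, VAE and reconstruction terms are active from the
#'   start). Lets the segmentor acquire signal before the min-max pressure
#'   kicks in.
#' @export
trainConfig <- function(epochs = 100L, batchSize = 4L, lr = 1e-4,
                        variant = "full", seed = 1L,
                        weights = lossWeights(), net = netConfig(),
                        focal = focalParams(), gm = gmParams(),
                        recon = reconParams(), stepsPerEpoch = NULL,
                        augment = TRUE, splitFractions = c(0.7, 0.15, 0.15),
                        valEvery = 1L, clip = 50.0, warmupEpochs = 2L,
                        valSubjects = Inf, mineRatio = 1L) {
  stopifnot(batchSize >= 1L, epochs >= 0L)
  variant <- match.arg(variant, VARIANTS)
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 lr = lr, variant = variant, seed = as.integer(seed),
                 weights = weights, net = net, focal = focal, gm = gm,
                 recon = recon, stepsPerEpoch = stepsPerEpoch,
                 augment = isTRUE(augment), splitFractions = splitFractions,
                 valEvery = as.integer(valEvery), clip = clip,
                 warmupEpochs = as.integer(warmupEpochs),
                 valSubjects = valSubjects, mineRatio = as.integer(mineRatio)),
            class = "trainConfig")
}

## ---- forward passes ---------------------------------------------------------

genForward <- function(model, x, train, flags, needRecon = TRUE) {
  fsk <- fwdSkeleton(model$enc, x, train)
  B <- dim(x$value)[4]
  if (flags$useZ) {
    sent <- fwdSentiency(model$senc, x, fsk$hard, train)
  } else {
    z0 <- tdConst(matrix(0, model$cfg$latent, B))
    sent <- list(mu = z0, logvar = z0, z = z0, eps = NULL)
  }
  film <- fwdFilm(model$film, fsk$hard, sent$z, train)
  probs <- fwdSegment(model$seg, film$penult, train)
  rec <- NULL
  if (needRecon && flags$useRecon) {
    sp <- fwdSpade(model$spade, sent$z, fsk$hard, train)
    rec <- fwdReconstruct(model$recon, film$features, sp)
  }
  list(fsk = fsk, sent = sent, film = film, probs = probs, rec = rec)
}

segSupLoss <- function(y1h, probs, flags, tc) {
  yN <- tdConst(y1h)
  switch(flags$segLoss,
    wsbf = tdAdd(tWeightedSoftFocal(yN, probs, tc$focal),
                 tBackgroundFocalDice(yN, probs, tc$focal$gamma, tc$focal$epsilon)),
    bfdOnly = tBackgroundFocalDice(yN, probs, tc$focal$gamma, tc$focal$epsilon),
    diceCE = {
      p <- tdClamp(probs, PROB_CLAMP, 1 - PROB_CLAMP)
      ce <- tdNeg(tdMeanAll(tdMul(yN, tdLog(p)))) # standard multi-class CE (mean)
      L <- dim(y1h)[3]
      diceL <- NULL
      for (c in seq_len(L)) {
        t <- tdSub(1, softDice(tdSliceC(yN, c), tdSliceC(probs, c), tc$focal$epsilon))
        diceL <- if (is.null(diceL)) t else tdAdd(diceL, t)
      }
      tdAdd(tdMul(ce, L), tdMul(diceL, 1 / L))
    })
}

lsResidualD <- function(disc, fake, real, train) {
  sf <- fwdDiscriminate(disc, fake, train)
  sr <- fwdDiscriminate(disc, real, train)
  tdAdd(tdMeanAll(tdSquare(sf)), tdMeanAll(tdSquare(tdSub(sr, 1))))
}

lsResidualG <- function(disc, fake, train) {
  tdMeanAll(tdSquare(tdSub(fwdDiscriminate(disc, fake, train), 1)))
}

advWrap <- function(residual, flags, tc) {
  if (flags$advMode == "gm") tAdvGM(residual, tc$gm) else residual
}

mimInputs <- function(fsk, sent) {
  list(s = tdInstMean(fsk$soft), z = sent$z)   # global-average-pooled factor
}

## ---- one optimization step --------------------------------------------------

#' One semi-supervised training step
#'
#' Runs the discriminator updates, the statistic-network update and the main
#' update on one labeled and one unlabeled batch; records every loss
#' component in the state.
#'
#' @param model A [buildModel()] environment with attached optimizers
#'   (see [fitModel()]); arrays as produced internally by the batch
#'   assembler.
#' @param state Mutable training-state environment.
#' @param xl,y1h Labeled images `(H, W, 1, B)` and one-hot masks.
#' @param xu Unlabeled images (may be `NULL` for the supervised variant).
#' @param tc A [trainConfig()].
#' @return The updated state (invisibly).
#' @export
trainStep <- function(model, state, xl, y1h, xu, tc, ramp = 1) {
  flags <- variantFlags(tc$variant)
  w <- tc$weights
  w$lambdaAdvGm <- w$lambdaAdvGm * ramp
  w$lambdaMim <- w$lambdaMim * ramp
  xlN <- tdConst(xl)
  fl <- genForward(model, xlN, TRUE, flags)
  fu <- NULL
  if (!is.null(xu) && flags$advMode != "none") {
    fu <- genForward(model, tdConst(xu), TRUE, flags)
  }

  comp <- list()
  # (1) discriminator updates on detached generator outputs
  if (flags$advMode != "none") {
    dLossL <- advWrap(lsResidualD(model$dI, tdConst(fl$probs$value),
                                  tdConst(y1h), TRUE), flags, tc)
    tdBackward(dLossL); adamStep(model$optDI); zeroGrads(model$allParams)
    comp$dLossLab <- dLossL$value
    if (!is.null(fu)) {
      dLossU <- advWrap(lsResidualD(model$dIu, tdConst(fu$probs$value),
                                    tdConst(y1h), TRUE), flags, tc)
      tdBackward(dLossU); adamStep(model$optDIu); zeroGrads(model$allParams)
      comp$dLossUnlab <- dLossU$value
    }
  }

  # (2) statistic-network update (ascends the MI bound, factors detached)
  if (flags$useMim) {
    sDet <- tdConst(tdInstMean(fl$fsk$soft)$value)
    zDet <- tdConst(fl$sent$z$value)
    if (!is.null(fu)) {
      sDet <- tdConst(cbind(sDet$value, tdInstMean(fu$fsk$soft)$value))
      zDet <- tdConst(cbind(zDet$value, fu$sent$z$value))
    }
    for (k in seq_len(tc$mineRatio %||% 1L)) {
      miDet <- tMine(model$mine, sDet, zDet, sample.int(ncol(zDet$value)))
      tdBackward(miDet, seed = -1); adamStep(model$optMine)
      zeroGrads(model$allParams)
    }
  }

  # (3) main update
  segL <- segSupLoss(y1h, fl$probs, flags, tc)
  comp$seg <- segL$value
  total <- tdMul(segL, w$lambdaSeg)
  zero <- tdConst(0)
  advLab <- advUnlab <- vae <- recL <- recU <- mim <- zero
  if (flags$advMode != "none") {
    advLab <- advWrap(lsResidualG(model$dI, fl$probs, TRUE), flags, tc)
    total <- tdAdd(total, tdMul(advLab, w$lambdaAdvGm))
    if (!is.null(fu)) {
      advUnlab <- advWrap(lsResidualG(model$dIu, fu$probs, TRUE), flags, tc)
      total <- tdAdd(total, tdMul(advUnlab, w$lambdaAdvGm))
    }
  }
  if (flags$useVae) {
    mu <- fl$sent$mu; lv <- fl$sent$logvar
    if (!is.null(fu)) {
      mu <- tdRbindCols(mu, fu$sent$mu); lv <- tdRbindCols(lv, fu$sent$logvar)
    }
    vae <- tKlGaussian(mu, lv)
    total <- tdAdd(total, tdMul(vae, w$lambdaVae))
  }
  if (flags$useRecon) {
    recL <- tSl2sim(xlN, fl$rec, tc$recon)
    total <- tdAdd(total, tdMul(recL, w$lambdaSl2sim))
    if (!is.null(fu)) {
      recU <- tSl2sim(tdConst(xu), fu$rec, tc$recon)
      total <- tdAdd(total, tdMul(recU, w$lambdaSl2sim))
    }
  }
  if (flags$useMim) {
    s <- tdInstMean(fl$fsk$soft); z <- fl$sent$z
    if (!is.null(fu)) {
      s <- tdRbindCols(s, tdInstMean(fu$fsk$soft))
      z <- tdRbindCols(z, fu$sent$z)
    }
    mim <- tMine(model$mine, s, z, sample.int(ncol(z$value)))
    total <- tdAdd(total, tdMul(mim, w$lambdaMim))
  }
  comp <- c(comp, list(advLab = advLab$value, advUnlab = advUnlab$value,
                       vae = vae$value, recLab = recL$value,
                       recUnlab = recU$value, mim = mim$value,
                       total = total$value))
  bad <- names(comp)[!vapply(comp, is.finite, logical(1))]
  if (length(bad)) stop("non-finite loss component(s): ", paste(bad, collapse = ", "))
  tdBackward(total)
  adamStep(model$optMain)
  zeroGrads(model$allParams)

  state$step <- state$step + 1L
  state$log[[length(state$log) + 1L]] <- data.frame(step = state$step, as.data.frame(comp))
  invisible(state)
}

# column-bind two (d, B) matrix nodes
tdRbindCols <- function(a, b) {
  na <- ncol(a$value)
  newNode(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

## ---- batch assembly ---------------------------------------------------------

buildPool <- function(study, subjects, withMasks) {
  cfg <- study@config
  pool <- list()
  for (s in subjects) for (fr in c("ED", "ES")) for (k in seq_len(cfg$nSlices)) {
    pool[[length(pool) + 1L]] <- list(
      img = normalizeSlice(study@images[[s]][[fr]][, , k]),
      mask = if (withMasks) study@masks[[s]][[fr]][, , k] else NULL)
  }
  pool
}

assembleBatch <- function(pool, idx, augment, noiseSigma = 0.03) {
  H <- nrow(pool[[1]]$img)
  B <- length(idx)
  x <- array(0, c(H, H, 1L, B))
  withMasks <- !is.null(pool[[idx[1]]]$mask)
  m <- if (withMasks) array(0L, c(H, H, B)) else NULL
  for (i in seq_along(idx)) {
    it <- pool[[idx[i]]]
    if (augment) {
      a <- augmentPair(it$img, it$mask, noiseSigma)
      x[, , 1L, i] <- a$image
      if (withMasks) m[, , i] <- a$mask
    } else {
      x[, , 1L, i] <- it$img
      if (withMasks) m[, , i] <- it$mask
    }
  }
  list(x = x, y1h = if (withMasks) oneHotMasks(m) else NULL)
}

## ---- fitting ----------------------------------------------------------------

#' Fit the semi-supervised model on a phantom study
#'
#' Builds the networks, splits the study at the subject level, then runs the
#' alternating optimization; the labeled stream cycles when shorter than the
#' unlabeled stream. After every `valEvery` epochs the mean validation Dice
#' over RV, myocardium and LV selects the best checkpoint.
#'
#' @param study A [PhantomStudy-class] with at least one labeled subject.
#' @param tc A [trainConfig()].
#' @param runDir Optional directory for the training log CSV, checkpoint and
#'   run manifest.
#' @param verbose Print per-epoch progress.
#' @return A checkpoint (class `cdCheckpoint`): parameter values, running
#'   statistics, optimizer state, config hash, split, and training history.
#' @export
fitModel <- function(study, tc = trainConfig(), runDir = NULL, verbose = FALSE) {
  if (!any(study@subjects$labeled)) stop("study has no labeled subject")
  set.seed(tc$seed)
  split <- splitStudy(study, tc$splitFractions, seed = tc$seed)
  labIds <- intersect(split$train, study@subjects$subject[study@subjects$labeled])
  ulIds <- setdiff(split$train, labIds)
  if (!length(labIds)) stop("no labeled subject in the training partition")
  flags <- variantFlags(tc$variant)
  sz <- study@config$imageSize
  model <- buildModel(tc$net, sz)
  model$variant <- tc$variant
  model$allParams <- c(model$mainParams, model$dI$params, model$dIu$params,
                       model$mine$params)
  model$optMain <- newAdam(model$mainParams, lr = tc$lr, clip = tc$clip)
  model$optDI <- newAdam(model$dI$params, lr = tc$lr, clip = tc$clip)
  model$optDIu <- newAdam(model$dIu$params, lr = tc$lr, clip = tc$clip)
  model$optMine <- newAdam(model$mine$params, lr = 10 * tc$lr, clip = tc$clip)

  labPool <- buildPool(study, labIds, TRUE)
  ulPool <- if (length(ulIds)) buildPool(study, ulIds, FALSE) else list()
  useUl <- length(ulPool) > 0 && flags$advMode != "none"

  state <- new.env(parent = emptyenv())
  state$step <- 0L; state$log <- list()
  history <- list()
  best <- list(dice = -Inf, snap = snapshotModel(model), epoch = 0L)

  nPerEpoch <- if (useUl) length(ulPool) else length(labPool)
  steps <- ceiling(nPerEpoch / tc$batchSize)
  if (!is.null(tc$stepsPerEpoch)) steps <- min(steps, tc$stepsPerEpoch)

  labCursor <- 0L
  for (epoch in seq_len(tc$epochs)) {
    ulOrder <- if (useUl) sample.int(length(ulPool)) else integer(0)
    labOrder <- sample.int(length(labPool))
    for (st in seq_len(steps)) {
      li <- labOrder[((labCursor + seq_len(tc$batchSize) - 1L) %% length(labPool)) + 1L]
      labCursor <- (labCursor + tc$batchSize) %% length(labPool)
      lb <- assembleBatch(labPool, li, tc$augment)
      xu <- NULL
      if (useUl) {
        ui <- ulOrder[((st - 1L) * tc$batchSize) %% length(ulPool) +
                        seq_len(min(tc$batchSize, length(ulPool)))]
        ui <- ((ui - 1L) %% length(ulPool)) + 1L
        xu <- assembleBatch(ulPool, ui, tc$augment)$x
      }
      ramp <- if (tc$warmupEpochs > 0L)
        min(1, state$step / max(1L, tc$warmupEpochs * steps)) else 1
      trainStep(model, state, lb$x, lb$y1h, xu, tc, ramp = ramp)
    }
    valDice <- NA_real_
    if (epoch %% tc$valEvery == 0L || epoch == tc$epochs) {
      nv <- min(length(split$val), tc$valSubjects %||% Inf)
      valDice <- meanDiceOnSubjects(model, study, split$val[seq_len(nv)])
      if (is.finite(valDice) && valDice > best$dice) {
        best <- list(dice = valDice, snap = snapshotModel(model), epoch = epoch)
      }
    }
    recent <- utils::tail(state$log, steps)
    meanTotal <- mean(vapply(recent, function(r) r$total, numeric(1)))
    history[[epoch]] <- data.frame(epoch = epoch, meanTotal = meanTotal,
                                   valDice = valDice)
    if (verbose) message(sprintf("epoch %d: total %.4f, val Dice %.3f",
                                 epoch, meanTotal, valDice))
  }
  if (tc$epochs == 0L) best$snap <- snapshotModel(model)
  ck <- structure(list(
    snapshot = best$snap, netConfig = tc$net, imageSize = sz,
    trainConfig = tc, split = split, bestEpoch = best$epoch,
    bestValDice = best$dice,
    history = if (length(history)) do.call(rbind, history) else data.frame(),
    log = if (length(state$log)) do.call(rbind, state$log) else data.frame(),
    configHash = configHash(tc), packageVersion = as.character(utils::packageVersion("cardisent"))),
    class = "cdCheckpoint")
  if (!is.null(runDir)) {
    dir.create(runDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ck$log, file.path(runDir, "training_log.csv"), row.names = FALSE)
    saveRDS(ck, file.path(runDir, "checkpoint.rds"))
    writeLines(jsonlite::toJSON(list(seed = tc$seed, variant = tc$variant,
                                     configHash = ck$configHash,
                                     packageVersion = ck$packageVersion),
                                auto_unbox = TRUE, pretty = TRUE),
               file.path(runDir, "manifest.json"))
  }
  ck
}

configHash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

## ---- checkpoint snapshot / restore -----------------------------------------

runningLayers <- function(model) {
  c(unname(model$enc$proj),
    model$film$bns,
    list(model$seg$b1, model$seg$b2, model$dI$b2, model$dI$b3,
         model$dIu$b2, model$dIu$b3))
}

snapshotModel <- function(model) {
  list(params = lapply(model$allParams, function(p)
         list(value = p$value, m = p$m, v = p$v)),
       running = lapply(runningLayers(model), function(l)
         list(rmean = if (!is.null(l$rmean)) l$rmean else NULL, rvar = l$rvar)),
       optT = c(model$optMain$t, model$optDI$t, model$optDIu$t, model$optMine$t))
}

restoreSnapshot <- function(model, snap) {
  for (i in seq_along(model$allParams)) {
    p <- model$allParams[[i]]
    p$value <- snap$params[[i]]$value
    p$m <- snap$params[[i]]$m; p$v <- snap$params[[i]]$v
  }
  rl <- runningLayers(model)
  for (i in seq_along(rl)) {
    if (!is.null(snap$running[[i]]$rmean)) rl[[i]]$rmean <- snap$running[[i]]$rmean
    rl[[i]]$rvar <- snap$running[[i]]$rvar
  }
  invisible(model)
}

#' Rebuild a model from a checkpoint
#' @param ck A checkpoint returned by [fitModel()] (or read with `readRDS`).
#' @export
restoreModel <- function(ck) {
  stopifnot(inherits(ck, "cdCheckpoint"))
  model <- buildModel(ck$netConfig, ck$imageSize)
  model$variant <- ck$trainConfig$variant
  model$allParams <- c(model$mainParams, model$dI$params, model$dIu$params,
                       model$mine$params)
  restoreSnapshot(model, ck$snapshot)
  model
}

## ---- prediction -------------------------------------------------------------

argmaxMasks <- function(probs) {
  d <- dim(probs)
  m <- matrix(aperm(probs, c(1, 2, 4, 3)), ncol = d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  aperm(array(lab, c(d[1], d[2], d[4])), c(1, 2, 3))
}

#' Segment and reconstruct a batch of slices
#'
#' Deterministic evaluation-mode inference (`z = mu`): per-pixel argmax
#' masks, reconstructions, the spatial factor and the style code.
#'
#' @param model A model environment (from [fitModel()] + [restoreModel()],
#'   or [buildModel()]).
#' @param images `(H, W, B)` array of normalized slices.
#' @return List with `masks` `(H, W, B)` in 0-3, `recon` `(H, W, B)`,
#'   `factor` (soft/hard arrays) and `code` (mu, logvar, z).
#' @export
predictSlices <- function(model, images) {
  d <- dim(images)
  if (d[1] != model$imageSize) stop("image size differs from the trained size")
  x <- tdConst(asBatchArray(images))
  flags <- variantFlags(model$variant %||% "full")
  f <- genForward(model, x, FALSE, flags, needRecon = TRUE)
  list(masks = argmaxMasks(f$probs$value),
       recon = if (is.null(f$rec)) NULL else array(f$rec$value, d),
       factor = list(soft = f$fsk$soft$value, hard = f$fsk$hard$value),
       code = list(mu = f$sent$mu$value, logvar = f$sent$logvar$value,
                   z = f$sent$z$value))
}

#' Predict full studies subject-by-subject
#'
#' @param model Model environment.
#' @param study A [PhantomStudy-class].
#' @param subjects Subject ids.
#' @return Per subject: list of ED/ES predicted label stacks and
#'   reconstructions.
#' @export
predictStudy <- function(model, study, subjects) {
  cfg <- study@config
  out <- list()
  for (s in subjects) {
    pr <- list(); rc <- list()
    for (fr in c("ED", "ES")) {
      img <- study@images[[s]][[fr]]
      norm <- array(0, dim(img))
      for (k in seq_len(cfg$nSlices)) norm[, , k] <- normalizeSlice(img[, , k])
      p <- predictSlices(model, norm)
      pr[[fr]] <- p$masks; rc[[fr]] <- p$recon
    }
    out[[as.character(s)]] <- list(masks = pr, recon = rc)
  }
  out
}

#' Swap style codes between two image batches
#'
#' Encodes both batches deterministically, then decodes each batch's spatial
#' factor under the other batch's mean style code. The spatial factor (and
#' hence the argmax segmentation) should be invariant to the swap, while the
#' reconstruction adopts the other batch's intensity character.
#'
#' @param model A trained model environment.
#' @param imagesA,imagesB `(H, W, B)` arrays of normalized slices (same B).
#' @param aggregate `"subject"` (default) averages each batch's style codes
#'   into one subject-level code before decoding — per-slice bias-field and
#'   noise realizations are slice-level nuisance, while the scanner signature
#'   is a property of the acquisition; `"slice"` swaps codes slice by slice.
#' @return List with `own` (reconstructions under own style), `swapped`
#'   (A's anatomy under B's style and vice versa), and the argmax `masks`
#'   before and after the swap.
#' @export
styleSwap <- function(model, imagesA, imagesB,
                      aggregate = c("subject", "slice")) {
  aggregate <- match.arg(aggregate)
  encode <- function(img) {
    x <- tdConst(asBatchArray(img))
    fsk <- fwdSkeleton(model$enc, x, FALSE)
    sent <- fwdSentiency(model$senc, x, fsk$hard, FALSE)
    z <- sent$z
    if (aggregate == "subject") {
      zv <- z$value
      z <- tdConst(matrix(rowMeans(zv), nrow(zv), ncol(zv)))
    }
    list(x = x, fsk = fsk, z = z)
  }
  decode <- function(fsk, z) {
    film <- fwdFilm(model$film, fsk$hard, z, FALSE)
    sp <- fwdSpade(model$spade, z, fsk$hard, FALSE)
    list(recon = fwdReconstruct(model$recon, film$features, sp)$value,
         masks = argmaxMasks(fwdSegment(model$seg, film$penult, FALSE)$value))
  }
  eA <- encode(imagesA); eB <- encode(imagesB)
  ownA <- decode(eA$fsk, eA$z); ownB <- decode(eB$fsk, eB$z)
  swapA <- decode(eA$fsk, eB$z); swapB <- decode(eB$fsk, eA$z)
  dA <- dim(imagesA)
  list(own = list(A = array(ownA$recon, dA), B = array(ownB$recon, dA)),
       swapped = list(A = array(swapA$recon, dA), B = array(swapB$recon, dA)),
       masks = list(A = ownA$masks, B = ownB$masks,
                    Aswap = swapA$masks, Bswap = swapB$masks))
}

meanDiceOnSubjects <- function(model, study, subjects) {
  preds <- predictStudy(model, study, subjects)
  vals <- c()
  for (s in subjects) {
    pm <- preds[[as.character(s)]]$masks
    for (fr in c("ED", "ES")) {
      S <- dim(pm[[fr]])[3]
      for (k in seq_len(S)) for (st in STRUCTURES) {
        lab <- LABEL_LEVELS[[st]]
        vals <- c(vals, diceCoef(study@masks[[s]][[fr]][, , k] == lab,
                                 pm[[fr]][, , k] == lab))
      }
    }
  }
  mean(vals)
}
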