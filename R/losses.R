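# Training objectives.
#
# The segmentation objective is a weighted soft background focal (WSBF) loss:
# a focal-modulated, class-weighted cross-entropy plus a background-aware
# focal dice term. Unlabeled predictions are driven by least-squares
# adversarial residuals passed through a Geman-McClure saturating function
# N / (2*beta + N). Reconstruction uses SL2SIM = (1 - SSIM) + alpha * MSE.
# Disentanglement is enforced by a Donsker-Varadhan neural mutual-information
# bound (minimized through the encoders, maximized through the statistic net).

#' Focal segmentation-loss parameters
#'
#' @param alpha0 Background class weight.
#' @param alpha1 Foreground class weight.
#' @param gamma Focusing exponent; the usual operating range is `[1, 3]`
#'   (a warning is emitted outside it).
#' @param epsilon Dice smoothing constant.
#' @param wMap Per-pixel weight map: `"inverse_freq"` weights each pixel by
#'   the normalized inverse batch frequency of its true class (mean 1), or
#'   `"uniform"` for no weighting.
#' @export
focalParams <- function(alpha0 = 0.25, alpha1 = 0.75, gamma = 2,
                        epsilon = 1e-6, wMap = c("inverse_freq", "uniform")) {
  stopifnot(epsilon > 0)
  if (gamma < 1 || gamma > 3) warning("gamma outside the usual range [1, 3]")
  structure(list(alpha0 = alpha0, alpha1 = alpha1, gamma = gamma,
                 epsilon = epsilon, wMap = match.arg(wMap)),
            class = "focalParams")
}

#' Geman-McClure scale parameter
#' @param beta Scale factor in `[0, 1]`; 0.5 by default.
#' @export
gmParams <- function(beta = 0.5) {
  stopifnot(beta >= 0, beta <= 1)
  structure(list(beta = beta), class = "gmParams")
}

#' Loss weights of the total objective
#'
#' Defaults are the weights of the combined objective:
#' `lambdaVae = 0.01`, `lambdaSeg = 10`, `lambdaAdvGm = 10`,
#' `lambdaSl2sim = 0.01`, `lambdaMim = 1`.
#' @export
lossWeights <- function(lambdaVae = 0.01, lambdaSeg = 10, lambdaAdvGm = 10,
                        lambdaSl2sim = 0.01, lambdaMim = 1) {
  w <- list(lambdaVae = lambdaVae, lambdaSeg = lambdaSeg,
            lambdaAdvGm = lambdaAdvGm, lambdaSl2sim = lambdaSl2sim,
            lambdaMim = lambdaMim)
  stopifnot(all(unlist(w) >= 0))
  structure(w, class = "lossWeights")
}

#' Reconstruction-loss parameters
#' @param alphaL2 Weight of the mean-squared-error term.
#' @param ssimWindow Odd Gaussian window width (pixels).
#' @param k1,k2 SSIM stabilizers (dynamic range 1).
#' @export
reconParams <- function(alphaL2 = 1.0, ssimWindow = 7L, k1 = 0.01, k2 = 0.03) {
  stopifnot(alphaL2 >= 0, ssimWindow %% 2L == 1L)
  structure(list(alphaL2 = alphaL2, ssimWindow = as.integer(ssimWindow),
                 k1 = k1, k2 = k2), class = "reconParams")
}

PROB_CLAMP <- 1e-7

ensureNode4 <- function(x) {
  if (isNode(x)) return(x)
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) stop("expected a (H, W, C, B) array")
  tdConst(x)
}

## ---- WSBF: weighted soft focal cross-entropy term ---------------------------

tWeightedSoftFocal <- function(y, yhat, fp) {
  # y: one-hot node/array, yhat: probability node/array, both (H, W, C, B)
  y <- ensureNode4(y); yhat <- ensureNode4(yhat)
  p <- tdClamp(yhat, PROB_CLAMP, 1 - PROB_CLAMP)
  ce <- tdNeg(tdAdd(tdMul(y, tdLog(p)),
                    tdMul(tdSub(1, y), tdLog(tdSub(1, p)))))
  aw <- tdAdd(tdMul(y, fp$alpha1 - fp$alpha0), fp$alpha0)
  focal <- tdPow(tdAbs(tdSub(y, p)), fp$gamma)
  w <- wsbfWeightMap(y$value, fp)
  tdMeanAll(tdMul(tdMul(tdMul(aw, focal), tdConst(w)), ce))
}

wsbfWeightMap <- function(yv, fp) {
  d <- dim(yv)
  if (fp$wMap == "uniform") return(array(1, dim = d))
  # inverse batch frequency of each pixel's true class, normalized to mean 1
  HW <- d[1] * d[2]
  freq <- rowSums(matrix(colSums(matrix(yv, HW, d[3] * d[4])), d[3], d[4]))
  freq <- freq / sum(freq)
  w <- 1 / (freq + 1e-8)
  w <- w / mean(w[freq > 0])
  # per-pixel map: weight of the pixel's true class, replicated over channels
  perPixelClass <- array(rep(rep(w, each = HW), times = d[4]), dim = d) * yv
  m3 <- array(perPixelClass, c(HW, d[3], d[4]))
  ap <- aperm(m3, c(1, 3, 2)); dim(ap) <- c(HW * d[4], d[3])
  pix <- rowSums(ap)                      # (hw, b)
  aperm(array(array(pix, c(HW, d[4])), c(HW, d[4], d[3])), c(1, 3, 2)) |>
    array(dim = d)
}

#' Weighted soft focal loss (cross-entropy term of WSBF)
#'
#' Mean over pixels and classes of
#' `(alpha0 + y * (alpha1 - alpha0)) * |y - yhat|^gamma * w * CE(y, yhat)`.
#'
#' @param yOnehot One-hot ground truth, `(H, W, L, B)`.
#' @param yProb Predicted class probabilities, same shape (clamped to
#'   `[1e-7, 1 - 1e-7]`).
#' @param params A [focalParams()].
#' @return Scalar loss.
#' @export
weightedSoftFocal <- function(yOnehot, yProb, params = focalParams()) {
  tWeightedSoftFocal(yOnehot, yProb, params)$value
}

## ---- background focal dice --------------------------------------------------

tBackgroundFocalDice <- function(y, yhat, gamma = 2, epsilon = 1e-6) {
  y <- ensureNode4(y); yhat <- ensureNode4(yhat)
  L <- dim(y$value)[3]
  total <- NULL
  for (c in seq_len(L)) {
    yc <- tdSliceC(y, c); pc <- tdSliceC(yhat, c)
    d1 <- softDice(yc, pc, epsilon)
    d2 <- softDice(tdSub(1, yc), tdSub(1, pc), epsilon)
    term <- tdPowGuard(tdClamp(tdSub(tdSub(2, d1), d2), 0, 2), 1 / gamma)
    total <- if (is.null(total)) term else tdAdd(total, term)
  }
  total
}

softDice <- function(a, b, epsilon) {
  num <- tdAdd(tdMul(tdSumAll(tdMul(a, b)), 2), epsilon)
  den <- tdAdd(tdAdd(tdSumAll(a), tdSumAll(b)), epsilon)
  tdDiv(num, den)
}

#' Background focal dice loss (BFD term of WSBF)
#'
#' Per class `c`: `[2 - softDice(y_c, p_c) - softDice(1 - y_c, 1 - p_c)]^(1/gamma)`,
#' summed over classes. `softDice(a, b) = (2*sum(ab) + eps) / (sum(a) + sum(b) + eps)`.
#'
#' @inheritParams weightedSoftFocal
#' @param gamma Focusing exponent.
#' @param epsilon Smoothing constant guarding empty classes.
#' @export
backgroundFocalDice <- function(yOnehot, yProb, gamma = 2, epsilon = 1e-6) {
  tBackgroundFocalDice(yOnehot, yProb, gamma, epsilon)$value
}

## ---- adversarial Geman-McClure ---------------------------------------------

tAdvGM <- function(residual, params = gmParams()) {
  if (isNode(residual)) tdDiv(residual, tdAdd(residual, 2 * params$beta))
  else residual / (2 * params$beta + residual)
}

#' Geman-McClure saturation of a least-squares adversarial residual
#'
#' Returns `N / (2*beta + N)` for a non-negative least-squares GAN residual
#' `N` (for a discriminator step, `N = E[D(fake)^2] + E[(D(real) - 1)^2]`;
#' for a generator step, `N = E[(D(fake) - 1)^2]`).
#'
#' @param residualSum Non-negative scalar residual.
#' @param params A [gmParams()].
#' @export
advGM <- function(residualSum, params = gmParams()) {
  stopifnot(residualSum >= 0)
  tAdvGM(residualSum, params)
}

## ---- Gaussian KL ------------------------------------------------------------

tKlGaussian <- function(mu, logvar) {
  # mean over batch of 1/2 * sum_d (mu^2 + exp(logvar) - 1 - logvar)
  B <- ncol(mu$value)
  per <- tdSub(tdSub(tdAdd(tdSquare(mu), tdExp(logvar)), 1), logvar)
  tdMul(tdSumAll(per), 0.5 / B)
}

#' KL divergence of a diagonal Gaussian posterior from the standard normal
#'
#' @param mu,logvar `(d, B)` matrices (or vectors for a single sample).
#' @return Mean over the batch of `0.5 * sum_d(mu^2 + exp(logvar) - 1 - logvar)`.
#' @export
klGaussian <- function(mu, logvar) {
  if (!is.matrix(mu)) { mu <- matrix(mu); logvar <- matrix(logvar) }
  tKlGaussian(tdConst(mu), tdConst(logvar))$value
}

## ---- SL2SIM -----------------------------------------------------------------

gaussKernel1 <- function(w, sigma = 1.5) {
  half <- (w - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  array(k, c(w, w, 1L, 1L))
}

tSsim <- function(x, y, rp) {
  w <- tdConst(gaussKernel1(rp$ssimWindow))
  b0 <- tdConst(0)
  blur <- function(a) tdConv(a, w, b0, 1L, 0L)   # valid windows
  c1 <- rp$k1^2; c2 <- rp$k2^2
  mx <- blur(x); my <- blur(y)
  sxx <- tdSub(blur(tdMul(x, x)), tdMul(mx, mx))
  syy <- tdSub(blur(tdMul(y, y)), tdMul(my, my))
  sxy <- tdSub(blur(tdMul(x, y)), tdMul(mx, my))
  num <- tdMul(tdAdd(tdMul(tdMul(mx, my), 2), c1), tdAdd(tdMul(sxy, 2), c2))
  den <- tdMul(tdAdd(tdAdd(tdMul(mx, mx), tdMul(my, my)), c1),
               tdAdd(tdAdd(sxx, syy), c2))
  tdMeanAll(tdDiv(num, den))
}

tSl2sim <- function(x, xhat, rp) {
  x <- ensureNode4(x); xhat <- ensureNode4(xhat)
  l2 <- tdMeanAll(tdSquare(tdSub(x, xhat)))
  tdAdd(tdSub(1, tSsim(x, xhat, rp)), tdMul(l2, rp$alphaL2))
}

#' Structural-similarity plus squared-error reconstruction loss
#'
#' `1 - SSIM(x, xhat) + alphaL2 * mean((x - xhat)^2)`, with SSIM computed over
#' Gaussian-weighted local windows (dynamic range 1).
#'
#' @param x,xhat Images in `[0, 1]`: `(H, W)` matrices or `(H, W, 1, B)` arrays.
#' @param params A [reconParams()].
#' @export
sl2sim <- function(x, xhat, params = reconParams()) {
  if (is.matrix(x)) { x <- array(x, c(dim(x), 1L, 1L)); xhat <- array(xhat, dim(x)) }
  tSl2sim(x, xhat, params)$value
}

## ---- MINE -------------------------------------------------------------------

tMine <- function(statNet, s, z, perm) {
  # Donsker-Varadhan bound: mean(T(joint)) - log(mean(exp(T(marginal))))
  Tj <- fwdMineStat(statNet, s, z)
  zPerm <- if (isNode(z)) {
    d <- dim(z$value)
    newNode(z$value[, perm, drop = FALSE], list(z), function(g) {
      gx <- matrix(0, d[1], d[2]); gx[, perm] <- g; list(gx)
    })
  } else tdConst(z[, perm, drop = FALSE])
  Tm <- fwdMineStat(statNet, s, zPerm)
  em <- tdClamp(tdMeanAll(tdExp(tdClamp(Tm, -30, 30))), 1e-8, Inf)
  tdSub(tdMeanAll(Tj), tdLog(em))
}

#' Generic statistic network for neural mutual-information estimation
#'
#' @param dx,dy Dimensions of the two variables.
#' @param hidden Hidden width of the 3-layer perceptron.
#' @export
newStatNet <- function(dx, dy, hidden = 64L) {
  e <- new.env(parent = emptyenv())
  e$d1 <- newDense(dx + dy, hidden)
  e$d2 <- newDense(hidden, hidden)
  e$d3 <- newDense(hidden, 1L)
  e$params <- layerParams(e$d1, e$d2, e$d3)
  e$cfg <- list()
  e
}

#' Neural mutual-information estimate (Donsker-Varadhan bound)
#'
#' `mean(T(joint)) - log(mean(exp(T(marginal))))`, marginal pairs formed by an
#' in-batch permutation of the second component; the log argument is clamped
#' below at `1e-8`.
#'
#' @param statNet A statistic network from [newStatNet()].
#' @param x,y `(dx, N)` and `(dy, N)` matrices of aligned joint samples.
#' @param perm Permutation of `1:N` forming the marginal pairs (defaults to a
#'   random derangement-style shuffle).
#' @export
mineEstimate <- function(statNet, x, y, perm = NULL) {
  N <- ncol(x)
  if (N < 2L) stop("need at least 2 samples")
  if (is.null(perm)) perm <- sample.int(N)
  tMine(statNet, tdConst(x), tdConst(y), perm)$value
}

#' Train a statistic network and estimate mutual information
#'
#' Maximizes the Donsker-Varadhan bound over the statistic network by
#' stochastic gradient ascent on minibatches, then evaluates the bound on the
#' full sample.
#'
#' @inheritParams mineEstimate
#' @param steps Optimizer steps.
#' @param batch Minibatch size.
#' @param lr Adam learning rate.
#' @return List with `mi` (nats) and the trained `statNet`.
#' @export
estimateMI <- function(x, y, steps = 400L, batch = 256L, lr = 5e-3,
                       hidden = 64L) {
  N <- ncol(x)
  net <- newStatNet(nrow(x), nrow(y), hidden)
  opt <- newAdam(net$params, lr = lr, clip = 5)
  for (s in seq_len(steps)) {
    idx <- sample.int(N, min(batch, N))
    mb <- tMine(net, tdConst(x[, idx, drop = FALSE]),
                tdConst(y[, idx, drop = FALSE]), sample.int(length(idx)))
    tdBackward(mb, seed = -1)              # ascend the bound
    adamStep(opt)
  }
  mi <- mineEstimate(net, x, y, sample.int(N))
  list(mi = mi, statNet = net)
}

## ---- total objective --------------------------------------------------------

#' Weighted total objective
#'
#' `lambdaSeg * seg + lambdaAdvGm * (advLabeled + advUnlabeled) + lambdaVae * vae +
#'  lambdaSl2sim * (reconLabeled + reconUnlabeled) + lambdaMim * mim`
#'
#' @param components Named list with elements `seg`, `advLabeled`,
#'   `advUnlabeled`, `vae`, `reconLabeled`, `reconUnlabeled`, `mim` (scalars;
#'   unlabeled-only terms may be zero for a fully labeled batch).
#' @param weights A [lossWeights()].
#' @export
totalLoss <- function(components, weights = lossWeights()) {
  need <- c("seg", "advLabeled", "advUnlabeled", "vae",
            "reconLabeled", "reconUnlabeled", "mim")
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("missing components: ", paste(miss, collapse = ", "))
  if (components$seg < 0) stop("segmentation loss must be non-negative")
  if (components$vae < 0) stop("KL loss must be non-negative")
  with(components,
       weights$lambdaSeg * seg +
       weights$lambdaAdvGm * (advLabeled + advUnlabeled) +
       weights$lambdaVae * vae +
       weights$lambdaSl2sim * (reconLabeled + reconUnlabeled) +
       weights$lambdaMim * mim)
}
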