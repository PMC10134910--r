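# Independent brute-force oracles used to pin down the loss and metric
# implementations. These deliberately use naive elementwise loops / direct
# set arithmetic so they share no code with the package internals.

oracleWSFL <- function(y, p, alpha0, alpha1, gamma, w = NULL) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  if (is.null(w)) w <- array(1, dim = dim(y))
  total <- 0
  for (i in seq_along(y)) {
    ce <- -y[i] * log(p[i]) - (1 - y[i]) * log(1 - p[i])
    aw <- alpha0 + y[i] * (alpha1 - alpha0)
    total <- total + aw * abs(y[i] - p[i])^gamma * w[i] * ce
  }
  total / length(y)
}

oracleBFD <- function(y, p, gamma, eps) {
  L <- dim(y)[3]
  total <- 0
  for (c in seq_len(L)) {
    yc <- as.vector(y[, , c, ]); pc <- as.vector(p[, , c, ])
    d1 <- (2 * sum(yc * pc) + eps) / (sum(yc) + sum(pc) + eps)
    d2 <- (2 * sum((1 - yc) * (1 - pc)) + eps) /
          (sum(1 - yc) + sum(1 - pc) + eps)
    total <- total + max(2 - d1 - d2, 0)^(1 / gamma)
  }
  total
}

# windowed SSIM by direct sliding-window evaluation (Gaussian weights)
oracleSSIM <- function(x, y, win = 7L, k1 = 0.01, k2 = 0.03, sigma = 1.5) {
  half <- (win - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- outer(g, g); kern <- kern / sum(kern)
  H <- nrow(x); W <- ncol(x)
  c1 <- k1^2; c2 <- k2^2
  vals <- c()
  for (i in 1:(H - win + 1)) for (j in 1:(W - win + 1)) {
    xp <- x[i:(i + win - 1), j:(j + win - 1)]
    yp <- y[i:(i + win - 1), j:(j + win - 1)]
    mx <- sum(kern * xp); my <- sum(kern * yp)
    sxx <- sum(kern * xp * xp) - mx^2
    syy <- sum(kern * yp * yp) - my^2
    sxy <- sum(kern * xp * yp) - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * sxy + c2)) /
                     ((mx^2 + my^2 + c1) * (sxx + syy + c2)))
  }
  mean(vals)
}

oracleHausdorff <- function(A, B, spacing = 1) {
  bound <- function(m) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(FALSE, H, W)
    for (i in 1:H) for (j in 1:W) {
      if (!m[i, j]) next
      nb <- c(if (i > 1) m[i - 1, j] else FALSE, if (i < H) m[i + 1, j] else FALSE,
              if (j > 1) m[i, j - 1] else FALSE, if (j < W) m[i, j + 1] else FALSE)
      if (any(!nb)) out[i, j] <- TRUE
    }
    out
  }
  pa <- which(bound(A), arr.ind = TRUE); pb <- which(bound(B), arr.ind = TRUE)
  dmat <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min))) * spacing
}

# rasterized-disk pixel count by pixel-center-in-circle enumeration
oracleDiskCount <- function(cx, cy, r, n) {
  cnt <- 0L
  for (i in 1:n) for (j in 1:n)
    if ((i - cx)^2 + (j - cy)^2 <= r^2) cnt <- cnt + 1L
  cnt
}

randomOnehot <- function(H, W, L = 4L, B = 1L) {
  m <- array(sample(0:(L - 1L), H * W * B, replace = TRUE), c(H, W, B))
  oneHotMasks(m, L)
}

randomProbs <- function(H, W, L = 4L, B = 1L) {
  a <- array(stats::rexp(H * W * L * B), c(H, W, L, B))
  for (b in seq_len(B)) {
    s <- apply(a[, , , b, drop = FALSE], c(1, 2), sum)
    for (c in seq_len(L)) a[, , c, b] <- a[, , c, b] / s
  }
  a
}

tinyStudy <- function(nSubjects = 6L, labelFraction = 0.34, seed = 11L,
                      nSlices = 3L) {
  generateStudy(phantomConfig(imageSize = 64L, nSubjects = nSubjects,
                              nSlices = nSlices, labelFraction = labelFraction,
                              seed = seed))
}
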