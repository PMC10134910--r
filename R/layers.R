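# Trainable layers built on the autodiff core. A layer is an environment
# holding its parameter nodes (and any running statistics); containers collect
# parameters with layerParams(). He-normal initialization throughout.

heInit <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

newConv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                    init = c("he", "zero")) {
  init <- match.arg(init)
  l <- new.env(parent = emptyenv())
  l$w <- tdParam(if (init == "zero") array(0, c(k, k, cin, cout))
                 else heInit(k, k, cin, cout))
  l$b <- tdParam(rep(0, cout))
  l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$params <- list(l$w, l$b)
  l$fwd <- function(x) tdConv(x, l$w, l$b, l$stride, l$pad)
  class(l) <- "cdLayer"
  l
}

newDense <- function(din, dout, init = c("he", "zero")) {
  init <- match.arg(init)
  l <- new.env(parent = emptyenv())
  l$w <- tdParam(if (init == "zero") matrix(0, dout, din)
                 else matrix(stats::rnorm(dout * din, sd = sqrt(2 / din)), dout, din))
  l$b <- tdParam(rep(0, dout))
  l$params <- list(l$w, l$b)
  l$fwd <- function(x) tdAddBiasCol(tdMatmul(l$w, x), l$b)
  class(l) <- "cdLayer"
  l
}

# batch normalization over (H, W, B) per channel, with running statistics
newBatchNorm <- function(c, momentum = 0.1, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$gamma <- tdParam(rep(1, c)); l$beta <- tdParam(rep(0, c))
  l$rmean <- rep(0, c); l$rvar <- rep(1, c)
  l$momentum <- momentum; l$eps <- eps
  l$params <- list(l$gamma, l$beta)
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x$value)
    if (train) {
      mu <- tdChannelMean(x)
      xc <- tdSub(x, tdBcChannel(mu, d))
      v <- tdChannelMean(tdSquare(xc))
      l$rmean <- (1 - l$momentum) * l$rmean + l$momentum * mu$value
      l$rvar <- (1 - l$momentum) * l$rvar + l$momentum * v$value
      xhat <- tdDiv(xc, tdBcChannel(tdSqrt(tdAdd(v, l$eps)), d))
    } else {
      xc <- tdSub(x, tdBcChannel(tdConst(l$rmean), d))
      xhat <- tdDiv(xc, tdBcChannel(tdConst(sqrt(l$rvar + l$eps)), d))
    }
    tdAdd(tdMul(xhat, tdBcChannel(l$gamma, d)), tdBcChannel(l$beta, d))
  }
  class(l) <- "cdLayer"
  l
}

# parameter-free instance normalization (per sample, per channel)
tInstanceNorm <- function(x, eps = 1e-5) {
  d <- dim(x$value)
  mu <- tdInstMean(x)
  xc <- tdSub(x, tdBcInst(mu, d))
  v <- tdInstMean(tdSquare(xc))
  tdDiv(xc, tdBcInst(tdSqrt(tdAdd(v, eps)), d))
}

# EvoNorm-style normalized projection: divide by the square root of the sum
# of batch-level and instance-level variance (no explicit activation), apply a
# per-channel affine, a 1x1 convolution, then multiplicative Gaussian dropout.
# Running batch variance is used at evaluation time.
newEvonormProjection <- function(cin, cout = cin, dropout = 0.1,
                                 momentum = 0.1, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$gamma <- tdParam(rep(1, cin)); l$beta <- tdParam(rep(0, cin))
  l$proj <- newConv(cin, cout, k = 1L, pad = 0L)
  l$rvar <- rep(1, cin)
  l$momentum <- momentum; l$eps <- eps; l$dropout <- dropout
  l$params <- c(list(l$gamma, l$beta), l$proj$params)
  l$fwd <- function(x, train = TRUE) {
    d <- dim(x$value)
    if (train) {
      mu <- tdChannelMean(x)
      vb <- tdChannelMean(tdSquare(tdSub(x, tdBcChannel(mu, d))))
      l$rvar <- (1 - l$momentum) * l$rvar + l$momentum * vb$value
      vbB <- tdBcChannel(vb, d)
    } else {
      vbB <- tdBcChannel(tdConst(l$rvar), d)
    }
    mi <- tdInstMean(x)
    vi <- tdInstMean(tdSquare(tdSub(x, tdBcInst(mi, d))))
    den <- tdSqrt(tdAdd(tdAdd(vbB, tdBcInst(vi, d)), l$eps))
    h <- tdDiv(x, den)
    h <- tdAdd(tdMul(h, tdBcChannel(l$gamma, d)), tdBcChannel(l$beta, d))
    h <- l$proj$fwd(h)
    tdGaussDropout(h, l$dropout, train)
  }
  class(l) <- "cdLayer"
  l
}

layerParams <- function(...) layerParams0(list(...))

layerParams0 <- function(ls) {
  out <- list()
  for (l in ls) {
    if (is.null(l)) next
    if (inherits(l, "cdLayer")) out <- c(out, l$params)
    else if (is.environment(l) && !is.null(l$params)) out <- c(out, l$params)
    else out <- c(out, layerParams0(l))
  }
  out
}

## ---- optimizer --------------------------------------------------------------

# Adam with global-norm gradient clipping; one optimizer per parameter group so
# adversarial players never share an update step.
newAdam <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                    eps = 1e-8, clip = 5.0) {
  o <- new.env(parent = emptyenv())
  o$params <- params; o$lr <- lr; o$beta1 <- beta1; o$beta2 <- beta2
  o$eps <- eps; o$clip <- clip; o$t <- 0L
  class(o) <- "cdAdam"
  o
}

adamStep <- function(o) {
  gs <- lapply(o$params, function(p) p$grad)
  sq <- sum(vapply(gs, function(g) if (is.null(g)) 0 else sum(g^2), numeric(1)))
  gn <- sqrt(sq)
  scale <- if (is.finite(o$clip) && gn > o$clip) o$clip / gn else 1
  o$t <- o$t + 1L
  bc1 <- 1 - o$beta1^o$t; bc2 <- 1 - o$beta2^o$t
  for (i in seq_along(o$params)) {
    p <- o$params[[i]]
    g <- gs[[i]]
    if (is.null(g)) next
    g <- g * scale
    p$m <- o$beta1 * p$m + (1 - o$beta1) * g
    p$v <- o$beta2 * p$v + (1 - o$beta2) * g^2
    p$value <- p$value - o$lr * (p$m / bc1) / (sqrt(p$v / bc2) + o$eps)
    p$grad <- NULL
  }
  invisible(gn)
}
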