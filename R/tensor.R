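# Minimal reverse-mode automatic differentiation over R arrays.
#
# A node is an environment carrying a value, an accumulated gradient, its
# parent nodes and a backward closure mapping the node's gradient to the
# parents' gradients. Node ids increase monotonically at creation time, so
# sorting by id yields a valid topological order of any dynamic graph.
# Image tensors use the column-major layout (H, W, C, B); dense activations
# are (d, B) matrices; losses are length-1 scalars.

.tape <- new.env(parent = emptyenv())
.tape$counter <- 0L

newNode <- function(value, parents = list(), backward = NULL, requires = FALSE) {
  force(value); force(parents)   # parents must take their ids before this node
  n <- new.env(parent = emptyenv())
  .tape$counter <- .tape$counter + 1L
  n$id <- .tape$counter
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$requires <- requires || any(vapply(parents, function(p) p$requires, logical(1)))
  class(n) <- "cdNode"
  n
}

isNode <- function(x) inherits(x, "cdNode")

tdConst <- function(value) newNode(value)

#' @noRd
tdParam <- function(value) {
  p <- newNode(value, requires = TRUE)
  p$m <- if (is.null(dim(value))) numeric(length(value)) else array(0, dim(value))
  p$v <- p$m
  p
}

tdValue <- function(x) if (isNode(x)) x$value else x

`%||%` <- function(a, b) if (is.null(a)) b else a

accumGrad <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar root. Gradients accumulate into every node with
# requires = TRUE reachable from the root; call zeroGrads() on parameters
# between optimizer steps.
tdBackward <- function(root, seed = 1) {
  stopifnot(isNode(root))
  # iterative DFS collecting the sub-graph, then sweep in decreasing id order
  nodes <- new.env(parent = emptyenv())
  stack <- list(root)
  order <- list()
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- TRUE
    order[[length(order) + 1L]] <- n
    for (p in n$parents) if (p$requires) stack[[length(stack) + 1L]] <- p
  }
  ids <- vapply(order, function(n) n$id, integer(1))
  order <- order[order(ids, decreasing = TRUE)]
  root$grad <- array(seed, dim = dim(root$value) %||% 1L)
  for (n in order) {
    if (is.null(n$backward) || is.null(n$grad)) next
    gs <- n$backward(n$grad)
    for (i in seq_along(n$parents)) {
      if (!is.null(gs[[i]])) accumGrad(n$parents[[i]], gs[[i]])
    }
  }
  invisible(root)
}

zeroGrads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

wrapConst <- function(x) if (isNode(x)) x else tdConst(x)

sameOrScalar <- function(a, b) {
  la <- length(a); lb <- length(b)
  la == lb || la == 1L || lb == 1L
}

reduceLike <- function(g, v) {
  # reduce a gradient to the shape of v (handles the scalar-broadcast case)
  if (length(v) == 1L) sum(g) else g
}

## ---- elementwise arithmetic -------------------------------------------------
# plain-numeric operands take a fast path that avoids creating constant nodes

tdAdd <- function(a, b) {
  if (!isNode(b)) {
    if (!isNode(a)) return(tdConst(a + b))
    return(newNode(a$value + b, list(a), function(g) list(g)))
  }
  if (!isNode(a)) return(newNode(a + b$value, list(b), function(g) list(g)))
  stopifnot(sameOrScalar(a$value, b$value))
  newNode(a$value + b$value, list(a, b), function(g) {
    list(reduceLike(g, a$value), reduceLike(g, b$value))
  })
}

tdSub <- function(a, b) {
  if (!isNode(b)) {
    if (!isNode(a)) return(tdConst(a - b))
    return(newNode(a$value - b, list(a), function(g) list(g)))
  }
  if (!isNode(a)) return(newNode(a - b$value, list(b), function(g) list(-g)))
  stopifnot(sameOrScalar(a$value, b$value))
  newNode(a$value - b$value, list(a, b), function(g) {
    list(reduceLike(g, a$value), reduceLike(-g, b$value))
  })
}

tdMul <- function(a, b) {
  if (!isNode(b)) {
    if (!isNode(a)) return(tdConst(a * b))
    return(newNode(a$value * b, list(a), function(g) list(g * b)))
  }
  if (!isNode(a)) return(newNode(a * b$value, list(b), function(g) list(g * a)))
  stopifnot(sameOrScalar(a$value, b$value))
  newNode(a$value * b$value, list(a, b), function(g) {
    list(reduceLike(g * b$value, a$value), reduceLike(g * a$value, b$value))
  })
}

tdDiv <- function(a, b) {
  if (!isNode(b)) {
    if (!isNode(a)) return(tdConst(a / b))
    return(newNode(a$value / b, list(a), function(g) list(g / b)))
  }
  if (!isNode(a)) {
    return(newNode(a / b$value, list(b),
                   function(g) list(reduceLike(-g * a / (b$value^2), b$value))))
  }
  stopifnot(sameOrScalar(a$value, b$value))
  newNode(a$value / b$value, list(a, b), function(g) {
    list(reduceLike(g / b$value, a$value),
         reduceLike(-g * a$value / (b$value^2), b$value))
  })
}

tdNeg <- function(a) tdMul(a, -1)

tdExp <- function(a) {
  v <- exp(a$value)
  newNode(v, list(a), function(g) list(g * v))
}

tdLog <- function(a) newNode(log(a$value), list(a), function(g) list(g / a$value))

tdSqrt <- function(a) {
  v <- sqrt(a$value)
  newNode(v, list(a), function(g) list(g / (2 * v)))
}

tdSquare <- function(a) newNode(a$value^2, list(a), function(g) list(2 * g * a$value))

tdAbs <- function(a) newNode(abs(a$value), list(a), function(g) list(g * sign(a$value)))

tdPow <- function(a, p) {
  v <- a$value^p
  newNode(v, list(a), function(g) {
    if (p == 0) return(list(g * 0))
    list(g * p * a$value^(p - 1))
  })
}

# power with an exact forward value but a gradient guard at the base's origin
# (needed for exponents < 1 where the derivative diverges)
tdPowGuard <- function(a, p, floor = 1e-6) {
  v <- a$value^p
  newNode(v, list(a), function(g) list(g * p * pmax(a$value, floor)^(p - 1)))
}

tdClamp <- function(a, lo, hi) {
  v <- pmin(pmax(a$value, lo), hi)
  inside <- (a$value > lo & a$value < hi) * 1
  newNode(v, list(a), function(g) list(g * inside))
}

## ---- activations ------------------------------------------------------------

tdSigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  newNode(v, list(a), function(g) list(g * v * (1 - v)))
}

tdTanh <- function(a) {
  v <- tanh(a$value)
  newNode(v, list(a), function(g) list(g * (1 - v^2)))
}

tdLeakyRelu <- function(a, slope = 0.2) {
  newNode(leakyFwdC(a$value, slope), list(a),
          function(g) list(leakyBwdC(g, a$value, slope)))
}

# straight-through binarization: hard {0,1} forward, identity gradient
tdSTRound <- function(a, threshold = 0.5) {
  v <- (a$value > threshold) * 1
  dim(v) <- dim(a$value)
  newNode(v, list(a), function(g) list(g))
}

tdGaussDropout <- function(a, rate, train = TRUE) {
  if (!train || rate <= 0) return(a)
  sdn <- sqrt(rate / (1 - rate))
  mask <- 1 + array(stats::rnorm(length(a$value), sd = sdn), dim = dim(a$value))
  newNode(a$value * mask, list(a), function(g) list(g * mask))
}

## ---- convolution and spatial ops -------------------------------------------

tdConv <- function(x, w, b, stride = 1L, pad = 1L) {
  v <- convForwardC(x$value, w$value, b$value, as.integer(stride), as.integer(pad))
  newNode(v, list(x, w, b), function(g) {
    r <- convBackwardC(x$value, w$value, g, as.integer(stride), as.integer(pad),
                       x$requires)
    list(r$gx, r$gw, r$gb)
  })
}

tdAvgPool2 <- function(x) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]
  oi <- seq(1L, H, 2L); ei <- oi + 1L
  oj <- seq(1L, W, 2L); ej <- oj + 1L
  v <- (x$value[oi, oj, , , drop = FALSE] + x$value[ei, oj, , , drop = FALSE] +
        x$value[oi, ej, , , drop = FALSE] + x$value[ei, ej, , , drop = FALSE]) / 4
  newNode(v, list(x), function(g) {
    gx <- array(0, dim = d)
    g4 <- g / 4
    gx[oi, oj, , ] <- g4; gx[ei, oj, , ] <- g4
    gx[oi, ej, , ] <- g4; gx[ei, ej, , ] <- g4
    list(gx)
  })
}

tdUpsample2 <- function(x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2L); rj <- rep(seq_len(d[2]), each = 2L)
  v <- x$value[ri, rj, , , drop = FALSE]
  oi <- seq(1L, 2L * d[1], 2L); ei <- oi + 1L
  oj <- seq(1L, 2L * d[2], 2L); ej <- oj + 1L
  newNode(v, list(x), function(g) {
    list(g[oi, oj, , , drop = FALSE] + g[ei, oj, , , drop = FALSE] +
         g[oi, ej, , , drop = FALSE] + g[ei, ej, , , drop = FALSE])
  })
}

# nearest-neighbor integer-factor downsample (keeps binary maps binary)
tdDownNearest <- function(x, factor) {
  if (factor == 1L) return(x)
  d <- dim(x$value)
  ii <- seq(1L, d[1], factor); jj <- seq(1L, d[2], factor)
  v <- x$value[ii, jj, , , drop = FALSE]
  newNode(v, list(x), function(g) {
    gx <- array(0, dim = d)
    gx[ii, jj, , ] <- g
    list(gx)
  })
}

tdConcatC <- function(xs) {
  cs <- vapply(xs, function(x) dim(x$value)[3], integer(1))
  v <- concatChannelsC(lapply(xs, function(x) x$value))
  newNode(v, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- sliceChannelsC(g, at + 1L, cs[i])
      at <- at + cs[i]
    }
    out
  })
}

# contiguous channel ranges only
tdSliceC <- function(x, idx) {
  stopifnot(all(diff(idx) == 1L) || length(idx) == 1L)
  C <- dim(x$value)[3]
  v <- sliceChannelsC(x$value, idx[1], length(idx))
  newNode(v, list(x), function(g) {
    list(unsliceChannelsC(g, idx[1], C))
  })
}

## ---- reductions and broadcasts ---------------------------------------------

tdMeanAll <- function(x) {
  n <- length(x$value)
  newNode(mean(x$value), list(x), function(g) {
    gx <- fillValueC(as.numeric(g) / n, n)
    dim(gx) <- dim(x$value)
    list(gx)
  })
}

tdSumAll <- function(x) {
  newNode(sum(x$value), list(x), function(g) {
    gx <- fillValueC(as.numeric(g), length(x$value))
    dim(gx) <- dim(x$value)
    list(gx)
  })
}

# per-channel mean over (H, W, B) -> length-C vector
tdChannelMean <- function(x) {
  d <- dim(x$value)
  HW <- d[1] * d[2]
  v <- channelSumC(x$value, HW, d[3], d[4]) / (HW * d[4])
  newNode(v, list(x), function(g) {
    gx <- bcChannelC(g / (HW * d[4]), HW, d[3], d[4])
    dim(gx) <- d
    list(gx)
  })
}

tdBcChannel <- function(v, dims) {
  HW <- dims[1] * dims[2]
  val <- bcChannelC(v$value, HW, dims[3], dims[4])
  dim(val) <- dims
  newNode(val, list(v), function(g) {
    list(channelSumC(g, HW, dims[3], dims[4]))
  })
}

# per-sample-per-channel mean over (H, W) -> (C, B) matrix
tdInstMean <- function(x) {
  d <- dim(x$value)
  HW <- d[1] * d[2]
  v <- matrix(instSumC(x$value, HW, d[3], d[4]) / HW, d[3], d[4])
  newNode(v, list(x), function(g) {
    gx <- bcInstC(g / HW, HW)
    dim(gx) <- d
    list(gx)
  })
}

tdBcInst <- function(m, dims) {
  HW <- dims[1] * dims[2]
  val <- bcInstC(m$value, HW)
  dim(val) <- dims
  newNode(val, list(m), function(g) {
    list(matrix(instSumC(g, HW, dims[3], dims[4]), dims[3], dims[4]))
  })
}

tdFlatten <- function(x) {
  d <- dim(x$value)
  v <- matrix(x$value, d[1] * d[2] * d[3], d[4])
  newNode(v, list(x), function(g) list(array(g, dim = d)))
}

# lift a (C, B) matrix to a constant-spatial (H, W, C, B) map
tdBcSpatial <- function(m, H, W) {
  d <- dim(m$value)
  val <- array(rep(as.vector(m$value), each = H * W), dim = c(H, W, d[1], d[2]))
  newNode(val, list(m), function(g) {
    list(matrix(colSums(matrix(g, H * W, d[1] * d[2])), d[1], d[2]))
  })
}

## ---- dense ops --------------------------------------------------------------

tdMatmul <- function(W, x) {
  newNode(W$value %*% x$value, list(W, x), function(g) {
    list(g %*% t(x$value), t(W$value) %*% g)
  })
}

tdAddBiasCol <- function(x, b) {
  # x: (d, B), b: length-d vector added to every column
  newNode(x$value + b$value, list(x, b), function(g) {
    list(g, rowSums(g))
  })
}

tdRowSlice <- function(x, idx) {
  d <- dim(x$value)
  newNode(x$value[idx, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    gx[idx, ] <- g
    list(gx)
  })
}

tdRbind <- function(a, b) {
  na <- nrow(a$value)
  newNode(rbind(a$value, b$value), list(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

## ---- softmax over channels --------------------------------------------------

tdSoftmaxC <- function(x) {
  d <- dim(x$value)
  HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  a3 <- array(x$value, c(HW, C, B))
  bcCB <- function(s) aperm(array(s, c(HW, B, C)), c(1, 3, 2))  # (hw, b) -> (hw, c, b)
  mx <- a3[, 1, , drop = FALSE][, 1, ]
  if (C > 1) for (cc in 2:C) mx <- pmax(mx, a3[, cc, , drop = FALSE][, 1, ])
  e <- exp(a3 - bcCB(mx))
  ap <- aperm(e, c(1, 3, 2)); dim(ap) <- c(HW * B, C)
  s <- rowSums(ap)
  y3 <- e / bcCB(s)
  newNode(array(y3, d), list(x), function(g) {
    gy <- array(g, c(HW, C, B)) * y3
    apg <- aperm(gy, c(1, 3, 2)); dim(apg) <- c(HW * B, C)
    dot <- rowSums(apg)
    list(array(gy - y3 * bcCB(dot), d))
  })
}
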