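# Internal layer representation: each layer is an environment holding its
# parameters, a forward cache and gradient slots. Tensors are arrays
# (H, W, C, N). Convolutions run through im2col + BLAS; pooling and the
# col2im scatter are compiled.

#' Parametric rectified linear unit
#'
#' A = B for B >= 0 and A = K * B for B < 0, with K the learnable
#' negative-side slope. With K = 0 this is ReLU; with K = 1 the identity.
#'
#' @param B input value(s).
#' @param K negative-side slope.
#' @return activation value(s), same shape as `B`.
#' @examples
#' prelu(-4, 0.1)  # -0.4
#' @export
prelu <- function(B, K) ifelse(B >= 0, B, K * B)

newConv <- function(k, inC, outC, stride = 1L, pad = NULL) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$k <- as.integer(k); e$inC <- inC; e$outC <- outC
  e$stride <- as.integer(stride)
  e$pad <- if (is.null(pad)) (k - 1L) %/% 2L else as.integer(pad)
  sd <- sqrt(2 / (k * k * inC))  # He initialisation
  e$W <- matrix(stats::rnorm(k * k * inC * outC, 0, sd), k * k * inC, outC)
  e$b <- numeric(outC)
  e
}

newPool <- function(type = "max", size = 2L, stride = 2L, pad = 0L) {
  e <- new.env(parent = emptyenv())
  e$type <- "pool"; e$poolType <- type
  e$size <- as.integer(size); e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e
}

newAct <- function(kind, channels, preluInit = 0.1) {
  e <- new.env(parent = emptyenv())
  e$type <- "act"; e$kind <- kind; e$C <- channels
  if (kind == "prelu") e$K <- rep(preluInit, channels)
  e
}

newHead <- function(kind) {
  e <- new.env(parent = emptyenv()); e$type <- "head"; e$kind <- kind; e
}

newDense <- function(inN, outN) {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"; e$inN <- inN; e$outN <- outN
  e$W <- matrix(stats::rnorm(inN * outN, 0, sqrt(2 / inN)), inN, outN)
  e$b <- numeric(outN)
  e
}

newUnit <- function(incep, res, act, alphaInit, alphaTrainable) {
  e <- new.env(parent = emptyenv())
  e$type <- "unit"; e$incep <- incep; e$res <- res; e$act <- act
  e$alpha <- alphaInit; e$alphaTrainable <- alphaTrainable
  e
}

convFwd <- function(l, x) {
  d <- dim(x)
  oH <- (d[1] + 2L * l$pad - l$k) %/% l$stride + 1L
  oW <- (d[2] + 2L * l$pad - l$k) %/% l$stride + 1L
  cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], l$k, l$pad, l$stride)
  ym <- cols %*% l$W
  for (j in seq_len(ncol(ym))) ym[, j] <- ym[, j] + l$b[j]
  dim(ym) <- c(oH, oW, d[4], l$outC)
  l$cacheCols <- cols; l$cacheDim <- d
  aperm(ym, c(1, 2, 4, 3))
}

convBwd <- function(l, dout) {
  d <- l$cacheDim
  dm <- aperm(dout, c(1, 2, 4, 3))
  dim(dm) <- c(length(dm) / l$outC, l$outC)
  l$gW <- crossprod(l$cacheCols, dm)
  l$gb <- colSums(dm)
  dcols <- dm %*% t(l$W)
  l$cacheCols <- NULL
  col2im_cpp(dcols, d[1], d[2], d[3], d[4], l$k, l$pad, l$stride)
}

poolFwd <- function(l, x) {
  d <- dim(x)
  r <- pool_fwd_cpp(x, d[1], d[2], d[3], d[4], l$size, l$stride, l$pad,
                    if (l$poolType == "max") 0L else 1L)
  l$cacheArg <- r$arg; l$cacheDim <- d
  r$y
}

poolBwd <- function(l, dout) {
  d <- l$cacheDim
  pool_bwd_cpp(dout, l$cacheArg, d[1], d[2], d[3], d[4], l$size, l$stride,
               l$pad, if (l$poolType == "max") 0L else 1L)
}

# negative-slope vector recycled column-major over (H*W*C, N); length H*W*C
preluSlopes <- function(l, d) rep(l$K, each = d[1] * d[2])

actFwd <- function(l, x) {
  l$cacheX <- x
  switch(l$kind,
    relu = pmax(x, 0),
    leakyrelu = pmax(x, 0) + 0.01 * pmin(x, 0),
    elu = pmax(x, 0) + expm1(pmin(x, 0)),
    tanh = tanh(x),
    prelu = {
      d <- dim(x)
      y <- pmax(x, 0) + as.vector(pmin(x, 0)) * preluSlopes(l, d)
      dim(y) <- d
      y
    })
}

actBwd <- function(l, dout) {
  x <- l$cacheX; l$cacheX <- NULL
  switch(l$kind,
    relu = dout * (x > 0),
    leakyrelu = dout * (0.01 + 0.99 * (x >= 0)),
    elu = dout * ((x >= 0) + exp(pmin(x, 0)) * (x < 0)),
    tanh = dout * (1 - tanh(x)^2),
    prelu = {
      d <- dim(x)
      neg <- x < 0
      contrib <- dout * x * neg
      s <- colSums(matrix(contrib, d[1] * d[2], d[3] * d[4]))
      l$gK <- rowSums(matrix(s, d[3], d[4]))
      g <- as.vector(dout) * ((as.vector(x) >= 0) +
                              as.vector(neg) * preluSlopes(l, d))
      dim(g) <- d
      g
    })
}

seqFwd <- function(layers, x) {
  for (l in layers) x <- layerFwd(l, x)
  x
}

seqBwd <- function(layers, dout) {
  for (l in rev(layers)) dout <- layerBwd(l, dout)
  dout
}

headFwd <- function(l, x) {
  d <- dim(x); l$cacheDim <- d
  switch(l$kind,
    flatten = t(matrix(x, d[1] * d[2] * d[3], d[4])),
    global_average = t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])),
                              d[3], d[4])),
    global_max = {
      m <- matrix(x, d[1] * d[2], d[3] * d[4])
      am <- max.col(t(m))  # argmax per (C, N) column
      l$cacheArg <- am
      t(matrix(m[cbind(am, seq_along(am))], d[3], d[4]))
    })
}

headBwd <- function(l, dout) {
  d <- l$cacheDim
  switch(l$kind,
    flatten = array(t(dout), dim = d),
    global_average = {
      dx <- array(0, d)
      per <- t(dout) / (d[1] * d[2])  # (C, N)
      array(rep(as.vector(per), each = d[1] * d[2]), dim = d)
    },
    global_max = {
      m <- matrix(0, d[1] * d[2], d[3] * d[4])
      m[cbind(l$cacheArg, seq_along(l$cacheArg))] <- as.vector(t(dout))
      array(m, dim = d)
    })
}

denseFwd <- function(l, x) {
  l$cacheX <- x
  sweep(x %*% l$W, 2, l$b, "+")
}

denseBwd <- function(l, dout) {
  l$gW <- crossprod(l$cacheX, dout)
  l$gb <- colSums(dout)
  l$cacheX <- NULL
  dout %*% t(l$W)
}

unitFwd <- function(l, x) {
  i <- seqFwd(l$incep, x)
  r <- seqFwd(l$res, x)
  l$cacheI <- i
  z <- r + l$alpha * i
  actFwd(l$act, z)
}

unitBwd <- function(l, dout) {
  dz <- actBwd(l$act, dout)
  if (l$alphaTrainable) l$gAlpha <- sum(dz * l$cacheI)
  l$cacheI <- NULL
  di <- l$alpha * dz
  dxi <- seqBwd(l$incep, di)
  dxr <- seqBwd(l$res, dz)
  dxi + dxr
}

layerFwd <- function(l, x) {
  switch(l$type,
    conv = convFwd(l, x), pool = poolFwd(l, x), act = actFwd(l, x),
    unit = unitFwd(l, x), head = headFwd(l, x), dense = denseFwd(l, x))
}

layerBwd <- function(l, dout) {
  switch(l$type,
    conv = convBwd(l, dout), pool = poolBwd(l, dout), act = actBwd(l, dout),
    unit = unitBwd(l, dout), head = headBwd(l, dout), dense = denseBwd(l, dout))
}

# flat list of (env, param-name, grad-name) for the optimiser
collectParams <- function(layers) {
  out <- list()
  walk <- function(l) {
    if (l$type == "conv" || l$type == "dense") {
      out[[length(out) + 1L]] <<- list(env = l, p = "W", g = "gW")
      out[[length(out) + 1L]] <<- list(env = l, p = "b", g = "gb")
    } else if (l$type == "act" && l$kind == "prelu") {
      out[[length(out) + 1L]] <<- list(env = l, p = "K", g = "gK")
    } else if (l$type == "unit") {
      lapply(l$incep, walk); lapply(l$res, walk); walk(l$act)
      if (l$alphaTrainable)
        out[[length(out) + 1L]] <<- list(env = l, p = "alpha", g = "gAlpha")
    }
  }
  lapply(layers, walk)
  out
}

optimStep <- function(params, optimizer, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; rho <- 0.9
  for (pr in params) {
    e <- pr$env
    g <- get(pr$g, envir = e, inherits = FALSE)
    if (is.null(g)) next
    p <- get(pr$p, envir = e)
    mslot <- paste0(".m_", pr$p); vslot <- paste0(".v_", pr$p)
    getState <- function(slot) {
      if (!exists(slot, envir = e, inherits = FALSE)) p * 0
      else get(slot, envir = e, inherits = FALSE)
    }
    upd <- switch(optimizer,
      sgd = lr * g,
      adam = {
        m <- b1 * getState(mslot) + (1 - b1) * g
        v <- b2 * getState(vslot) + (1 - b2) * g^2
        assign(mslot, m, e); assign(vslot, v, e)
        lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
      },
      nadam = {
        m <- b1 * getState(mslot) + (1 - b1) * g
        v <- b2 * getState(vslot) + (1 - b2) * g^2
        assign(mslot, m, e); assign(vslot, v, e)
        mh <- m / (1 - b1^(t + 1)); gh <- g / (1 - b1^t)
        lr * (b1 * mh + (1 - b1) * gh) / (sqrt(v / (1 - b2^t)) + eps)
      },
      adamax = {
        m <- b1 * getState(mslot) + (1 - b1) * g
        u <- pmax(b2 * getState(vslot), abs(g))
        assign(mslot, m, e); assign(vslot, u, e)
        (lr / (1 - b1^t)) * m / (u + eps)
      },
      rmsprop = {
        v <- rho * getState(vslot) + (1 - rho) * g^2
        assign(vslot, v, e)
        lr * g / (sqrt(v) + eps)
      })
    assign(pr$p, p - upd, e)
  }
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# loss value and gradient w.r.t. the softmax probabilities
lossAndGradP <- function(loss, P, Y) {
  n <- nrow(P); K <- ncol(P)
  Pc <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  switch(loss,
    categorical_crossentropy = list(value = -sum(Y * log(Pc)) / n,
                                    dP = -(Y / Pc) / n),
    kld = list(value = sum(Y * log(pmax(Y, 1e-12) / Pc)) / n,
               dP = -(Y / Pc) / n),
    binary_crossentropy = list(
      value = -mean(Y * log(Pc) + (1 - Y) * log(1 - Pc)),
      dP = (-(Y / Pc) + (1 - Y) / (1 - Pc)) / (n * K)),
    mse = list(value = mean((P - Y)^2), dP = 2 * (P - Y) / (n * K)),
    mae = list(value = mean(abs(P - Y)), dP = sign(P - Y) / (n * K)),
    msle = list(value = mean((log1p(P) - log1p(Y))^2),
                dP = 2 * (log1p(P) - log1p(Y)) / ((1 + P) * n * K)))
}
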