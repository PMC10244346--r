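# Minimal CNN machinery: feature maps are arrays of dim (H, W, C), layers
# carry explicit forward/backward rules, and optimization is Adam.  This is
# the backbone behind the weakly supervised patch classifier (which needs
# access to last-layer activations and their gradients for class-activation
# mapping) and the bright-field-to-fluorescence translator.  Convolutions
# run as im2col (C++) + BLAS matrix products.

.convF <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  cols <- cpp_im2col(as.numeric(x), d[1], d[2], d[3], k, k, stride, pad)
  y <- W %*% cols + b
  oh <- (d[1] + 2 * pad - k) %/% stride + 1
  ow <- (d[2] + 2 * pad - k) %/% stride + 1
  list(y = array(t(y), c(oh, ow, nrow(W))),
       cache = list(cols = cols, dims = d, k = k, stride = stride, pad = pad, W = W))
}

.convB <- function(dy, cache) {
  d <- dim(dy)
  dyMat <- t(matrix(dy, d[1] * d[2], d[3]))
  dW <- dyMat %*% t(cache$cols)
  db <- rowSums(dyMat)
  dcols <- t(cache$W) %*% dyMat
  dd <- cache$dims
  dx <- array(cpp_col2im(dcols, dd[1], dd[2], dd[3], cache$k, cache$k,
                         cache$stride, cache$pad), dd)
  list(dx = dx, dW = dW, db = db)
}

.inormF <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); N <- d[1] * d[2]
  xm <- matrix(x, N, d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  sg <- sqrt(v + eps)
  xh <- sweep(sweep(xm, 2, mu), 2, sg, "/")
  y <- sweep(sweep(xh, 2, gamma, "*"), 2, beta, "+")
  list(y = array(y, d), cache = list(xh = xh, sg = sg, gamma = gamma, d = d))
}

.inormB <- function(dy, cache) {
  d <- cache$d; N <- d[1] * d[2]
  dym <- matrix(dy, N, d[3])
  dgamma <- colSums(dym * cache$xh)
  dbeta <- colSums(dym)
  t1 <- sweep(dym, 2, colMeans(dym))
  t2 <- sweep(cache$xh, 2, colMeans(dym * cache$xh), "*")
  dx <- sweep(t1 - t2, 2, cache$gamma / cache$sg, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

.lreluF <- function(x, a = 0) {
  y <- ifelse(x > 0, x, a * x)
  list(y = y, cache = x > 0)
}
.lreluB <- function(dy, cache, a = 0) dy * ifelse(cache, 1, a)

.poolF <- function(x) {  # 2x2 average pooling, stride 2
  d <- dim(x)
  oh <- d[1] %/% 2L; ow <- d[2] %/% 2L
  x <- x[seq_len(2 * oh), seq_len(2 * ow), , drop = FALSE]
  y <- (x[seq(1, 2 * oh, 2), seq(1, 2 * ow, 2), , drop = FALSE] +
          x[seq(2, 2 * oh, 2), seq(1, 2 * ow, 2), , drop = FALSE] +
          x[seq(1, 2 * oh, 2), seq(2, 2 * ow, 2), , drop = FALSE] +
          x[seq(2, 2 * oh, 2), seq(2, 2 * ow, 2), , drop = FALSE]) / 4
  list(y = y, cache = d)
}
.poolB <- function(dy, cache) {
  d <- cache
  dx <- array(0, d)
  g <- dy / 4
  oh <- dim(dy)[1]; ow <- dim(dy)[2]
  dx[seq(1, 2 * oh, 2), seq(1, 2 * ow, 2), ] <- g
  dx[seq(2, 2 * oh, 2), seq(1, 2 * ow, 2), ] <- g
  dx[seq(1, 2 * oh, 2), seq(2, 2 * ow, 2), ] <- g
  dx[seq(2, 2 * oh, 2), seq(2, 2 * ow, 2), ] <- g
  dx
}

.upF <- function(x) {  # nearest-neighbor 2x upsampling
  d <- dim(x)
  idx1 <- rep(seq_len(d[1]), each = 2)
  idx2 <- rep(seq_len(d[2]), each = 2)
  list(y = x[idx1, idx2, , drop = FALSE], cache = d)
}
.upB <- function(dy, cache) {
  d <- cache
  oh <- d[1]; ow <- d[2]
  dy[seq(1, 2 * oh, 2), seq(1, 2 * ow, 2), , drop = FALSE] +
    dy[seq(2, 2 * oh, 2), seq(1, 2 * ow, 2), , drop = FALSE] +
    dy[seq(1, 2 * oh, 2), seq(2, 2 * ow, 2), , drop = FALSE] +
    dy[seq(2, 2 * oh, 2), seq(2, 2 * ow, 2), , drop = FALSE]
}

.sigmoidF <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}
.sigmoidB <- function(dy, cache) dy * cache * (1 - cache)

# ---- sequential networks ---------------------------------------------------

.convLayer <- function(inC, outC, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  fanIn <- k * k * inC
  list(kind = "conv",
       W = matrix(rnorm(outC * fanIn, 0, sqrt(2 / fanIn)), outC, fanIn),
       b = numeric(outC), k = k, stride = stride, pad = pad,
       inC = inC, outC = outC)
}

.inormLayer <- function(C) list(kind = "inorm", gamma = rep(1, C), beta = numeric(C), outC = C)

#' @keywords internal
.buildSequential <- function(spec, inC) {
  layers <- list()
  C <- inC
  for (s in spec) {
    l <- switch(s[[1]],
      conv = { L <- .convLayer(C, s$out, s$k, s$stride %||% 1L,
                               s$pad %||% ((s$k - 1L) %/% 2L)); C <- s$out; L },
      inorm = .inormLayer(C),
      relu = list(kind = "relu", outC = C),
      lrelu = list(kind = "lrelu", a = s$a %||% 0.2, outC = C),
      pool = list(kind = "pool", outC = C),
      up = list(kind = "up", outC = C),
      gap = list(kind = "gap", outC = C),
      dense = { L <- list(kind = "dense",
                          W = matrix(rnorm(s$out * C, 0, sqrt(2 / C)), s$out, C),
                          b = numeric(s$out), outC = s$out); C <- s$out; L },
      sigmoid = list(kind = "sigmoid", outC = C),
      dropout = list(kind = "dropout", rate = s$rate %||% 0.3, outC = C),
      stop("unknown layer kind: ", s[[1]]))
    layers[[length(layers) + 1L]] <- l
  }
  list(layers = layers, inC = inC)
}

.seqForward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  acts <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    r <- switch(l$kind,
      conv = .convF(x, l$W, l$b, l$k, l$stride, l$pad),
      inorm = .inormF(x, l$gamma, l$beta),
      relu = .lreluF(x, 0),
      lrelu = .lreluF(x, l$a),
      pool = .poolF(x),
      up = .upF(x),
      sigmoid = .sigmoidF(x),
      gap = {
        d <- dim(x)
        list(y = colMeans(matrix(x, d[1] * d[2], d[3])), cache = d)
      },
      dense = list(y = as.numeric(l$W %*% x + l$b), cache = x),
      dropout = if (train && l$rate > 0) {
        m <- (runif(length(x)) > l$rate) / (1 - l$rate)
        list(y = x * m, cache = m)
      } else list(y = x, cache = NULL))
    caches[[i]] <- r$cache
    x <- r$y
    acts[[i]] <- x
  }
  list(out = x, caches = caches, acts = acts)
}

# Backward pass through a sequential net.  Returns parameter gradients and
# the gradient at the output of every layer (dAt[[i]] is d(loss)/d(output of
# layer i)); dAt[[0]] equivalent (input gradient) is in $dx.
.seqBackward <- function(net, fw, dout) {
  n <- length(net$layers)
  grads <- vector("list", n)
  dAt <- vector("list", n)
  dy <- dout
  for (i in rev(seq_len(n))) {
    dAt[[i]] <- dy
    l <- net$layers[[i]]
    cache <- fw$caches[[i]]
    if (l$kind == "conv") {
      r <- .convB(dy, cache)
      grads[[i]] <- list(W = r$dW, b = r$db)
      dy <- r$dx
    } else if (l$kind == "inorm") {
      r <- .inormB(dy, cache)
      grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
      dy <- r$dx
    } else if (l$kind == "relu") dy <- .lreluB(dy, cache, 0)
    else if (l$kind == "lrelu") dy <- .lreluB(dy, cache, l$a)
    else if (l$kind == "pool") dy <- .poolB(dy, cache)
    else if (l$kind == "up") dy <- .upB(dy, cache)
    else if (l$kind == "sigmoid") dy <- .sigmoidB(dy, cache)
    else if (l$kind == "gap") {
      d <- cache
      dy <- array(rep(dy / (d[1] * d[2]), each = d[1] * d[2]), d)
    } else if (l$kind == "dense") {
      grads[[i]] <- list(W = outer(dy, as.numeric(cache)), b = dy)
      dy <- as.numeric(t(l$W) %*% dy)
    } else if (l$kind == "dropout") {
      if (!is.null(cache)) dy <- dy * cache
    }
  }
  list(grads = grads, dx = dy, dAt = dAt)
}

.adamInit <- function(net) {
  lapply(net$layers, function(l) {
    if (l$kind == "conv") list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    else if (l$kind == "dense") list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    else if (l$kind == "inorm") list(mg = l$gamma * 0, vg = l$gamma * 0,
                                     mb = l$beta * 0, vb = l$beta * 0)
    else NULL
  })
}

.adamUpdate <- function(p, g, m, v, lr, b1, b2, t, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

.adamStep <- function(net, grads, state, lr, b1 = 0.9, b2 = 0.999, t = 1L) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    if (l$kind %in% c("conv", "dense")) {
      u <- .adamUpdate(l$W, g$W, s$mW, s$vW, lr, b1, b2, t)
      l$W <- u$p; s$mW <- u$m; s$vW <- u$v
      u <- .adamUpdate(l$b, g$b, s$mb, s$vb, lr, b1, b2, t)
      l$b <- u$p; s$mb <- u$m; s$vb <- u$v
    } else if (l$kind == "inorm") {
      u <- .adamUpdate(l$gamma, g$gamma, s$mg, s$vg, lr, b1, b2, t)
      l$gamma <- u$p; s$mg <- u$m; s$vg <- u$v
      u <- .adamUpdate(l$beta, g$beta, s$mb, s$vb, lr, b1, b2, t)
      l$beta <- u$p; s$mb <- u$m; s$vb <- u$v
    }
    net$layers[[i]] <- l
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# deterministic serialization helper used by invariance tests
.netParamHash <- function(net) {
  v <- unlist(lapply(net$layers, function(l)
    c(l$W, l$b, l$gamma, l$beta)), use.names = FALSE)
  sum(v * seq_along(v) %% 997)
}
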