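# Conditional-adversarial bright-field-to-fluorescence translation.  The
# generator is a small U-Net (skip connections, nearest-neighbor upsampling
# + convolution instead of transposed convolution, instance normalization);
# the discriminator is a patch discriminator whose output pixels each see a
# 16 x 16 receptive field (verified by gradient probing at build time).
# The objective is lambda * L1 + the adversarial term, with the adversarial
# term disabled for the second half of training.

#' Translator configuration presets
#'
#' \code{"desk"} is the tested CPU-scale path (64-px patches, narrow
#' channels, 30 epochs); \code{"paper"} carries the published large-scale
#' settings (256-px patches, 1260 patches/epoch, mini-batch 16, 2000 epochs
#' with learning rate 2e-4 kept for the first half then linearly decayed,
#' Adam beta1 = 0.5, lambda = 100, adversarial term disabled in the second
#' half).
#'
#' @param preset \code{"desk"} or \code{"paper"}
#' @return List of configuration values.
#' @export
translatorConfig <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "desk")
    list(preset = "desk", side = 64L, base = 4L, lambda = 100,
         epochs = 30L, patchesPerEpoch = 32L, batch = 4L, lr = 2e-3,
         beta1 = 0.5, beta2 = 0.999, ganDisableAfter = 15L, dropout = 0,
         seed = 1L)
  else
    list(preset = "paper", side = 256L, base = 64L, lambda = 100,
         epochs = 2000L, patchesPerEpoch = 1260L, batch = 16L, lr = 2e-4,
         beta1 = 0.5, beta2 = 0.999, ganDisableAfter = 1000L, dropout = 0.5,
         seed = 1L)
}

# generator parameter container: layers indexed for .adamStep
.buildGenerator <- function(base, dropout) {
  b <- base
  layers <- list(
    conv1 = .convLayer(1L, b, 3L), in1 = .inormLayer(b),
    conv2 = .convLayer(b, 2L * b, 3L), in2 = .inormLayer(2L * b),
    conv3 = .convLayer(2L * b, 4L * b, 3L), in3 = .inormLayer(4L * b),
    conv4 = .convLayer(4L * b, 2L * b, 3L), in4 = .inormLayer(2L * b),
    conv5 = .convLayer(4L * b, b, 3L), in5 = .inormLayer(b),
    conv6 = .convLayer(2L * b + 1L, 1L, 3L))
  list(layers = layers, base = b, dropout = dropout)
}

.genForward <- function(G, x, train = FALSE) {
  L <- G$layers
  cc <- list()
  r <- .convF(x, L$conv1$W, L$conv1$b, 3L, 1L, 1L); cc$c1 <- r$cache
  r2 <- .inormF(r$y, L$in1$gamma, L$in1$beta); cc$i1 <- r2$cache
  r3 <- .lreluF(r2$y, 0.2); cc$a1 <- r3$cache
  e1 <- r3$y
  p <- .poolF(e1); cc$p1 <- p$cache
  r <- .convF(p$y, L$conv2$W, L$conv2$b, 3L, 1L, 1L); cc$c2 <- r$cache
  r2 <- .inormF(r$y, L$in2$gamma, L$in2$beta); cc$i2 <- r2$cache
  r3 <- .lreluF(r2$y, 0.2); cc$a2 <- r3$cache
  e2 <- r3$y
  p <- .poolF(e2); cc$p2 <- p$cache
  r <- .convF(p$y, L$conv3$W, L$conv3$b, 3L, 1L, 1L); cc$c3 <- r$cache
  r2 <- .inormF(r$y, L$in3$gamma, L$in3$beta); cc$i3 <- r2$cache
  r3 <- .lreluF(r2$y, 0.2); cc$a3 <- r3$cache
  e3 <- r3$y
  if (train && G$dropout > 0) {
    m <- array((runif(length(e3)) > G$dropout) / (1 - G$dropout), dim(e3))
    e3 <- e3 * m; cc$drop <- m
  } else cc$drop <- NULL
  u <- .upF(e3); cc$u1 <- u$cache
  r <- .convF(u$y, L$conv4$W, L$conv4$b, 3L, 1L, 1L); cc$c4 <- r$cache
  r2 <- .inormF(r$y, L$in4$gamma, L$in4$beta); cc$i4 <- r2$cache
  r3 <- .lreluF(r2$y, 0); cc$a4 <- r3$cache
  d1 <- r3$y
  cat1 <- array(c(d1, e2), c(dim(d1)[1], dim(d1)[2], dim(d1)[3] + dim(e2)[3]))
  r <- .convF(cat1, L$conv5$W, L$conv5$b, 3L, 1L, 1L); cc$c5 <- r$cache
  r2 <- .inormF(r$y, L$in5$gamma, L$in5$beta); cc$i5 <- r2$cache
  r3 <- .lreluF(r2$y, 0); cc$a5 <- r3$cache
  d2 <- r3$y
  u <- .upF(d2); cc$u2 <- u$cache
  cat2 <- array(c(u$y, e1, x),
                c(dim(x)[1], dim(x)[2], dim(u$y)[3] + dim(e1)[3] + 1L))
  r <- .convF(cat2, L$conv6$W, L$conv6$b, 3L, 1L, 1L); cc$c6 <- r$cache
  z <- r$y
  y <- pmin(pmax(z, 0), 1)
  cc$clamp <- z > 0 & z < 1
  cc$dims <- list(d1 = dim(d1), e2 = dim(e2), u2 = dim(u$y), e1 = dim(e1))
  list(y = y, caches = cc)
}

.genBackward <- function(G, fw, dy) {
  L <- G$layers; cc <- fw$caches
  g <- list()
  dz <- dy * cc$clamp
  r <- .convB(dz, cc$c6); g$conv6 <- list(W = r$dW, b = r$db)
  dcat2 <- r$dx
  nb <- cc$dims$u2[3]
  du2 <- dcat2[, , seq_len(nb), drop = FALSE]
  de1a <- dcat2[, , nb + seq_len(cc$dims$e1[3]), drop = FALSE]
  dd2 <- .upB(du2, cc$u2)
  dd2 <- .lreluB(dd2, cc$a5, 0)
  r <- .inormB(dd2, cc$i5); g$in5 <- list(gamma = r$dgamma, beta = r$dbeta)
  r2 <- .convB(r$dx, cc$c5); g$conv5 <- list(W = r2$dW, b = r2$db)
  dcat1 <- r2$dx
  nd1 <- cc$dims$d1[3]
  dd1 <- dcat1[, , seq_len(nd1), drop = FALSE]
  de2a <- dcat1[, , nd1 + seq_len(cc$dims$e2[3]), drop = FALSE]
  dd1 <- .lreluB(dd1, cc$a4, 0)
  r <- .inormB(dd1, cc$i4); g$in4 <- list(gamma = r$dgamma, beta = r$dbeta)
  r2 <- .convB(r$dx, cc$c4); g$conv4 <- list(W = r2$dW, b = r2$db)
  de3 <- .upB(r2$dx, cc$u1)
  if (!is.null(cc$drop)) de3 <- de3 * cc$drop
  de3 <- .lreluB(de3, cc$a3, 0.2)
  r <- .inormB(de3, cc$i3); g$in3 <- list(gamma = r$dgamma, beta = r$dbeta)
  r2 <- .convB(r$dx, cc$c3); g$conv3 <- list(W = r2$dW, b = r2$db)
  de2 <- .poolB(r2$dx, cc$p2) + de2a
  de2 <- .lreluB(de2, cc$a2, 0.2)
  r <- .inormB(de2, cc$i2); g$in2 <- list(gamma = r$dgamma, beta = r$dbeta)
  r2 <- .convB(r$dx, cc$c2); g$conv2 <- list(W = r2$dW, b = r2$db)
  de1 <- .poolB(r2$dx, cc$p1) + de1a
  de1 <- .lreluB(de1, cc$a1, 0.2)
  r <- .inormB(de1, cc$i1); g$in1 <- list(gamma = r$dgamma, beta = r$dbeta)
  r2 <- .convB(r$dx, cc$c1); g$conv1 <- list(W = r2$dW, b = r2$db)
  g[names(G$layers)]
}

.buildDiscriminator <- function(base) {
  .buildSequential(list(
    list("conv", out = base, k = 4L, stride = 2L, pad = 1L),
    list("lrelu", a = 0.2),
    list("conv", out = 2L * base, k = 3L, stride = 2L, pad = 1L),
    list("lrelu", a = 0.2),
    list("conv", out = 1L, k = 3L, stride = 1L, pad = 1L)), inC = 2L)
}

# empirical receptive field of one interior output pixel of D, by
# backpropagating a unit gradient and measuring the input support
.probeReceptiveField <- function(D, side) {
  x <- array(runif(side * side * 2), c(side, side, 2L))
  fw <- .seqForward(D, x)
  od <- dim(fw$out)
  ci <- ceiling(od[1] / 2); cj <- ceiling(od[2] / 2)
  dout <- array(0, od); dout[ci, cj, 1] <- 1
  bw <- .seqBackward(D, fw, dout)
  supp <- apply(abs(bw$dx) > 1e-14, c(1, 2), any)
  rows <- range(which(rowSums(supp) > 0))
  cols <- range(which(colSums(supp) > 0))
  c(rows[2] - rows[1] + 1L, cols[2] - cols[1] + 1L)
}

#' Build the generator/discriminator pair
#'
#' The discriminator's empirical receptive field is probed at build time
#' (single-pixel gradient support) and must be 16 x 16.
#'
#' @param config from \code{\link{translatorConfig}}
#' @return Object of class \code{translator} (untrained).
#' @export
buildTranslator <- function(config = translatorConfig("desk")) {
  withSeed(config$seed, {
    G <- .buildGenerator(config$base, config$dropout)
    D <- .buildDiscriminator(config$base)
    rf <- .probeReceptiveField(D, config$side)
    if (!all(rf == 16L))
      stop(sprintf("discriminator receptive field is %d x %d, expected 16 x 16",
                   rf[1], rf[2]))
    structure(list(G = G, D = D, config = config, history = NULL,
                   receptiveField = rf),
              class = "translator")
  })
}

#' @export
print.translator <- function(x, ...) {
  cat(sprintf("translator (%s): base %d channels, D receptive field %d x %d%s\n",
              x$config$preset, x$config$base, x$receptiveField[1],
              x$receptiveField[2],
              if (is.null(x$history)) " (untrained)"
              else sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

.sigm <- function(x) 1 / (1 + exp(-x))

#' Train the bright-field-to-fluorescence translator
#'
#' Minimizes lambda * L1 + the adversarial term over randomly sampled
#' aligned patches; the discriminator is updated alongside until
#' \code{ganDisableAfter} epochs, after which its parameters are frozen and
#' the generator trains on the L1 term alone.  The learning rate is held
#' for the first half of the epochs and linearly decayed to zero over the
#' second half.
#'
#' @param pairs list of aligned pairs: each element a list with
#'   \code{bright} and \code{fluor} (\linkS4class{WellImage} or matrix of
#'   identical shape)
#' @param config from \code{\link{translatorConfig}}
#' @param model optional pre-built \code{translator} to continue training
#' @return Trained \code{translator}; \code{$history} has per-epoch columns
#'   \code{l1} (raw mean L1), \code{lambda_l1}, \code{l1_display}
#'   (lambda * L1 / 5, the conventional plotting scale), \code{gan},
#'   \code{total} (= lambda_l1 + gan, exactly) and \code{lr}.
#' @export
trainTranslator <- function(pairs, config = translatorConfig("desk"),
                            model = NULL) {
  for (p in pairs) {
    bb <- .asMatrix(p$bright); ff <- .asMatrix(p$fluor)
    if (!all(dim(bb) == dim(ff))) stop("unpaired shapes in training pairs")
  }
  if (is.null(model)) model <- buildTranslator(config)
  config <- model$config
  G <- model$G; D <- model$D
  side <- config$side; lam <- config$lambda
  withSeed(deriveSeed(config$seed, 1L), {
    stG <- .adamInit(list(layers = G$layers))
    stD <- .adamInit(D)
    tG <- 0L; tD <- 0L
    hist <- NULL
    dHashAtFreeze <- NULL
    for (ep in seq_len(config$epochs)) {
      lr <- if (ep <= config$epochs / 2) config$lr
      else config$lr * (config$epochs - ep + 1) / (config$epochs / 2)
      ganOn <- ep <= config$ganDisableAfter
      if (!ganOn && is.null(dHashAtFreeze)) dHashAtFreeze <- .netParamHash(D)
      epL1 <- epGan <- 0
      nb <- 0L
      for (start in seq(1, config$patchesPerEpoch, by = config$batch)) {
        bsz <- min(config$batch, config$patchesPerEpoch - start + 1L)
        xs <- vector("list", bsz); ys <- vector("list", bsz)
        for (s in seq_len(bsz)) {
          pi <- sample.int(length(pairs), 1)
          bb <- .asMatrix(pairs[[pi]]$bright); ff <- .asMatrix(pairs[[pi]]$fluor)
          r0 <- sample.int(nrow(bb) - side + 1L, 1) - 1L
          c0 <- sample.int(ncol(bb) - side + 1L, 1) - 1L
          xs[[s]] <- array(bb[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side)],
                           c(side, side, 1L))
          ys[[s]] <- array(ff[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side)],
                           c(side, side, 1L))
        }
        # --- discriminator update (real vs generated pairs) ---
        if (ganOn) {
          gD <- NULL
          for (s in seq_len(bsz)) {
            fake <- .genForward(G, xs[[s]], train = TRUE)$y
            inR <- array(c(xs[[s]], ys[[s]]), c(side, side, 2L))
            inF <- array(c(xs[[s]], fake), c(side, side, 2L))
            fwR <- .seqForward(D, inR); fwF <- .seqForward(D, inF)
            N <- length(fwR$out)
            dR <- -(1 - .sigm(fwR$out)) / N
            dF <- .sigm(fwF$out) / N
            bwR <- .seqBackward(D, fwR, dR)
            bwF <- .seqBackward(D, fwF, dF)
            add <- function(a, b) if (is.null(a)) b else
              mapply(function(u, v) if (is.null(u)) NULL else
                mapply(`+`, u, v, SIMPLIFY = FALSE), a, b, SIMPLIFY = FALSE)
            gD <- add(gD, add(bwR$grads, bwF$grads))
          }
          gD <- lapply(gD, function(g) if (is.null(g)) NULL else lapply(g, `/`, bsz))
          tD <- tD + 1L
          up <- .adamStep(D, gD, stD, lr, config$beta1, config$beta2, tD)
          D <- up$net; stD <- up$state
        }
        # --- generator update ---
        gG <- NULL
        for (s in seq_len(bsz)) {
          fwG <- .genForward(G, xs[[s]], train = TRUE)
          fake <- fwG$y
          Np <- length(fake)
          l1 <- mean(abs(fake - ys[[s]]))
          dfake <- lam * sign(fake - ys[[s]]) / Np
          ganTerm <- 0
          if (ganOn) {
            inF <- array(c(xs[[s]], fake), c(side, side, 2L))
            fwF <- .seqForward(D, inF)
            Nd <- length(fwF$out)
            ganTerm <- mean(log(pmax(1 - .sigm(fwF$out), 1e-12)))
            dScore <- -.sigm(fwF$out) / Nd
            bwD <- .seqBackward(D, fwF, dScore)
            dfake <- dfake + bwD$dx[, , 2, drop = FALSE]
          }
          gs <- .genBackward(G, fwG, dfake)
          gG <- if (is.null(gG)) gs else
            mapply(function(u, v) mapply(`+`, u, v, SIMPLIFY = FALSE),
                   gG, gs, SIMPLIFY = FALSE)
          epL1 <- epL1 + l1; epGan <- epGan + ganTerm
          nb <- nb + 1L
        }
        gG <- lapply(gG, function(g) lapply(g, `/`, bsz))
        tG <- tG + 1L
        netG <- list(layers = G$layers)
        up <- .adamStep(netG, gG, stG, lr, config$beta1, config$beta2, tG)
        G$layers <- up$net$layers; stG <- up$state
      }
      l1m <- epL1 / nb; ganm <- epGan / nb
      hist <- rbind(hist, data.frame(
        epoch = ep, l1 = l1m, lambda_l1 = lam * l1m,
        l1_display = lam * l1m / 5, gan = ganm,
        total = lam * l1m + ganm, lr = lr, gan_on = ganOn))
    }
    model$G <- G; model$D <- D; model$history <- hist
    model$dFreezeHash <- dHashAtFreeze       # D parameters when GAN was disabled
    model$dFinalHash <- .netParamHash(D)     # must match dFreezeHash afterwards
    model
  })
}

#' Predict fluorescence from a bright-field image
#'
#' The image is edge-padded to a multiple of the generator's downsampling
#' factor, passed through the generator, and cropped back.
#'
#' @param model a trained \code{translator}
#' @param bright \linkS4class{WellImage} or matrix
#' @return \linkS4class{WellImage} (cTnT channel) with intensities in
#'   [0,1].
#' @export
predictFluorescence <- function(model, bright) {
  p <- .asMatrix(bright)
  H <- nrow(p); W <- ncol(p)
  Hp <- ceiling(H / 4) * 4L; Wp <- ceiling(W / 4) * 4L
  if (Hp > H) p <- p[c(seq_len(H), rep(H, Hp - H)), , drop = FALSE]
  if (Wp > W) p <- p[, c(seq_len(W), rep(W, Wp - W)), drop = FALSE]
  y <- .genForward(model$G, array(p, c(Hp, Wp, 1L)), train = FALSE)$y
  out <- matrix(y[, , 1], Hp, Wp)[seq_len(H), seq_len(W)]
  wid <- if (is(bright, "WellImage")) wellId(bright) else "well"
  WellImage(out, wellId = wid, channel = "cTnT")
}

#' Pixel-level correlation of predicted and true fluorescence
#'
#' Both images are resized to \code{evalSize} squared, the Pearson
#' correlation over pixels is computed, and a joint intensity histogram is
#' returned with counts per \code{binScale}.
#'
#' @param pred,true \linkS4class{WellImage} or matrix
#' @param evalSize evaluation side (default 512)
#' @param binScale histogram counts are divided by this (default 100)
#' @param nbins histogram bins per axis (default 64)
#' @return List with \code{r} (NA with a message when either image is
#'   constant), \code{hist} (nbins x nbins, counts / binScale),
#'   \code{breaks}.
#' @export
evaluatePixelCorrelation <- function(pred, true, evalSize = 512L,
                                     binScale = 100, nbins = 64L) {
  a <- .resizeTo(.asMatrix(pred), evalSize)
  b <- .resizeTo(.asMatrix(true), evalSize)
  r <- if (sd(a) == 0 || sd(b) == 0) {
    message("constant image: pixel correlation undefined")
    NA_real_
  } else cor(as.numeric(a), as.numeric(b))
  br <- seq(0, 1, length.out = nbins + 1L)
  ia <- pmin(pmax(findInterval(a, br, rightmost.closed = TRUE), 1L), nbins)
  ib <- pmin(pmax(findInterval(b, br, rightmost.closed = TRUE), 1L), nbins)
  h <- matrix(0, nbins, nbins)
  tb <- table(ia, ib)
  h[cbind(as.integer(rownames(tb))[row(tb)], as.integer(colnames(tb))[col(tb)])] <- tb
  list(r = r, hist = h / binScale, breaks = br)
}
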