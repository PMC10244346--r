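# Seed plumbing: all randomness flows through withSeed()/deriveSeed() so that
# generation is reproducible without touching the caller's RNG state.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed}, so callers' random streams are
#' unaffected.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return The value of \code{code}.
#' @export
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed to per-well / per-module streams;
#' results stay below 2^31.
#'
#' @param seed master seed
#' @param index stream index (>= 0)
#' @return integer seed
#' @export
deriveSeed <- function(seed, index = 0L) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(index) * 1234567 + 1) %% 2147483647)
}

# separable circular Gaussian blur (stats::filter along both axes)
.blurSep <- function(z, sigma) {
  if (sigma <= 0) return(z)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  z <- stats::filter(z, k, circular = TRUE)
  t(stats::filter(t(z), k, circular = TRUE))
}

# smooth band-limited noise field, rescaled to zero mean unit variance; the
# large-sigma fields are synthesized at reduced resolution and upscaled
.smoothNoise <- function(side, sigma) {
  f <- if (sigma >= 4) 4L else if (sigma >= 2) 2L else 1L
  s2 <- as.integer(ceiling(side / f))
  z <- matrix(rnorm(s2 * s2), s2, s2)
  z <- .blurSep(z, sigma / f)
  if (f > 1L)
    z <- .m(EBImage::resize(EBImage::Image(z), w = side, h = side))
  else z <- matrix(z, s2, s2)
  z <- z[seq_len(side), seq_len(side)]
  (z - mean(z)) / stats::sd(z)
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# polygon area (shoelace) and perimeter for a 2-column coordinate matrix
.polyArea <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

.polyPerimeter <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(0)
  i2 <- c(2:n, 1)
  sum(sqrt(rowSums((xy[i2, , drop = FALSE] - xy)^2)))
}

# strip EBImage's Image class down to a plain numeric matrix
.m <- function(x) {
  d <- dim(x)
  matrix(as.numeric(x), d[1], d[2])
}

# 8-connected component labeling: EBImage's bwlabel is 4-connected, so
# labels touching diagonally are merged by union-find
.label8 <- function(mask) {
  lbl <- .m(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lbl)
  if (n <= 1) return(lbl)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  H <- nrow(lbl); W <- ncol(lbl)
  prs <- rbind(cbind(as.vector(lbl[-H, -W]), as.vector(lbl[-1, -1])),
               cbind(as.vector(lbl[-H, -1]), as.vector(lbl[-1, -W])))
  prs <- prs[prs[, 1] > 0 & prs[, 2] > 0 & prs[, 1] != prs[, 2], , drop = FALSE]
  if (nrow(prs) > 0) {
    prs <- unique(prs)
    for (r in seq_len(nrow(prs))) {
      ra <- findRoot(prs[r, 1]); rb <- findRoot(prs[r, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_len(n), findRoot, numeric(1))
  newId <- match(root, sort(unique(root)))
  out <- lbl
  out[lbl > 0] <- newId[lbl[lbl > 0]]
  out
}
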