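# Synthetic whole-well generator.  Wells are multi-colony images whose
# committed ("fated") area fraction follows a Gaussian bump in log CHIR
# concentration centered at a line-specific optimum; image streams contract
# colonies at a dose-proportional rate.  All randomness flows through the
# plan seed, so identical (plan, dose, seed) calls are pixel-identical.

# Internal renderer shared by generateWell() and generateStream().
# Returns plain matrices plus the colony geometry.
.renderWell <- function(plan, dose, line, seed) {
  side <- plan@imageSize
  cen <- plan@optimalCenter[[line]]
  curve <- if (dose <= 0) 0 else
    exp(-((log(dose) - log(cen))^2) / (2 * plan@logWidth^2))
  pal <- maskPalette()
  withSeed(seed, {
    targetCov <- runif(1, 0.40, 0.60)
    nCol <- sample(seq(plan@coloniesPerWell[1], plan@coloniesPerWell[2]), 1)
    rBase <- side * sqrt(targetCov / (pi * nCol))
    # colony centers kept away from the border
    m <- max(8, side * 0.08)
    cy <- runif(nCol, m + rBase * 0.5, side - m - rBase * 0.5)
    cx <- runif(nCol, m + rBase * 0.5, side - m - rBase * 0.5)
    rk <- rBase * runif(nCol, 0.8, 1.15)
    amp <- matrix(rnorm(4 * nCol, 0, 0.09), nCol)
    phs <- matrix(runif(4 * nCol, 0, 2 * pi), nCol)
    rasterize <- function(scale) {
      msk <- matrix(FALSE, side, side)
      for (k in seq_len(nCol)) {
        rmax <- scale * rk[k] * 1.5
        y1 <- max(1, floor(cy[k] - rmax)); y2 <- min(side, ceiling(cy[k] + rmax))
        x1 <- max(1, floor(cx[k] - rmax)); x2 <- min(side, ceiling(cx[k] + rmax))
        dy <- matrix(y1:y2 - cy[k], y2 - y1 + 1, x2 - x1 + 1)
        dx <- matrix(x1:x2 - cx[k], y2 - y1 + 1, x2 - x1 + 1, byrow = TRUE)
        th <- atan2(dx, dy)
        rad <- scale * rk[k] *
          (1 + amp[k, 1] * cos(2 * th + phs[k, 1]) + amp[k, 2] * cos(3 * th + phs[k, 2]) +
             amp[k, 3] * cos(4 * th + phs[k, 3]) + amp[k, 4] * cos(5 * th + phs[k, 4]))
        msk[y1:y2, x1:x2] <- msk[y1:y2, x1:x2] | (dy * dy + dx * dx <= rad * rad)
      }
      msk
    }
    colonyMask <- rasterize(1)
    # one calibration pass compensates overlap/perturbation losses so the
    # achieved coverage tracks the drawn target
    achieved <- mean(colonyMask)
    if (achieved > 0 && abs(achieved - targetCov) / targetCov > 0.08)
      colonyMask <- rasterize(min(sqrt(targetCov / achieved), 1.6))
    cov <- mean(colonyMask)
    # latent colony quality: unimodal in achieved coverage, acts on the
    # fluorescence intensity level so 0 h morphology predicts efficiency
    q <- exp(-((cov - 0.5)^2) / (2 * 0.15^2))
    # committed fraction of the colony area: the dose-response bump
    darkFrac <- plan@maxDarkFraction * curve
    u <- .smoothNoise(side, 8)
    fated <- colonyMask & FALSE
    if (darkFrac > 0 && any(colonyMask)) {
      thr <- quantile(u[colonyMask], 1 - darkFrac)
      fated <- colonyMask & (u > thr)
    }
    # bright-field: near-flat background, textured colony interior, and a
    # finer higher-variance texture in committed regions
    bright <- 0.62 + 0.01 * .smoothNoise(side, 6) +
      0.004 * matrix(rnorm(side * side), side, side)
    interior <- 0.48 + 0.05 * .smoothNoise(side, 2)
    fatedTex <- 0.48 + 0.05 * plan@textureMargin * .smoothNoise(side, 1)
    bright[colonyMask] <- interior[colonyMask]
    bright[fated] <- fatedTex[fated]
    cellNoise <- matrix(rnorm(side * side, 0, plan@noiseSd), side, side)
    bright[colonyMask] <- bright[colonyMask] + cellNoise[colonyMask]
    bright <- .clip01(bright)
    # fluorescence: positives only inside committed regions; intensity level
    # carries the colony-quality signal
    fluor <- 0.02 + 0.03 * abs(.smoothNoise(side, 3))
    fl <- 0.55 + 0.35 * q + 0.06 * .smoothNoise(side, 2)
    fluor[fated] <- fl[fated]
    fluor <- .clip01(fluor)
    # three-level mask: committed = dark gray, a thin likely rim = light
    # gray, everything else (background and uncommitted colony) = black
    codes <- matrix(pal[["black"]], side, side)
    if (any(fated)) {
      rim <- EBImage::dilate(EBImage::Image(fated * 1),
                             EBImage::makeBrush(7, "disc")) > 0.5
      rim <- as.matrix(rim) & colonyMask & !fated
      codes[rim] <- pal[["light_gray"]]
      codes[fated] <- pal[["dark_gray"]]
    }
    list(bright = bright, fluor = fluor, codes = codes,
         colonyMask = colonyMask, coverage = cov, quality = q,
         darkFrac = darkFrac)
  })
}

#' Generate one synthetic well
#'
#' Renders the bright-field image, the paired fluorescence label and the
#' three-level region mask of one well at the given CHIR dose.  The
#' committed (dark-gray) fraction of the colony area equals
#' \code{maxDarkFraction} times a Gaussian bump in log dose centered at the
#' line optimum; fluorescence positives lie inside committed regions.
#'
#' @param plan a \linkS4class{SyntheticPlan}
#' @param dose CHIR concentration in micromolar (> 0)
#' @param line cell line id (defaults to the plan's first line)
#' @param seed integer seed (defaults to the plan seed)
#' @return List with \code{bright}, \code{fluor} (\linkS4class{WellImage})
#'   and \code{mask} (\linkS4class{RegionMask}).
#' @export
#' @examples
#' plan <- syntheticPlan(imageSize = 256L, seed = 7L)
#' w <- generateWell(plan, dose = 6)
generateWell <- function(plan, dose, line = plan@cellLines[1], seed = plan@seed) {
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive")
  if (!is.finite(seed)) stop("invalid seed")
  r <- .renderWell(plan, dose, line, seed)
  id <- sprintf("well_s%d", seed)
  list(bright = WellImage(r$bright, wellId = id, channel = "brightfield"),
       fluor = WellImage(r$fluor, wellId = id, channel = "cTnT"),
       mask = RegionMask(r$codes, wellId = id))
}

# separable bilinear sampling of img at coordinates scaled by 1/s about the
# image center; outside-template pixels get `fill`
.warpScale <- function(img, s, fill) {
  side <- nrow(img)
  c0 <- (side + 1) / 2
  xs <- (seq_len(side) - c0) / s + c0
  lo <- floor(xs)
  fr <- xs - lo
  idx <- function(k) pmin(pmax(k, 1L), side)
  inR <- xs >= 1 & xs <= side
  a <- img[idx(lo), , drop = FALSE] * (1 - fr) + img[idx(lo + 1), , drop = FALSE] * fr
  a[!inR, ] <- fill
  b <- t(t(a[, idx(lo), drop = FALSE]) * (1 - fr)) + t(t(a[, idx(lo + 1), drop = FALSE]) * fr)
  b[, !inR] <- fill
  b
}

#' Generate a 0-12 h synthetic image stream
#'
#' Ten frames of one well in which colonies contract toward the well center
#' at a rate proportional to dose while colony regions brighten, emulating
#' the early dose-dependent compaction response.  A dose of 0 is accepted as
#' the no-contraction surrogate and yields ten identical frames.
#'
#' @inheritParams generateWell
#' @return An \linkS4class{ImageStream} with dose metadata.
#' @export
generateStream <- function(plan, dose, line = plan@cellLines[1], seed = plan@seed) {
  if (!is.finite(dose) || dose < 0) stop("dose must be non-negative")
  r <- .renderWell(plan, max(dose, min(plan@concentrations)), line, seed)
  maxC <- max(plan@concentrations)
  cRate <- 0.02 * dose / maxC          # per-frame relative contraction
  bGain <- 0.06 * dose / maxC          # total brightening over the stream
  id <- sprintf("stream_s%d", seed)
  fr <- vector("list", 10L)
  for (t in 1:10) {
    s <- 1 - cRate * (t - 1)
    if (cRate == 0) {
      b <- r$bright
      m <- r$colonyMask
    } else {
      b <- .warpScale(r$bright, s, fill = 0.62)
      m <- .warpScale(r$colonyMask * 1, s, fill = 0) > 0.5
    }
    b[m] <- b[m] + bGain * (t - 1) / 9
    fr[[t]] <- WellImage(.clip01(b), wellId = id, channel = "brightfield")
  }
  ImageStream(fr, wellId = id, chirUm = dose, chirH = plan@durations[1])
}

#' Generate a synthetic batch of wells
#'
#' Builds the per-well record table of a batch: lines, concentrations and
#' durations are cycled over the wells, each well is rendered once to
#' compute its true efficiency from the fluorescence label, and a
#' deterministic image store hands back any well's images (or its 0-12 h
#' stream) on demand without holding them in memory.
#'
#' @param plan a \linkS4class{SyntheticPlan}
#' @param batch batch identifier (affects derived seeds)
#' @param dir optional directory; when given, bright/fluor TIFFs, mask PNGs
#'   and the record CSV are written there
#' @return List with \code{records} (data.frame: well_id, line, batch,
#'   chir_um, chir_h, efficiency_index, positive_fraction, seed) and
#'   \code{store(well_id, what)} with \code{what} one of \code{"well"} or
#'   \code{"stream"}.
#' @export
generateBatch <- function(plan, batch = 1L, dir = NULL) {
  n <- plan@nWells
  cols <- c("well_id", "line", "batch", "chir_um", "chir_h",
            "efficiency_index", "positive_fraction", "seed")
  if (n == 0L) {
    records <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(list(records = records, store = function(...) stop("empty batch")))
  }
  line <- plan@cellLines[(seq_len(n) - 1L) %% length(plan@cellLines) + 1L]
  conc <- plan@concentrations[(seq_len(n) - 1L) %% length(plan@concentrations) + 1L]
  dur <- plan@durations[((seq_len(n) - 1L) %/% length(plan@concentrations)) %%
                          length(plan@durations) + 1L]
  seeds <- vapply(seq_len(n), function(i)
    deriveSeed(plan@seed, i + 100000L * as.integer(batch)), integer(1))
  eff <- pos <- numeric(n)
  ids <- sprintf("B%d_W%03d", as.integer(batch), seq_len(n))
  for (i in seq_len(n)) {
    r <- .renderWell(plan, conc[i], line[i], seeds[i])
    e <- efficiencyIndex(r$fluor)
    eff[i] <- e$index
    pos[i] <- e$positive_fraction
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      tiff::writeTIFF(r$bright, file.path(dir, paste0(ids[i], "_bf.tif")),
                      bits.per.sample = 16L)
      tiff::writeTIFF(r$fluor, file.path(dir, paste0(ids[i], "_fl.tif")),
                      bits.per.sample = 16L)
      png::writePNG(r$codes / 255, file.path(dir, paste0(ids[i], "_mask.png")))
    }
  }
  records <- data.frame(well_id = ids, line = line, batch = as.integer(batch),
                        chir_um = conc, chir_h = dur, efficiency_index = eff,
                        positive_fraction = pos, seed = seeds,
                        stringsAsFactors = FALSE)
  if (!is.null(dir))
    write.csv(records[, cols[1:7]], file.path(dir, "records.csv"), row.names = FALSE)
  store <- function(well_id, what = c("well", "stream")) {
    what <- match.arg(what)
    i <- match(well_id, records$well_id)
    if (is.na(i)) stop("unknown well: ", well_id)
    if (what == "well")
      generateWell(plan, records$chir_um[i], records$line[i], records$seed[i])
    else generateStream(plan, records$chir_um[i], records$line[i], records$seed[i])
  }
  list(records = records, store = store)
}
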