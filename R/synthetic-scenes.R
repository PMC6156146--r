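## Synthetic fluorescence-scene generator.
##
## Geometry is built per cell inside a small local window (bounding box of the
## cell disc) and pasted into the full frame, so cost scales with cell count,
## not frame area. All randomness is drawn from R's RNG stream: seeding is
## done once at the entry points, making (config, seed) -> scene bit-identical.

# chebyshev dilation of a logical matrix by radius k (vectorized shifts)
dilateCheb <- function(m, k = 1L) {
  out <- m
  for (i in seq_len(k)) {
    g <- out
    g <- g | shiftMat(out, 1L, 0L, FALSE) | shiftMat(out, -1L, 0L, FALSE) |
      shiftMat(out, 0L, 1L, FALSE) | shiftMat(out, 0L, -1L, FALSE) |
      shiftMat(out, 1L, 1L, FALSE) | shiftMat(out, 1L, -1L, FALSE) |
      shiftMat(out, -1L, 1L, FALSE) | shiftMat(out, -1L, -1L, FALSE)
    out <- g
  }
  out
}

erodeCheb <- function(m, k = 1L) !dilateCheb(!m, k)

# draw per-object skeleton lengths (um) implementing the fragmentation dial:
# f = 0 -> one tubule carrying the whole budget; otherwise each object is
# independently "short" with probability f. Short lengths stay below
# 0.75 x cutoff and long lengths above 1.75 x cutoff so true classes sit well
# away from the classification boundary.
drawObjectLengths <- function(cfg) {
  f <- cfg$mitoFragmentation
  if (f == 0) return(cfg$mitoTotalLengthUm)
  meanShort <- cfg$mitoFragmentLengthUm
  meanLong <- 2.6 * cfg$shortLongCutoffUm
  n <- max(1L, round(cfg$mitoTotalLengthUm /
                       (f * meanShort + (1 - f) * meanLong)))
  isShort <- runif(n) < f
  len <- numeric(n)
  len[isShort] <- pmin(0.75 * cfg$shortLongCutoffUm,
                       runif(sum(isShort), 0.6, 1.2) * meanShort)
  len[!isShort] <- runif(sum(!isShort), 1.75, 3.5) * cfg$shortLongCutoffUm
  len
}

# persistent random walk of n unit-pixel steps inside `allowed`, avoiding
# `avoid`; returns visited pixel rows/cols and the number of steps taken
randomWalkPixels <- function(start, nSteps, allowed, avoid) {
  .walkCpp(as.integer(start), as.integer(nSteps), allowed & !avoid, 0.35)
}

# build the mitochondrial network inside one local window.
# region: logical matrix (the cell region, local coordinates).
# Returns local label matrix + object table. Objects are painted as
# width-`mitoWidthPx` tubules and kept >= 2 px apart so distinct objects stay
# distinct connected components; a window too small for a single fragment
# footprint is a degenerate-region error.
genMitoLocal <- function(cfg, region) {
  if (!any(region)) stop("generateMitoNetwork: empty cell region")
  # clear a 1-px frame so dilations can use unchecked linear offsets
  region[c(1L, nrow(region)), ] <- FALSE
  region[, c(1L, ncol(region))] <- FALSE
  if (!any(region))
    stop("generateMitoNetwork: cell region smaller than one fragment footprint")
  halfW <- max(1L, (cfg$mitoWidthPx - 1L) %/% 2L)
  allowed <- erodeCheb(region, halfW)
  minSteps <- max(1L, round(0.6 * cfg$mitoFragmentLengthUm / cfg$pixelSizeUm))
  if (sum(allowed) < minSteps * cfg$mitoWidthPx)
    stop("generateMitoNetwork: cell region smaller than one fragment footprint")
  lens <- drawObjectLengths(cfg)
  labels <- matrix(0L, nrow(region), ncol(region))
  dil1 <- matrix(FALSE, nrow(region), ncol(region))   # mask dilated by 1
  boxOff <- as.matrix(expand.grid(dr = -halfW:halfW, dc = -halfW:halfW))
  cheb1Off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  objLen <- numeric(length(lens)); objArea <- integer(length(lens))
  nObj <- 0L
  allowedIdx <- which(allowed)
  nrReg <- nrow(region)
  cheb1Lin <- cheb1Off[, 1L] + cheb1Off[, 2L] * nrReg
  for (len in lens) {
    nSteps <- max(1L, round(len / cfg$pixelSizeUm))
    done <- FALSE
    for (attempt in 1:40) {
      st <- 0L
      draws <- allowedIdx[sample.int(length(allowedIdx), 30L, replace = TRUE)]
      for (cand in draws) {
        if (!any(dil1[cand + cheb1Lin])) { st <- cand; break }
      }
      if (st == 0L) break
      start <- c((st - 1L) %% nrow(region) + 1L,
                 (st - 1L) %/% nrow(region) + 1L)
      w <- randomWalkPixels(start, nSteps, allowed, dil1)
      if (w$steps < max(1L, nSteps %/% 3L) && attempt < 40L) next
      n9 <- nrow(boxOff)
      rr <- rep(w$rows, each = n9) + boxOff[, 1L]
      cc <- rep(w$cols, each = n9) + boxOff[, 2L]
      keep <- rr >= 1L & rr <= nrow(region) & cc >= 1L & cc <= ncol(region)
      body <- unique((cc[keep] - 1L) * nrow(region) + rr[keep])
      body <- body[region[body]]
      # a colliding placement is never accepted: distinct generator objects
      # must remain distinct connected components of the painted mask
      if (any(dil1[body])) next
      nObj <- nObj + 1L
      labels[body] <- nObj
      objLen[nObj] <- w$steps * cfg$pixelSizeUm
      objArea[nObj] <- length(body)
      # body pixels sit inside `region`, which keeps a margin from the
      # window border, so the 1-px dilation can use unchecked offsets
      dil1[rep(body, each = length(cheb1Lin)) + cheb1Lin] <- TRUE
      done <- TRUE
      break
    }
    if (!done) break   # window saturated; stop placing further objects
  }
  # an object's true skeleton length is the skeleton of its painted mask
  # (walk folding can make this shorter than the walk itself), so classes
  # are exactly recoverable from a clean render
  lens <- skeletonLengthByLabel(thinMask(labels > 0L), labels,
                                cfg$pixelSizeUm)
  maskLen <- numeric(nObj)
  maskLen[as.integer(names(lens))] <- as.numeric(lens)
  obj <- data.frame(
    label = seq_len(nObj),
    skeletonLengthUm = maskLen,
    class = as.character(ifelse(maskLen >= cfg$shortLongCutoffUm,
                                "long", "short")),
    areaPx = objArea[seq_len(nObj)])
  list(labels = labels, objects = obj)
}

#' Generate a per-cell mitochondrial network
#'
#' Draws mitochondria as persistent random-walk tubules of configurable width
#' confined to a cell region. The fragmentation level controls the mix of
#' short fragments and long tubules (see [sceneConfig()]); each object's true
#' skeleton length and short/long class (by the generator's own cutoff) are
#' recorded. Distinct objects are kept at least two pixels apart so they
#' remain distinct connected components. Uses the current RNG state.
#'
#' @param config a [sceneConfig()].
#' @param cellRegion logical matrix: the region the network must stay inside.
#' @return list with \code{mask} (logical), \code{labels} (integer matrix)
#'   and \code{objects} (data.frame: label, skeletonLengthUm, class, areaPx).
#' @export
generateMitoNetwork <- function(config, cellRegion) {
  validateSceneConfig(config)
  res <- genMitoLocal(config, cellRegion)
  list(mask = res$labels > 0L, labels = res$labels, objects = res$objects)
}

# sample punctum centers in a local window.
# mode "fraction": each punctum is independently colocalized with probability
# colocFraction (center inside mito mask) or not. Non-colocalized centers
# keep a full disc radius clear of the mitochondrial mask so their flag is
# consistent with every overlap-based readout (a punctum labelled
# not-colocalized contributes no green-on-mito area).
# Returns data.frame(row, col, isColocalized).
placePunctaLocal <- function(region, mito, nPuncta, colocFraction, cfg) {
  if (nPuncta <= 0L)
    return(data.frame(row = integer(0), col = integer(0),
                      isColocalized = logical(0)))
  inIdx <- which(region & mito)
  clearance <- as.integer(ceiling(cfg$punctumRadiusUm / cfg$pixelSizeUm)) + 1L
  outMask <- region & !dilateCheb(mito, clearance)
  if (!any(outMask)) outMask <- region & !mito   # crowded cell: fall back
  outIdx <- which(outMask)
  if (colocFraction > 0 && length(inIdx) == 0L)
    stop("placePuncta: colocFraction > 0 with an empty mitochondrial mask")
  minSep <- cfg$minPunctumSeparationUm / cfg$pixelSizeUm
  nr <- nrow(region)
  rows <- integer(nPuncta); cols <- integer(nPuncta)
  flags <- runif(nPuncta) < colocFraction
  placed <- logical(nPuncta)
  nDone <- 0L
  for (i in seq_len(nPuncta)) {
    pool <- if (flags[i]) inIdx else outIdx
    if (length(pool) == 0L) {
      flags[i] <- !flags[i]
      pool <- if (flags[i]) inIdx else outIdx
    }
    if (length(pool) == 0L) stop("placePuncta: no placement pixels available")
    for (try in 1:60) {
      id <- pool[sample.int(length(pool), 1L)]
      r <- (id - 1L) %% nr + 1L; cl <- (id - 1L) %/% nr + 1L
      if (nDone == 0L || minSep <= 0 ||
          min((rows[which(placed)] - r)^2 +
              (cols[which(placed)] - cl)^2) >= minSep^2) {
        rows[i] <- r; cols[i] <- cl
        placed[i] <- TRUE
        nDone <- nDone + 1L
        break
      }
      # a punctum that cannot honour the separation is dropped, never
      # stacked: distinct ground-truth puncta must stay resolvable
    }
  }
  data.frame(row = rows[placed], col = cols[placed],
             isColocalized = flags[placed])
}

# place background puncta plus enough colocalized puncta to bring the
# green-on-mito covered fraction of the mitochondrial area up to `target`.
# Punctum centers are guaranteed a full disc radius away from the window
# border, so discs are stamped with unchecked linear offsets.
# Returns the puncta table and the achieved fraction.
placePunctaToTargetLocal <- function(region, mito, target, nBackground, cfg) {
  nr <- nrow(region)
  off <- discOffsets(cfg$punctumRadiusUm / cfg$pixelSizeUm)
  linOff <- off[, 1L] + off[, 2L] * nr
  nb <- rpois(1L, nBackground)
  bg <- placePunctaLocal(region, mito, nb, 0, cfg)
  mitoIdx <- which(mito)
  mArea <- length(mitoIdx)
  covered <- matrix(FALSE, nrow(region), ncol(region))
  nCov <- 0L
  for (i in seq_len(nrow(bg))) {
    pix <- (bg$col[i] - 1L) * nr + bg$row[i] + linOff
    gain <- pix[mito[pix] & !covered[pix]]
    covered[gain] <- TRUE
    nCov <- nCov + length(gain)
  }
  rows <- integer(512L); cols <- integer(512L); np <- 0L
  if (mArea > 0L && target > 0) {
    minSep2 <- (cfg$minPunctumSeparationUm / cfg$pixelSizeUm)^2
    stall <- 0L
    while (nCov / mArea < target && np < 500L && stall < 200L) {
      id <- mitoIdx[sample.int(mArea, 1L)]
      r <- (id - 1L) %% nr + 1L; cl <- (id - 1L) %/% nr + 1L
      # honour the separation while the mask is uncrowded, relax once stalled
      if (stall < 25L && minSep2 > 0 && np > 0L &&
          min((rows[seq_len(np)] - r)^2 + (cols[seq_len(np)] - cl)^2) <
            minSep2) {
        stall <- stall + 1L
        next
      }
      pix <- id + linOff
      gain <- pix[mito[pix] & !covered[pix]]
      if (length(gain) == 0L) { stall <- stall + 1L; next }
      deficit <- target * mArea - nCov
      if (length(gain) >= deficit) {
        # final punctum: it would cross the target. Refine among a few
        # candidates toward the gain closest to the remaining deficit, then
        # accept with probability deficit/gain (randomized rounding), which
        # makes the expected covered area equal the target exactly at every
        # coverage level — the injected slope stays unbiased.
        for (alt in 1:10) {
          if (length(gain) <= deficit + 1) break
          id2 <- mitoIdx[sample.int(mArea, 1L)]
          pix2 <- id2 + linOff
          gain2 <- pix2[mito[pix2] & !covered[pix2]]
          if (length(gain2) >= deficit && length(gain2) < length(gain)) {
            gain <- gain2; id <- id2
            r <- (id - 1L) %% nr + 1L; cl <- (id - 1L) %/% nr + 1L
          }
        }
        if (runif(1) < deficit / length(gain)) {
          covered[gain] <- TRUE
          nCov <- nCov + length(gain)
          np <- np + 1L
          rows[np] <- r; cols[np] <- cl
        }
        break
      }
      covered[gain] <- TRUE
      nCov <- nCov + length(gain)
      np <- np + 1L
      rows[np] <- r; cols[np] <- cl
      stall <- 0L
    }
  }
  rows <- rows[seq_len(np)]; cols <- cols[seq_len(np)]
  pts <- rbind(bg,
               data.frame(row = rows, col = cols,
                          isColocalized = rep(TRUE, length(rows))))
  list(puncta = pts,
       achieved = if (mArea > 0L) nCov / mArea else NA_real_)
}

#' Place LC3 puncta with known colocalization ground truth
#'
#' Each punctum is independently colocalized with probability
#' \code{colocFraction}; colocalized centers are sampled uniformly from the
#' mitochondrial mask, the rest uniformly from outside it. Uses the current
#' RNG state.
#'
#' @param mitoMask logical matrix.
#' @param nPuncta number of puncta to place.
#' @param colocFraction fraction in \[0, 1\].
#' @param region logical matrix restricting placement (default: whole frame).
#' @param config a [sceneConfig()] (separation and radius parameters).
#' @return data.frame: row, col, radiusPx, isColocalized.
#' @export
placePuncta <- function(mitoMask, nPuncta, colocFraction,
                        region = NULL, config = sceneConfig()) {
  if (colocFraction < 0 || colocFraction > 1)
    stop("colocFraction must lie in [0, 1]")
  if (is.null(region)) region <- matrix(TRUE, nrow(mitoMask), ncol(mitoMask))
  pts <- placePunctaLocal(region, mitoMask, as.integer(nPuncta),
                          colocFraction, config)
  pts$radiusPx <- config$punctumRadiusUm / config$pixelSizeUm
  pts[, c("row", "col", "radiusPx", "isColocalized")]
}

#' Generate one ground-truthed synthetic scene
#'
#' Lays cells out on a jittered grid, builds a nucleus, mitochondrial network
#' and LC3 puncta per cell, and renders the three channels through the optics
#' model. When \code{targetColocFraction} is given, colocalized puncta are
#' added per cell until the covered fraction of that cell's mitochondrial
#' area reaches the target (the flux time-course mode); otherwise each
#' punctum is colocalized independently with \code{config$colocFraction}.
#'
#' @param config a [sceneConfig()].
#' @param seed integer seed (default \code{config$seed}); the same
#'   (config, seed) reproduces a bit-identical scene and ground truth.
#' @param targetColocFraction \code{NULL}, a single fraction, or one fraction
#'   per cell.
#' @param render if FALSE, skip rendering and return only the ground truth.
#' @return list with \code{stack} (an [ImageStack-class], or NULL) and
#'   \code{truth} (a [SceneGroundTruth-class]).
#' @export
generateScene <- function(config = sceneConfig(), seed = config$seed,
                          targetColocFraction = NULL, render = TRUE) {
  validateSceneConfig(config)
  set.seed(as.integer(seed))
  dims <- as.integer(config$imageSize)
  px <- config$pixelSizeUm
  n <- as.integer(config$nCells)
  cellLabels <- matrix(0L, dims[1L], dims[2L])
  nucleiLabels <- cellLabels
  mitoLabels <- cellLabels
  punctaMask <- matrix(FALSE, dims[1L], dims[2L])
  mitoObjects <- list(); punctaList <- list(); perCell <- list()
  if (n > 0L) {
    g <- ceiling(sqrt(n))
    spacing <- floor(min(dims) / g)
    cellR <- max(4, min(config$cellRadiusUm / px, (spacing - 4) / 2))
    nucR <- min(config$nucleusRadiusUm / px, cellR / 2)
    puncR <- config$punctumRadiusUm / px
    cellOff <- discOffsets(cellR)
    nucOff <- discOffsets(nucR)
    puncOff <- discOffsets(puncR)
    targets <- if (is.null(targetColocFraction)) rep(NA_real_, n)
               else rep_len(targetColocFraction, n)
    half <- as.integer(ceiling(cellR)) + 2L
    mitoRegOff <- discOffsets(cellR - puncR - 2)
    innerOff <- discOffsets(cellR - puncR - 1)
    nMitoLab <- 0L
    for (i in seq_len(n)) {
      gr <- (i - 1L) %/% g; gc <- (i - 1L) %% g
      cr <- as.integer(round((gr + 0.5) * spacing + runif(1, -2, 2)))
      cc <- as.integer(round((gc + 0.5) * spacing + runif(1, -2, 2)))
      cr <- clampRange(cr, half + 1L, dims[1L] - half)
      cc <- clampRange(cc, half + 1L, dims[2L] - half)
      r0 <- cr - half; c0 <- cc - half
      wdim <- c(2L * half + 1L, 2L * half + 1L)
      # mitochondria stay an extra punctum radius away from the cell edge so
      # that every mitochondrial pixel can be covered by a punctum whose disc
      # lies fully inside the cell (keeps high coverage targets reachable)
      region <- matrix(FALSE, wdim[1L], wdim[2L])
      region[stampIndices(half + 1L, half + 1L, mitoRegOff, wdim)] <- TRUE
      # global cell + nucleus
      cellIdx <- stampIndices(cr, cc, cellOff, dims)
      cellLabels[cellIdx] <- i
      nucleiLabels[stampIndices(cr, cc, nucOff, dims)] <- i
      # mitochondria in the local window
      mres <- genMitoLocal(config, region)
      objLocal <- mres$objects
      locIdx <- which(mres$labels > 0L)
      glbIdx <- ((locIdx - 1L) %/% wdim[1L] + c0 - 1L) * dims[1L] +
        ((locIdx - 1L) %% wdim[1L] + r0)
      mitoLabels[glbIdx] <- mres$labels[locIdx] + nMitoLab
      if (nrow(objLocal)) {
        objLocal$label <- objLocal$label + nMitoLab
        objLocal$cell <- i
        mitoObjects[[i]] <- objLocal
        nMitoLab <- nMitoLab + nrow(objLocal)
      }
      # puncta: keep whole discs inside the cell region
      inner <- matrix(FALSE, wdim[1L], wdim[2L])
      inner[stampIndices(half + 1L, half + 1L, innerOff, wdim)] <- TRUE
      mitoLoc <- mres$labels > 0L
      if (is.na(targets[i])) {
        np <- rpois(1L, config$nPunctaPerCell)
        pts <- placePunctaLocal(inner, mitoLoc & inner, np,
                                config$colocFraction, config)
        achieved <- NA_real_
      } else {
        res <- placePunctaToTargetLocal(inner, mitoLoc & inner, targets[i],
                                        config$nPunctaPerCell, config)
        pts <- res$puncta
        achieved <- res$achieved
      }
      if (nrow(pts)) {
        # discs never touch the frame border (centers stay a disc radius
        # inside the cell), so stamp with unchecked linear offsets
        ctr <- (pts$col + c0 - 2L) * dims[1L] + (pts$row + r0 - 1L)
        puncLin <- puncOff[, 1L] + puncOff[, 2L] * dims[1L]
        punctaMask[rep(ctr, each = length(puncLin)) + puncLin] <- TRUE
        pts$areaPx <- length(puncLin)
        pts$row <- pts$row + r0 - 1L
        pts$col <- pts$col + c0 - 1L
        pts$cell <- i
        pts$radiusPx <- puncR
        punctaList[[i]] <- pts[, c("row", "col", "radiusPx",
                                   "isColocalized", "cell", "areaPx")]
      }
      mA <- sum(mitoLoc)
      cA <- sum(punctaMask[glbIdx])
      perCell[[i]] <- data.frame(
        cell = i, mitoAreaPx = mA, colocAreaPx = cA,
        colocAreaFraction = if (mA > 0L) cA / mA else NA_real_,
        targetFraction = targets[i])
    }
  }
  emptyPuncta <- data.frame(row = integer(0), col = integer(0),
                            radiusPx = numeric(0), isColocalized = logical(0),
                            cell = integer(0), areaPx = integer(0))
  truth <- new("SceneGroundTruth",
    cellLabels = cellLabels, nucleiLabels = nucleiLabels,
    mitoLabels = mitoLabels,
    mitoObjects = if (length(mitoObjects))
      do.call(rbind, mitoObjects)[, c("label", "cell", "skeletonLengthUm",
                                      "class", "areaPx")]
      else data.frame(label = integer(0), cell = integer(0),
                      skeletonLengthUm = numeric(0), class = character(0),
                      areaPx = integer(0)),
    puncta = if (length(punctaList)) do.call(rbind, punctaList)
             else emptyPuncta,
    punctaMask = punctaMask,
    perCell = if (length(perCell)) do.call(rbind, perCell)
              else data.frame(cell = integer(0), mitoAreaPx = integer(0),
                              colocAreaPx = integer(0),
                              colocAreaFraction = numeric(0),
                              targetFraction = numeric(0)),
    config = unclass(config))
  rownames(truth@mitoObjects) <- NULL
  rownames(truth@puncta) <- NULL
  stack <- if (render) renderScene(truth, config) else NULL
  list(stack = stack, truth = truth)
}

#' Render a ground-truth scene through the optics model
#'
#' Paints object intensities over the channel backgrounds (red: mitochondria;
#' green: diffuse cytosolic LC3 plus puncta; blue: nuclei), convolves with a
#' Gaussian PSF, then applies Poisson shot noise and additive Gaussian read
#' noise as configured. Pixel values are rounded to integer camera counts.
#' Noise draws come from the current RNG state.
#'
#' @param truth a [SceneGroundTruth-class].
#' @param config the [sceneConfig()] used to build it.
#' @return an [ImageStack-class].
#' @export
renderScene <- function(truth, config) {
  dims <- dim(truth@cellLabels)
  bg <- config$backgroundLevel
  amp <- config$amplitudes
  red <- matrix(bg[["red"]], dims[1L], dims[2L]) +
    amp[["mito"]] * (truth@mitoLabels > 0L)
  green <- matrix(bg[["green"]], dims[1L], dims[2L]) +
    config$cytoLevelGreen * (truth@cellLabels > 0L) +
    amp[["puncta"]] * truth@punctaMask
  blue <- matrix(bg[["blue"]], dims[1L], dims[2L]) +
    amp[["nucleus"]] * (truth@nucleiLabels > 0L)
  sigmaPx <- config$psfSigmaUm / config$pixelSizeUm
  optics <- function(m) {
    if (sigmaPx > 0)
      m <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigmaPx))
    if (config$shotNoise)
      m <- matrix(rpois(length(m), pmax(m, 0)), nrow(m), ncol(m))
    if (config$readNoiseSd > 0)
      m <- m + rnorm(length(m), 0, config$readNoiseSd)
    matrix(round(pmax(m, 0)), nrow(m), ncol(m))
  }
  ImageStack(red = optics(red), green = optics(green), blue = optics(blue),
             pixelSizeUm = config$pixelSizeUm,
             metadata = list(channelRoles = c(red = "mitochondria",
                                              green = "LC3",
                                              blue = "nucleus"),
                             psfSigmaUm = config$psfSigmaUm,
                             shotNoise = config$shotNoise,
                             readNoiseSd = config$readNoiseSd))
}
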