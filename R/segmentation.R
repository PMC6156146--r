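## Segmentation: the computational analogue of the high-content "mask"
## protocol. All tunable thresholds live in segmentationParams() so every
## results file can log the exact parameter block used.

#' Segmentation parameters
#'
#' One block holding every threshold and scale used by the segmentation
#' stage; defaults are logged into results files for provenance.
#'
#' @param nucleusSmoothSigmaPx Gaussian smoothing of the blue channel before
#'   nucleus thresholding.
#' @param nucleusMinAreaPx nuclei smaller than this are discarded.
#' @param cytoSmoothSigmaPx smoothing of the summed cytoplasmic intensity
#'   before cell-region assignment.
#' @param tophatRadiusPx radius of the white top-hat structuring disc used
#'   for background subtraction before mitochondria / puncta thresholding.
#' @param thresholdMethod "halfmax" thresholds each cell at
#'   \code{halfmaxFraction} of its robust foreground amplitude (99th
#'   percentile of the top-hat image); "otsu" uses a per-cell Otsu split.
#' @param halfmaxFraction fraction of the foreground amplitude used by the
#'   "halfmax" method.
#' @param minObjectAmplitude absolute lower bound on any object threshold;
#'   suppresses spurious objects in cells without signal.
#' @param mitoMinAreaPx,punctumMinAreaPx minimum object sizes.
#' @param shortLongCutoffUm skeleton-length cutoff separating "short" from
#'   "long" mitochondria (same default as the scene generator).
#' @param logSigmaPx Laplacian-of-Gaussian scales for punctum detection.
#' @param minOverlapFraction punctum-over-mitochondria overlap fraction
#'   required to call a punctum colocalized.
#' @param pearsonK background-threshold multiplier for the Pearson readout
#'   (threshold = background mean + k x SD).
#' @return a named list of class \code{SegmentationParams}.
#' @export
segmentationParams <- function(nucleusSmoothSigmaPx = 1,
                               nucleusMinAreaPx = 30L,
                               cytoSmoothSigmaPx = 2,
                               tophatRadiusPx = 5L,
                               thresholdMethod = c("halfmax", "otsu"),
                               halfmaxFraction = 0.5,
                               minObjectAmplitude = 20,
                               mitoMinAreaPx = 2L,
                               punctumMinAreaPx = 2L,
                               shortLongCutoffUm = 4,
                               logSigmaPx = 1.4,
                               minOverlapFraction = 0.5,
                               pearsonK = 3) {
  thresholdMethod <- match.arg(thresholdMethod)
  structure(as.list(environment()), class = "SegmentationParams")
}

#' @export
print.SegmentationParams <- function(x, ...) {
  cat("SegmentationParams:",
      paste(names(x), vapply(x, function(v) paste(format(v), collapse = ","),
                             character(1)), sep = "=", collapse = " "), "\n")
  invisible(x)
}

asImg <- function(m) EBImage::Image(m)
asMat <- function(img) {
  m <- EBImage::imageData(img)
  dim(m) <- dim(m)[1:2]
  m
}

smoothMat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  asMat(EBImage::gblur(asImg(m), sigma = sigma))
}

# robust foreground threshold for a vector of (top-hat filtered) intensities
objectThreshold <- function(v, params) {
  thr <- if (params$thresholdMethod == "halfmax") {
    params$halfmaxFraction * quantile(v, 0.99, names = FALSE)
  } else {
    otsuThreshold(v)
  }
  max(thr, params$minObjectAmplitude)
}

#' Detect nuclei in the DAPI channel
#'
#' Smooths, thresholds (Otsu with a robust noise floor), fills holes, and
#' splits touching nuclei by a distance-transform watershed. A blank image
#' yields zero labels.
#'
#' @param blue 2-D intensity matrix.
#' @param params a [segmentationParams()].
#' @return integer label matrix, one label per nucleus.
#' @export
detectNuclei <- function(blue, params = segmentationParams()) {
  if (any(blue < 0)) stop("detectNuclei: negative intensities")
  sm <- smoothMat(blue, params$nucleusSmoothSigmaPx)
  v <- as.vector(sm)
  thr <- max(otsuThreshold(v), median(v) + 5 * mad(v))
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(blue), ncol(blue)))
  mask <- asMat(EBImage::fillHull(asImg(mask))) > 0
  lab <- EBImage::watershed(EBImage::distmap(asImg(mask)), tolerance = 1)
  lab <- asMat(lab)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$nucleusMinAreaPx)
  out <- matrix(0L, nrow(blue), ncol(blue))
  if (length(keep)) {
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    out[pos] <- remap[lab[pos]]
  }
  out
}

#' Assign cytoplasmic cell regions to nuclei
#'
#' Seeded region growing (Voronoi propagation on the smoothed summed
#' cytoplasmic intensity) from nucleus seeds over the cytoplasmic foreground,
#' one region per nucleus. Cells touching the image border are flagged for
#' exclusion from per-cell statistics.
#'
#' @param nuclei integer label matrix from [detectNuclei()].
#' @param red,green intensity matrices (summed as the cytoplasmic signal).
#' @param params a [segmentationParams()].
#' @return integer label matrix with attribute \code{borderCells}: labels
#'   touching the image border.
#' @export
assignCellRegions <- function(nuclei, red, green,
                              params = segmentationParams()) {
  dims <- dim(nuclei)
  if (max(nuclei) == 0L) {
    out <- matrix(0L, dims[1L], dims[2L])
    attr(out, "borderCells") <- integer(0)
    return(out)
  }
  cyto <- smoothMat(red + green, params$cytoSmoothSigmaPx)
  v <- as.vector(cyto)
  if (length(v) > 250000L) v <- v[seq(1L, length(v), length.out = 250000L)]
  # lower cut of a 3-class Otsu on log intensities: the log compresses the
  # bright-organelle tail so the cut lands between background and the
  # diffuse cytoplasmic level rather than inside the cell
  thr <- expm1(otsuThreshold3(log1p(v)))
  fg <- cyto > thr | nuclei > 0L
  fg <- asMat(EBImage::fillHull(asImg(fg))) > 0
  lab <- EBImage::propagate(asImg(cyto), seeds = asImg(nuclei),
                            mask = asImg(fg))
  out <- matrix(as.integer(asMat(lab)), dims[1L], dims[2L])
  border <- sort(unique(c(out[1L, ], out[dims[1L], ],
                          out[, 1L], out[, dims[2L]])))
  attr(out, "borderCells") <- border[border > 0L]
  out
}

# per-cell top-hat threshold -> binary mask over all cells
perCellObjectMask <- function(tophat, cellLab, params) {
  mask <- matrix(FALSE, nrow(tophat), ncol(tophat))
  inCell <- which(cellLab > 0L)
  if (length(inCell) == 0L) return(mask)
  byCell <- split(inCell, cellLab[inCell])
  for (idx in byCell) {
    v <- tophat[idx]
    thr <- objectThreshold(v, params)
    mask[idx[v > thr]] <- TRUE
  }
  mask
}

labelFeatures <- function(lab, cellLab) {
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label = integer(0), cell = integer(0),
                      areaPx = integer(0), row = numeric(0),
                      col = numeric(0)))
  pos <- which(lab > 0L)
  l <- lab[pos]
  r <- (pos - 1L) %% nrow(lab) + 1L
  cl <- (pos - 1L) %/% nrow(lab) + 1L
  area <- tabulate(l, nbins = n)
  rc <- rowsum(cbind(r, cl), l)
  cr <- round(rc[, 1L] / area[as.integer(rownames(rc))])
  cc <- round(rc[, 2L] / area[as.integer(rownames(rc))])
  cellOf <- cellLab[(cc - 1L) * nrow(lab) + cr]
  data.frame(label = as.integer(rownames(rc)), cell = as.integer(cellOf),
             areaPx = area[as.integer(rownames(rc))],
             row = rc[, 1L] / area[as.integer(rownames(rc))],
             col = rc[, 2L] / area[as.integer(rownames(rc))])
}

#' Segment and classify mitochondria
#'
#' Background is removed with a white top-hat, each cell is thresholded
#' independently, connected components become mitochondrial objects, and
#' each object is skeletonized; objects with skeleton length at or above the
#' cutoff are classed "long", the rest "short" (the fragmented phenotype).
#'
#' @param red intensity matrix (mitochondrial channel).
#' @param cellLabels integer cell-region labels.
#' @param params a [segmentationParams()].
#' @param pixelSizeUm micrometers per pixel.
#' @return list: \code{labels} (integer matrix), \code{features}
#'   (data.frame: label, cell, areaPx, areaUm2, skeletonLengthUm, class),
#'   \code{mask} (logical).
#' @export
segmentMitochondria <- function(red, cellLabels,
                                params = segmentationParams(),
                                pixelSizeUm = 0.65) {
  tophat <- asMat(EBImage::whiteTopHat(
    asImg(red), EBImage::makeBrush(2L * params$tophatRadiusPx + 1L, "disc")))
  mask <- perCellObjectMask(tophat, cellLabels, params)
  lab <- asMat(EBImage::bwlabel(asImg(mask)))
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes)) {
    drop <- which(sizes < params$mitoMinAreaPx)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      lab <- asMat(EBImage::reenumerate(asImg(lab)))
    }
  }
  lab <- matrix(as.integer(lab), nrow(red), ncol(red))
  feats <- labelFeatures(lab, cellLabels)
  skel <- thinMask(lab > 0L)
  lens <- skeletonLengthByLabel(skel, lab, pixelSizeUm)
  feats$skeletonLengthUm <- as.numeric(lens[as.character(feats$label)])
  feats$skeletonLengthUm[is.na(feats$skeletonLengthUm)] <- 0
  feats$class <- ifelse(feats$skeletonLengthUm >= params$shortLongCutoffUm,
                        "long", "short")
  feats$areaUm2 <- feats$areaPx * pixelSizeUm^2
  list(labels = lab,
       features = feats[, c("label", "cell", "areaPx", "areaUm2",
                            "skeletonLengthUm", "class")],
       mask = lab > 0L)
}

# Laplacian-of-Gaussian kernel (negated, so blobs give positive peaks)
logKernel <- function(sigma) {
  r <- max(2L, ceiling(3 * sigma))
  g <- expand.grid(x = -r:r, y = -r:r)
  s2 <- sigma^2
  k <- (g$x^2 + g$y^2 - 2 * s2) / (s2^2) * exp(-(g$x^2 + g$y^2) / (2 * s2))
  k <- -matrix(k, 2L * r + 1L, 2L * r + 1L)
  k - mean(k)
}

#' Detect LC3 puncta
#'
#' Band-pass spot detection: the green channel is top-hat filtered (removing
#' the diffuse cytosolic LC3 pool), thresholded per cell, and split into
#' puncta at Laplacian-of-Gaussian maxima; punctum area is measured on the
#' local segmentation around each detection. Puncta are assigned to the cell
#' containing their centroid.
#'
#' @param green intensity matrix (LC3 channel).
#' @param cellLabels integer cell-region labels.
#' @param params a [segmentationParams()].
#' @param pixelSizeUm micrometers per pixel.
#' @return list: \code{labels} (integer matrix), \code{features}
#'   (data.frame: label, cell, row, col, areaPx, areaUm2), \code{mask}.
#' @export
detectPuncta <- function(green, cellLabels, params = segmentationParams(),
                         pixelSizeUm = 0.65) {
  tophat <- asMat(EBImage::whiteTopHat(
    asImg(green), EBImage::makeBrush(2L * params$tophatRadiusPx + 1L,
                                     "disc")))
  mask <- perCellObjectMask(tophat, cellLabels, params)
  comp <- asMat(EBImage::bwlabel(asImg(mask)))
  sizes <- tabulate(comp[comp > 0L])
  if (length(sizes)) {
    drop <- which(sizes < params$punctumMinAreaPx)
    if (length(drop)) {
      comp[comp %in% drop] <- 0L
      mask <- comp > 0L
    }
  }
  out <- matrix(0L, nrow(green), ncol(green))
  if (any(mask)) {
    resp <- asMat(EBImage::filter2(asImg(tophat),
                                   logKernel(params$logSigmaPx)))
    isMax <- resp > shiftMat(resp, 1L, 0L, Inf) &
      resp > shiftMat(resp, -1L, 0L, Inf) &
      resp > shiftMat(resp, 0L, 1L, Inf) &
      resp > shiftMat(resp, 0L, -1L, Inf) &
      resp > shiftMat(resp, 1L, 1L, Inf) &
      resp > shiftMat(resp, 1L, -1L, Inf) &
      resp > shiftMat(resp, -1L, 1L, Inf) &
      resp > shiftMat(resp, -1L, -1L, Inf) & mask
    seeds <- matrix(0L, nrow(green), ncol(green))
    pk <- which(isMax)
    seeds[pk] <- seq_along(pk)
    if (length(pk)) {
      spl <- asMat(EBImage::propagate(asImg(tophat), seeds = asImg(seeds),
                                      mask = asImg(mask)))
      out <- matrix(as.integer(spl), nrow(green), ncol(green))
    }
    # components with no LoG maximum (flat plateaus) are kept whole
    miss <- mask & out == 0L
    if (any(miss)) {
      extra <- asMat(EBImage::bwlabel(asImg(miss)))
      out[miss] <- as.integer(extra[miss]) + max(out)
    }
    out <- matrix(as.integer(asMat(EBImage::reenumerate(asImg(out)))),
                  nrow(green), ncol(green))
  }
  feats <- labelFeatures(out, cellLabels)
  feats$areaUm2 <- feats$areaPx * pixelSizeUm^2
  list(labels = out,
       features = feats[, c("label", "cell", "row", "col", "areaPx",
                            "areaUm2")],
       mask = out > 0L)
}

#' Range threshold mask
#'
#' Retains the pixels of a starting mask whose intensity is at least
#' \code{percent} percent of the way from the in-mask minimum to the in-mask
#' maximum — the imaging-flow-cytometry style "threshold mask" used to
#' exclude dim pixels before counting colocalized puncta. Antitone in
#' \code{percent}: a 70 percent mask is a subset of a 30 percent mask.
#'
#' @param image intensity matrix.
#' @param startMask logical matrix, non-empty.
#' @param percent number in \[0, 100\].
#' @return logical matrix, a subset of \code{startMask}.
#' @export
thresholdMask <- function(image, startMask, percent) {
  if (!any(startMask)) stop("thresholdMask: empty starting mask")
  if (percent < 0 || percent > 100)
    stop("thresholdMask: percent must lie in [0, 100]")
  v <- image[startMask]
  cut <- min(v) + percent / 100 * (max(v) - min(v))
  startMask & image >= cut
}

#' Segment a whole scene
#'
#' Runs nucleus detection, cell-region assignment, mitochondrial
#' segmentation/classification and punctum detection on an [ImageStack-class]
#' and bundles the results.
#'
#' @param stack an [ImageStack-class] with red, green and blue channels.
#' @param params a [segmentationParams()].
#' @return a [LabeledObjects-class].
#' @export
segmentScene <- function(stack, params = segmentationParams()) {
  red <- channelImage(stack, "red")
  green <- channelImage(stack, "green")
  blue <- channelImage(stack, "blue")
  px <- pixelSize(stack)
  nuc <- detectNuclei(blue, params)
  cells <- assignCellRegions(nuc, red, green, params)
  border <- attr(cells, "borderCells")
  mito <- segmentMitochondria(red, cells, params, px)
  punc <- detectPuncta(green, cells, params, px)
  nCell <- max(cells)
  cellTable <- if (nCell > 0L) {
    data.frame(cell = seq_len(nCell),
               areaPx = tabulate(cells[cells > 0L], nbins = nCell),
               border = seq_len(nCell) %in% border)
  } else {
    data.frame(cell = integer(0), areaPx = integer(0), border = logical(0))
  }
  new("LabeledObjects",
      nucleiLabels = nuc, cellLabels = matrix(as.integer(cells), nrow(nuc)),
      mitoLabels = mito$labels, punctaLabels = punc$labels,
      mitoFeatures = mito$features, punctaFeatures = punc$features,
      cellTable = cellTable, pixelSizeUm = px)
}
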