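## Colocalization readouts: object-overlap counts, colocalized area as a
## proportion of mitochondrial area, summed puncta area per cell, and the
## background-thresholded Pearson correlation.

#' Count puncta colocalized with mitochondria
#'
#' A punctum counts as colocalized when at least \code{minOverlapFraction}
#' of its pixel area overlaps the mitochondrial mask.
#'
#' @param punctaLabels integer label matrix of puncta (0 = background).
#' @param mitoMask logical matrix, same shape.
#' @param minOverlapFraction required overlap fraction in (0, 1\].
#' @return integer count; with attribute \code{perPunctum}, the logical
#'   colocalization call per punctum label.
#' @export
countColocalizedPuncta <- function(punctaLabels, mitoMask,
                                   minOverlapFraction = 0.5) {
  if (!identical(dim(punctaLabels), dim(mitoMask)))
    stop("countColocalizedPuncta: shape mismatch")
  if (minOverlapFraction <= 0 || minOverlapFraction > 1)
    stop("countColocalizedPuncta: minOverlapFraction must lie in (0, 1]")
  n <- max(punctaLabels)
  if (n == 0L) {
    out <- 0L
    attr(out, "perPunctum") <- logical(0)
    return(out)
  }
  area <- tabulate(punctaLabels[punctaLabels > 0L], nbins = n)
  overlap <- tabulate(punctaLabels[punctaLabels > 0L & mitoMask], nbins = n)
  call <- area > 0L & overlap / pmax(area, 1L) >= minOverlapFraction
  out <- sum(call)
  attr(out, "perPunctum") <- call
  out
}

#' Colocalized area as a proportion of mitochondrial area
#'
#' Returns |green mask intersect mito mask| / |mito mask| — the readout the
#' flux time courses are fitted on. Undefined (NA with attribute
#' \code{undefined}) when the mitochondrial mask is empty.
#'
#' @param greenMask,mitoMask logical matrices of identical shape.
#' @return fraction in \[0, 1\], or NA flagged undefined.
#' @export
colocalizedAreaFraction <- function(greenMask, mitoMask) {
  if (!identical(dim(greenMask), dim(mitoMask)))
    stop("colocalizedAreaFraction: shape mismatch")
  m <- sum(mitoMask)
  if (m == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- "empty mitochondrial mask"
    return(out)
  }
  sum(greenMask & mitoMask) / m
}

#' Summed LC3 punctum area per cell
#'
#' The autophagosome-load readout: total punctum area per cell in square
#' micrometers. Cells without puncta report 0.
#'
#' @param punctaFeatures data.frame with columns \code{cell} and
#'   \code{areaPx} (one row per punctum).
#' @param cellIds integer vector of cells to report (default: all cells
#'   present in \code{punctaFeatures}).
#' @param pixelSizeUm micrometers per pixel.
#' @return named numeric vector of areas (um^2), one entry per cell.
#' @export
summedPunctaAreaPerCell <- function(punctaFeatures, cellIds = NULL,
                                    pixelSizeUm = 0.65) {
  if (is.null(cellIds))
    cellIds <- sort(unique(punctaFeatures$cell))
  keep <- punctaFeatures$cell %in% cellIds & !is.na(punctaFeatures$cell)
  tot <- rowsum(punctaFeatures$areaPx[keep] * pixelSizeUm^2,
                punctaFeatures$cell[keep])
  out <- setNames(numeric(length(cellIds)), as.character(cellIds))
  out[rownames(tot)] <- tot[, 1L]
  out
}

#' Background-thresholded Pearson correlation
#'
#' For each channel a threshold is set at mean + k x SD of the background
#' pixels; the Pearson product-moment correlation is computed over pixels
#' above threshold in at least one channel (or both, if
#' \code{combine = "intersection"}). Undefined (NA, flagged) when fewer than
#' 10 pixels qualify or a channel has zero variance over them.
#'
#' @param ch1,ch2 intensity matrices of identical shape.
#' @param backgroundRegion logical matrix marking background pixels
#'   (disjoint from the analysis foreground), non-empty.
#' @param k SD multiplier (default 3).
#' @param combine "union" (default) or "intersection" of the two
#'   above-threshold sets.
#' @param foregroundRegion optional logical matrix restricting the analysis
#'   (e.g. one cell).
#' @return Pearson r in \[-1, 1\], or NA with attribute \code{undefined}.
#' @export
pearsonBackgroundThreshold <- function(ch1, ch2, backgroundRegion, k = 3,
                                       combine = c("union", "intersection"),
                                       foregroundRegion = NULL) {
  combine <- match.arg(combine)
  if (!identical(dim(ch1), dim(ch2)))
    stop("pearsonBackgroundThreshold: shape mismatch")
  if (!any(backgroundRegion))
    stop("pearsonBackgroundThreshold: empty background region")
  t1 <- mean(ch1[backgroundRegion]) + k * sd(ch1[backgroundRegion])
  t2 <- mean(ch2[backgroundRegion]) + k * sd(ch2[backgroundRegion])
  sel <- if (combine == "union") ch1 > t1 | ch2 > t2 else ch1 > t1 & ch2 > t2
  if (!is.null(foregroundRegion)) sel <- sel & foregroundRegion
  x <- ch1[sel]; y <- ch2[sel]
  if (length(x) < 10L) {
    out <- NA_real_
    attr(out, "undefined") <- "fewer than 10 qualifying pixels"
    return(out)
  }
  if (var(x) == 0 || var(y) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- "zero variance over qualifying pixels"
    return(out)
  }
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

#' Per-cell mitophagy readouts
#'
#' The primary per-cell measurements on segmented masks: punctum counts,
#' colocalized punctum counts, colocalized area as a percentage of
#' mitochondrial area, summed punctum area, mitochondrial area and
#' morphology counts. Border cells and cells without segmented mitochondria
#' are reported with NA readouts.
#'
#' @param objects a [LabeledObjects-class] from [segmentScene()].
#' @param params a [segmentationParams()].
#' @return data.frame, one row per cell: cell, border, mitoAreaUm2,
#'   nShortMito, nLongMito, nPuncta, nColocPuncta, colocAreaPct,
#'   summedPunctaAreaUm2.
#' @export
perCellReadouts <- function(objects, params = segmentationParams()) {
  cl <- objects@cellLabels
  nCell <- nrow(objects@cellTable)
  px <- objects@pixelSizeUm
  mm <- mitoMask(objects)
  pm <- objects@punctaLabels > 0L
  colocCall <- attr(countColocalizedPuncta(objects@punctaLabels, mm,
                                           params$minOverlapFraction),
                    "perPunctum")
  pf <- objects@punctaFeatures
  out <- objects@cellTable[, c("cell", "border")]
  if (nCell == 0L) {
    out[c("mitoAreaUm2", "colocAreaPct", "summedPunctaAreaUm2")] <- numeric(0)
    out[c("nShortMito", "nLongMito", "nPuncta", "nColocPuncta")] <- integer(0)
    return(out)
  }
  mf <- objects@mitoFeatures
  mitoAreaPx <- tabulate(cl[mm], nbins = nCell)
  colocAreaPx <- tabulate(cl[mm & pm], nbins = nCell)
  countBy <- function(cells) {
    cells <- cells[!is.na(cells) & cells > 0L]
    tabulate(cells, nbins = nCell)
  }
  out$mitoAreaUm2 <- mitoAreaPx * px^2
  out$nShortMito <- countBy(mf$cell[mf$class == "short"])
  out$nLongMito <- countBy(mf$cell[mf$class == "long"])
  out$nPuncta <- countBy(pf$cell)
  out$nColocPuncta <- countBy(pf$cell[colocCall[pf$label]])
  out$colocAreaPct <- ifelse(mitoAreaPx > 0L,
                             100 * colocAreaPx / pmax(mitoAreaPx, 1L),
                             NA_real_)
  out$summedPunctaAreaUm2 <-
    as.numeric(summedPunctaAreaPerCell(pf, seq_len(nCell), px))
  bad <- out$border
  out[bad, c("mitoAreaUm2", "nShortMito", "nLongMito", "nPuncta",
             "nColocPuncta", "colocAreaPct", "summedPunctaAreaUm2")] <- NA
  out
}

#' Per-cell colocalization records at range-threshold-mask variants
#'
#' Mirrors the imaging-flow-cytometry "duplicate analyses": for each cell
#' and each threshold percent (default 30 and 70), the mitochondrial mask is
#' refined with [thresholdMask()] on the red channel and the colocalization
#' readouts are recomputed against the refined mask. The Pearson readout
#' uses the background outside all cells with the k x SD rule.
#'
#' @param objects a [LabeledObjects-class].
#' @param stack the [ImageStack-class] the objects came from.
#' @param thresholdPercents numeric vector of percents.
#' @param params a [segmentationParams()].
#' @return data.frame, one row per cell per threshold percent: cell,
#'   thresholdPercent, nPuncta, nColocPuncta, colocAreaFraction,
#'   summedPunctaAreaUm2, pearsonR, pearsonUndefined.
#' @export
colocalizationRecords <- function(objects, stack,
                                  thresholdPercents = c(30, 70),
                                  params = segmentationParams()) {
  red <- channelImage(stack, "red")
  green <- channelImage(stack, "green")
  cl <- objects@cellLabels
  px <- objects@pixelSizeUm
  mm <- mitoMask(objects)
  pm <- objects@punctaLabels > 0L
  pf <- objects@punctaFeatures
  bgRegion <- cl == 0L
  nCell <- nrow(objects@cellTable)
  sumArea <- summedPunctaAreaPerCell(pf, seq_len(nCell), px)
  rows <- list()
  for (cc in seq_len(nCell)) {
    if (objects@cellTable$border[cc]) next
    inCell <- cl == cc
    mitoC <- mm & inCell
    rP <- pearsonBackgroundThreshold(red, green, bgRegion, k = params$pearsonK,
                                     foregroundRegion = inCell)
    for (pct in thresholdPercents) {
      if (any(mitoC)) {
        refined <- thresholdMask(red, mitoC, pct)
        nColoc <- countColocalizedPuncta(objects@punctaLabels * inCell,
                                         refined, params$minOverlapFraction)
        frac <- colocalizedAreaFraction(pm & inCell, refined)
      } else {
        nColoc <- NA_integer_
        frac <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cc, thresholdPercent = pct,
        nPuncta = sum(!is.na(pf$cell) & pf$cell == cc),
        nColocPuncta = as.integer(nColoc),
        colocAreaFraction = as.numeric(frac),
        summedPunctaAreaUm2 = sumArea[as.character(cc)],
        pearsonR = as.numeric(rP),
        pearsonUndefined = !is.null(attr(rP, "undefined")))
    }
  }
  if (!length(rows))
    return(data.frame(cell = integer(0), thresholdPercent = numeric(0),
                      nPuncta = integer(0), nColocPuncta = integer(0),
                      colocAreaFraction = numeric(0),
                      summedPunctaAreaUm2 = numeric(0),
                      pearsonR = numeric(0), pearsonUndefined = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
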