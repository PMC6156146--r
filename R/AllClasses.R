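#' @import methods
NULL

#' ImageStack: registered multi-channel fluorescence image
#'
#' Container for a registered set of 2-D intensity grids (red = mitochondria,
#' green = LC3, blue = nucleus) sharing one pixel grid, plus physical pixel
#' size and free-form acquisition metadata.
#'
#' @slot channels named list of numeric matrices, identical dimensions;
#'   names among "red", "green", "blue".
#' @slot pixelSizeUm physical pixel size, micrometers per pixel.
#' @slot metadata list of acquisition descriptors.
#' @export
setClass("ImageStack",
  representation(channels = "list", pixelSizeUm = "numeric",
                 metadata = "list"),
  prototype(channels = list(), pixelSizeUm = 0.65, metadata = list()))

setValidity("ImageStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel required")
  if (is.null(names(ch)) || !all(names(ch) %in% c("red", "green", "blue")))
    return("channels must be named among 'red', 'green', 'blue'")
  dims <- lapply(ch, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    return("all channels must have identical dimensions")
  if (any(vapply(ch, function(m) any(m < 0), logical(1))))
    return("intensities must be non-negative")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  TRUE
})

#' Construct an ImageStack
#'
#' @param red,green,blue numeric matrices (any may be omitted).
#' @param pixelSizeUm micrometers per pixel.
#' @param metadata list of acquisition descriptors.
#' @return an [ImageStack-class] object.
#' @export
ImageStack <- function(red = NULL, green = NULL, blue = NULL,
                       pixelSizeUm = 0.65, metadata = list()) {
  ch <- Filter(Negate(is.null),
               list(red = red, green = green, blue = blue))
  new("ImageStack", channels = ch, pixelSizeUm = pixelSizeUm,
      metadata = metadata)
}

#' SceneGroundTruth: generator-side truth for a synthetic scene
#'
#' Everything the synthetic generator knows about a scene before optics and
#' noise are applied; the oracle every segmentation and colocalization result
#' is checked against.
#'
#' @slot cellLabels integer matrix, one label per cell region.
#' @slot nucleiLabels integer matrix of nucleus discs (same labels as cells).
#' @slot mitoLabels integer matrix, one label per mitochondrial object.
#' @slot mitoObjects data.frame: label, cell, skeletonLengthUm, class
#'   ("short"/"long"), areaPx.
#' @slot puncta data.frame: row, col, radiusPx, isColocalized, cell, areaPx.
#' @slot punctaMask logical matrix, union of all punctum discs.
#' @slot perCell data.frame of per-cell truth: cell, mitoAreaPx, colocAreaPx,
#'   colocAreaFraction, targetFraction.
#' @slot config the SceneConfig used.
#' @export
setClass("SceneGroundTruth",
  representation(cellLabels = "matrix", nucleiLabels = "matrix",
                 mitoLabels = "matrix", mitoObjects = "data.frame",
                 puncta = "data.frame", punctaMask = "matrix",
                 perCell = "data.frame", config = "list"))

#' LabeledObjects: segmentation output for one scene
#'
#' @slot nucleiLabels,cellLabels,mitoLabels,punctaLabels integer label
#'   matrices (0 = background).
#' @slot mitoFeatures data.frame: label, cell, areaPx, areaUm2,
#'   skeletonLengthUm, class.
#' @slot punctaFeatures data.frame: label, cell, row, col, areaPx, areaUm2.
#' @slot cellTable data.frame: cell, areaPx, border (touches image edge).
#' @slot pixelSizeUm micrometers per pixel.
#' @export
setClass("LabeledObjects",
  representation(nucleiLabels = "matrix", cellLabels = "matrix",
                 mitoLabels = "matrix", punctaLabels = "matrix",
                 mitoFeatures = "data.frame", punctaFeatures = "data.frame",
                 cellTable = "data.frame", pixelSizeUm = "numeric"))

setValidity("LabeledObjects", function(object) {
  for (s in c("nucleiLabels", "cellLabels", "mitoLabels", "punctaLabels")) {
    m <- slot(object, s)
    if (any(m < 0)) return(sprintf("%s: labels must be non-negative", s))
  }
  cls <- object@mitoFeatures$class
  if (length(cls) && !all(cls %in% c("short", "long")))
    return("mito classes must partition into 'short'/'long'")
  TRUE
})

#' FluxFit: flux estimate from an inhibitor time course
#'
#' Ordinary-least-squares fit of a per-cell mitophagy readout on time under
#' lysosomal inhibition; the slope is the mitophagic (or autophagic) flux.
#'
#' @slot genotype label of the fitted group.
#' @slot slope readout units per hour.
#' @slot slopeSEM standard error of the slope.
#' @slot intercept readout units at t = 0.
#' @slot pValue regression p-value for the slope.
#' @slot nCells number of per-cell observations.
#' @slot timepointsH distinct time points (hours).
#' @slot degenerate TRUE when the fit had zero residual variance.
#' @export
setClass("FluxFit",
  representation(genotype = "character", slope = "numeric",
                 slopeSEM = "numeric", intercept = "numeric",
                 pValue = "numeric", nCells = "integer",
                 timepointsH = "numeric", degenerate = "logical"))

setValidity("FluxFit", function(object) {
  if (length(object@slopeSEM) && !is.na(object@slopeSEM) &&
      object@slopeSEM < 0) return("slopeSEM must be >= 0")
  if (object@nCells <= 0L) return("nCells must be positive")
  p <- object@pValue
  if (length(p) && !is.na(p) && (p < 0 || p > 1))
    return("pValue must lie in [0, 1]")
  TRUE
})
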