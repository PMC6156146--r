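#' @describeIn ImageStack extract one channel as a matrix
#' @param x,which see generic.
#' @export
setMethod("channelImage", "ImageStack", function(x, which) {
  if (!which %in% names(x@channels))
    stop(sprintf("channel '%s' missing from stack", which))
  x@channels[[which]]
})

#' @describeIn ImageStack pixel size in micrometers
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSizeUm)

#' @describeIn LabeledObjects pixel size in micrometers
#' @export
setMethod("pixelSize", "LabeledObjects", function(x) x@pixelSizeUm)

setMethod("dim", "ImageStack", function(x) dim(x@channels[[1L]]))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object)
  cat(sprintf("ImageStack: %d x %d px (%.3g um/px), channels: %s\n",
              d[1L], d[2L], object@pixelSizeUm,
              paste(names(object@channels), collapse = ", ")))
})

#' @describeIn SceneGroundTruth binary union of mitochondrial objects
#' @param x object.
#' @export
setMethod("mitoMask", "SceneGroundTruth", function(x) x@mitoLabels > 0L)

#' @describeIn LabeledObjects binary union of segmented mitochondria
#' @export
setMethod("mitoMask", "LabeledObjects", function(x) x@mitoLabels > 0L)

#' @describeIn SceneGroundTruth cell-region labels
#' @export
setMethod("cellLabels", "SceneGroundTruth", function(x) x@cellLabels)

#' @describeIn LabeledObjects cell-region labels
#' @export
setMethod("cellLabels", "LabeledObjects", function(x) x@cellLabels)

#' @describeIn SceneGroundTruth ground-truth puncta table
#' @export
setMethod("puncta", "SceneGroundTruth", function(x) x@puncta)

#' @describeIn LabeledObjects detected puncta table
#' @export
setMethod("puncta", "LabeledObjects", function(x) x@punctaFeatures)

setMethod("show", "SceneGroundTruth", function(object) {
  cat(sprintf(
    "SceneGroundTruth: %d cells, %d mito objects (%d short / %d long), %d puncta (%d colocalized)\n",
    max(object@cellLabels), nrow(object@mitoObjects),
    sum(object@mitoObjects$class == "short"),
    sum(object@mitoObjects$class == "long"),
    nrow(object@puncta), sum(object@puncta$isColocalized)))
})

setMethod("show", "LabeledObjects", function(object) {
  cat(sprintf(
    "LabeledObjects: %d nuclei, %d cells (%d border), %d mito objects, %d puncta\n",
    max(object@nucleiLabels), nrow(object@cellTable),
    sum(object@cellTable$border), nrow(object@mitoFeatures),
    nrow(object@punctaFeatures)))
})

setMethod("show", "FluxFit", function(object) {
  cat(sprintf(
    "FluxFit [%s]: slope %.3f +/- %.3f (SEM) per h, intercept %.3f, p = %.3g, n = %d cells over t = {%s} h%s\n",
    object@genotype, object@slope, object@slopeSEM, object@intercept,
    object@pValue, object@nCells,
    paste(object@timepointsH, collapse = ", "),
    if (object@degenerate) " [degenerate fit]" else ""))
})
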