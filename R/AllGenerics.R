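#' Extract a channel from an ImageStack
#' @param x an ImageStack.
#' @param which "red", "green" or "blue".
#' @return numeric intensity matrix.
#' @export
setGeneric("channelImage", function(x, which) standardGeneric("channelImage"))

#' Physical pixel size in micrometers
#' @param x an object carrying pixel-size metadata.
#' @return micrometers per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Binary mitochondrial mask
#' @param x a SceneGroundTruth or LabeledObjects.
#' @return logical matrix.
#' @export
setGeneric("mitoMask", function(x) standardGeneric("mitoMask"))

#' Cell-region label matrix
#' @param x a SceneGroundTruth or LabeledObjects.
#' @return integer matrix of cell labels.
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' Puncta table
#' @param x a SceneGroundTruth or LabeledObjects.
#' @return data.frame of puncta.
#' @export
setGeneric("puncta", function(x) standardGeneric("puncta"))
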