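# Shared fixtures: small, fast scene configurations built in code.

# noiseless, blur-free optics: rendered channels equal painted intensities
noiselessConfig <- function(...) {
  sceneConfig(psfSigmaUm = 0, shotNoise = FALSE, readNoiseSd = 0, ...)
}

smallScene <- function(seed = 1L, ...) {
  generateScene(noiselessConfig(nCells = 4L, imageSize = c(140L, 140L),
                                seed = seed, ...))
}

# map segmentation cell labels onto ground-truth cell ids via nucleus centers
matchCellLabels <- function(objects, truth) {
  segNuc <- objects@nucleiLabels
  map <- integer(max(segNuc))
  for (lab in seq_len(max(segNuc))) {
    px <- which(segNuc == lab)
    if (!length(px)) next
    truthIds <- truth@cellLabels[px]
    truthIds <- truthIds[truthIds > 0L]
    if (length(truthIds)) map[lab] <- as.integer(names(which.max(
      table(truthIds))))
  }
  map
}
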