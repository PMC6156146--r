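#' Configuration for a synthetic fluorescence scene
#'
#' Defines the geometry, optics and noise of one simulated field of view:
#' cells on a jittered grid, each with a nucleus, a mitochondrial network of
#' tunable fragmentation (red channel), a diffuse cytosolic LC3 pool plus
#' LC3 puncta (green channel), and a DAPI nucleus (blue channel). Objects are
#' painted at configurable amplitudes, convolved with a Gaussian PSF, then
#' subjected to Poisson shot noise and additive Gaussian read noise.
#'
#' Defaults emulate a 20x high-content acquisition of mouse embryonic
#' fibroblasts: 0.65 um pixels, ~14 um cell radius, ~50 um of mitochondrial
#' skeleton per cell, diffraction-limited puncta of ~1 um radius.
#'
#' @param imageSize c(rows, cols) in pixels.
#' @param pixelSizeUm micrometers per pixel.
#' @param nCells number of cells, laid out on a jittered grid.
#' @param cellRadiusUm cell-region radius.
#' @param nucleusRadiusUm nucleus radius.
#' @param mitoTotalLengthUm nominal total mitochondrial skeleton length per
#'   cell.
#' @param mitoFragmentation fraction in \[0, 1\]: 0 = one long tubule per
#'   cell, 1 = all short fragments; intermediate values mix the two with this
#'   probability of "short" per object.
#' @param mitoFragmentLengthUm mean skeleton length of a short fragment.
#' @param mitoWidthPx painted tubule width in pixels.
#' @param shortLongCutoffUm skeleton-length cutoff separating "short" from
#'   "long" objects; the segmentation default uses the same value so classes
#'   are recoverable.
#' @param nPunctaPerCell expected LC3 punctum count per cell.
#' @param punctumRadiusUm punctum disc radius.
#' @param colocFraction fraction in \[0, 1\] of puncta whose centers are
#'   placed inside the mitochondrial mask.
#' @param minPunctumSeparationUm minimum center-to-center distance between
#'   puncta; the default keeps punctum discs a full pixel apart so distinct
#'   ground-truth puncta stay distinct image components (the coverage-target
#'   mode relaxes it when a cell saturates).
#' @param backgroundLevel named intensity offsets per channel (red, green,
#'   blue).
#' @param cytoLevelGreen amplitude of the diffuse cytosolic LC3 pool painted
#'   over the whole cell in the green channel.
#' @param amplitudes named object amplitudes: mito, puncta, nucleus.
#' @param psfSigmaUm Gaussian PSF sigma (0 disables blur).
#' @param shotNoise logical: apply Poisson shot noise.
#' @param readNoiseSd additive Gaussian read-noise SD (0 disables).
#' @param seed integer master seed; (config, seed) reproduces a bit-identical
#'   scene.
#' @return a validated object of class \code{SceneConfig} (a named list).
#' @export
sceneConfig <- function(imageSize = c(480L, 480L),
                        pixelSizeUm = 0.65,
                        nCells = 25L,
                        cellRadiusUm = 14,
                        nucleusRadiusUm = 4.5,
                        mitoTotalLengthUm = 50,
                        mitoFragmentation = 0.5,
                        mitoFragmentLengthUm = 2.5,
                        mitoWidthPx = 3L,
                        shortLongCutoffUm = 4,
                        nPunctaPerCell = 12,
                        punctumRadiusUm = 1.0,
                        colocFraction = 0.2,
                        minPunctumSeparationUm = 2.8,
                        backgroundLevel = c(red = 10, green = 10, blue = 10),
                        cytoLevelGreen = 25,
                        amplitudes = c(mito = 150, puncta = 150,
                                       nucleus = 120),
                        psfSigmaUm = 0.3,
                        shotNoise = TRUE,
                        readNoiseSd = 2,
                        seed = 1L) {
  cfg <- structure(as.list(environment()), class = "SceneConfig")
  validateSceneConfig(cfg)
  cfg
}

validateSceneConfig <- function(cfg) {
  stopifnot(length(cfg$imageSize) == 2L, all(cfg$imageSize > 0))
  if (cfg$pixelSizeUm <= 0) stop("pixelSizeUm must be > 0")
  for (f in c("mitoFragmentation", "colocFraction")) {
    v <- cfg[[f]]
    if (v < 0 || v > 1) stop(sprintf("%s must lie in [0, 1]", f))
  }
  if (cfg$nCells < 0) stop("nCells must be >= 0")
  stopifnot(all(c("red", "green", "blue") %in% names(cfg$backgroundLevel)),
            all(c("mito", "puncta", "nucleus") %in% names(cfg$amplitudes)))
  if (cfg$psfSigmaUm < 0 || cfg$readNoiseSd < 0)
    stop("psfSigmaUm and readNoiseSd must be >= 0")
  invisible(cfg)
}

#' @export
print.SceneConfig <- function(x, ...) {
  cat(sprintf(
    "SceneConfig: %dx%d px @ %.3g um/px, %d cells, fragmentation %.2f, %g puncta/cell (coloc %.2f), PSF %.2f um, shot noise %s\n",
    x$imageSize[1L], x$imageSize[2L], x$pixelSizeUm, x$nCells,
    x$mitoFragmentation, x$nPunctaPerCell, x$colocFraction, x$psfSigmaUm,
    if (x$shotNoise) "on" else "off"))
  invisible(x)
}

#' Configuration for a lysosomal-inhibitor time course
#'
#' Describes a simulated flux experiment: lysosomal inhibitors (E64d /
#' pepstatin A analogue) block autophagosome turnover, so the colocalized
#' (mitophagosome) readout accumulates linearly in time with a
#' genotype-specific slope. Readout units are percentage points of
#' mitochondrial area (0-100 scale), so a slope of 1.96 means the colocalized
#' proportion of mitochondrial area grows by 1.96 points per hour.
#'
#' Cell-to-cell heterogeneity follows a gamma distribution with constant
#' coefficient of variation around the time-dependent mean, so the
#' per-timepoint ground-truth mean equals \code{baselinePercent + slope * t}
#' exactly and values never leave \[0, 100\].
#'
#' @param timepointsH strictly increasing sampling times in hours.
#' @param genotypeSlopes named numeric: true readout increase per hour for
#'   each genotype (percentage points of mitochondrial area per hour).
#' @param baselinePercent readout mean at t = 0 (percent).
#' @param nCellsPerTimepoint cells measured per timepoint per genotype.
#' @param cellCV coefficient of variation of the per-cell gamma
#'   heterogeneity.
#' @param seed integer master seed.
#' @return a validated object of class \code{TimeCourseConfig}.
#' @export
timeCourseConfig <- function(timepointsH = c(0, 6, 24),
                             genotypeSlopes = c(wildtype = 0.73,
                                                opa1 = 1.96),
                             baselinePercent = 5,
                             nCellsPerTimepoint = 500L,
                             cellCV = 0.25,
                             seed = 1L) {
  cfg <- structure(as.list(environment()), class = "TimeCourseConfig")
  validateTimeCourseConfig(cfg)
  cfg
}

validateTimeCourseConfig <- function(cfg) {
  t <- cfg$timepointsH
  if (length(t) < 1L || any(diff(t) <= 0))
    stop("timepointsH must be strictly increasing")
  if (is.null(names(cfg$genotypeSlopes)))
    stop("genotypeSlopes must be a named vector")
  top <- (cfg$baselinePercent + cfg$genotypeSlopes * max(t)) / 100
  if (any(top < 0 | top > 1) || cfg$baselinePercent < 0)
    stop("baseline + slope * max(t) must stay within [0, 100] percent")
  if (cfg$nCellsPerTimepoint < 1L) stop("nCellsPerTimepoint must be >= 1")
  if (cfg$cellCV < 0) stop("cellCV must be >= 0")
  invisible(cfg)
}

#' @export
print.TimeCourseConfig <- function(x, ...) {
  cat(sprintf(
    "TimeCourseConfig: t = {%s} h, baseline %.3g%%, %d cells/timepoint, CV %.2f\n",
    paste(x$timepointsH, collapse = ", "), x$baselinePercent,
    x$nCellsPerTimepoint, x$cellCV))
  for (g in names(x$genotypeSlopes))
    cat(sprintf("  %s: %.3g %%-points of mito area per hour\n",
                g, x$genotypeSlopes[[g]]))
  invisible(x)
}
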