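## Lysosomal-inhibitor time courses with injected mitophagosome-accumulation
## slopes, and the parameter-recovery study used for validation.

# per-cell ground-truth coverage targets for one timepoint: gamma
# heterogeneity with constant CV around the time-dependent mean, so the
# population mean equals the target exactly and values stay positive
drawCellTargets <- function(n, meanFrac, cv) {
  if (cv <= 0) return(rep(meanFrac, n))
  shape <- 1 / cv^2
  pmin(rgamma(n, shape = shape, rate = shape / meanFrac), 0.98)
}

#' Generate a lysosomal-inhibitor time course
#'
#' At each timepoint t the mean ground-truth colocalized-area fraction is
#' \code{(baselinePercent + slope * t) / 100}; per-cell targets add
#' gamma-distributed cell-to-cell heterogeneity (constant CV), and the scene
#' generator places colocalized puncta to meet each cell's target. With
#' \code{mode = "values"} no images are built and the per-cell ground-truth
#' readouts themselves are returned — the fast path for statistical
#' calibration studies.
#'
#' @param tc a [timeCourseConfig()].
#' @param scene a [sceneConfig()] describing each field of view.
#' @param genotype which entry of \code{tc$genotypeSlopes} to simulate
#'   (default: all).
#' @param mode "images" (render + ground truth) or "values" (ground-truth
#'   per-cell readouts only).
#' @param seed master seed (default \code{tc$seed}).
#' @return For \code{mode = "values"}: a data.frame with genotype, timeH,
#'   cell, value (percent of mitochondrial area). For \code{mode =
#'   "images"}: a list of records, each with genotype, timeH, sceneIndex,
#'   stack, truth.
#' @export
generateTimeCourse <- function(tc = timeCourseConfig(),
                               scene = sceneConfig(),
                               genotype = NULL,
                               mode = c("images", "values"),
                               seed = tc$seed) {
  mode <- match.arg(mode)
  validateTimeCourseConfig(tc)
  genos <- if (is.null(genotype)) names(tc$genotypeSlopes) else genotype
  stopifnot(all(genos %in% names(tc$genotypeSlopes)))
  if (mode == "values") {
    set.seed(as.integer(seed))
    rows <- list()
    for (g in genos) {
      for (t in tc$timepointsH) {
        mu <- (tc$baselinePercent + tc$genotypeSlopes[[g]] * t) / 100
        v <- drawCellTargets(tc$nCellsPerTimepoint, mu, tc$cellCV)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, timeH = t,
          cell = seq_len(tc$nCellsPerTimepoint), value = 100 * v)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  nScenes <- ceiling(tc$nCellsPerTimepoint / scene$nCells)
  records <- list()
  idx <- 0L
  for (g in genos) {
    for (t in tc$timepointsH) {
      mu <- (tc$baselinePercent + tc$genotypeSlopes[[g]] * t) / 100
      for (s in seq_len(nScenes)) {
        idx <- idx + 1L
        sSeed <- deriveSeed(seed, idx)
        set.seed(sSeed)
        targets <- drawCellTargets(scene$nCells, mu, tc$cellCV)
        sc <- generateScene(scene, seed = sSeed,
                            targetColocFraction = targets)
        records[[idx]] <- list(genotype = g, timeH = t, sceneIndex = s,
                               stack = sc$stack, truth = sc$truth)
      }
    }
  }
  records
}

#' Analyze a generated time course through the pipeline
#'
#' Segments every scene of an image-mode time course and extracts the
#' per-cell colocalized-area readout (percent of mitochondrial area).
#'
#' @param records output of [generateTimeCourse()] with
#'   \code{mode = "images"}.
#' @param params a [segmentationParams()].
#' @return data.frame: genotype, timeH, sceneIndex, cell, value (measured),
#'   truthValue (generator ground truth per scene mean is in
#'   \code{truth@perCell}).
#' @export
analyzeTimeCourse <- function(records, params = segmentationParams()) {
  rows <- lapply(records, function(rec) {
    obj <- segmentScene(rec$stack, params)
    rd <- perCellReadouts(obj, params)
    keep <- !rd$border & is.finite(rd$colocAreaPct)
    if (!any(keep)) return(NULL)
    data.frame(genotype = rec$genotype, timeH = rec$timeH,
               sceneIndex = rec$sceneIndex, cell = rd$cell[keep],
               value = rd$colocAreaPct[keep])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flux-slope parameter-recovery study
#'
#' The validation backbone: simulates replicate inhibitor time courses with
#' a known injected accumulation slope, runs the full pipeline
#' (scene generation, rendering, segmentation, colocalization, OLS fit) on
#' each, and returns the recovered slope per replicate.
#'
#' @param injectedSlope percentage points of mitochondrial area per hour.
#' @param nReplicates number of replicate time courses.
#' @param tc a [timeCourseConfig()] (its genotypeSlopes are replaced by the
#'   injected slope).
#' @param scene a [sceneConfig()].
#' @param params a [segmentationParams()].
#' @param seed master seed; replicate r uses a derived sub-seed.
#' @param mode "images" (full pipeline) or "values" (ground-truth readouts,
#'   no imaging) — the latter isolates the statistical stage.
#' @return data.frame: replicate, slope, slopeSEM, pValue, nCells.
#' @export
fluxRecoveryStudy <- function(injectedSlope, nReplicates = 20L,
                              tc = timeCourseConfig(),
                              scene = sceneConfig(nCells = 100L,
                                                  imageSize = c(480L, 480L)),
                              params = segmentationParams(),
                              seed = 1L,
                              mode = c("images", "values")) {
  mode <- match.arg(mode)
  tc$genotypeSlopes <- c(injected = injectedSlope)
  validateTimeCourseConfig(tc)
  out <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    repSeed <- deriveSeed(seed, 1000L + r)
    if (mode == "images") {
      recs <- generateTimeCourse(tc, scene, genotype = "injected",
                                 mode = "images", seed = repSeed)
      df <- analyzeTimeCourse(recs, params)
    } else {
      df <- generateTimeCourse(tc, scene, genotype = "injected",
                               mode = "values", seed = repSeed)
    }
    fit <- fitFluxSlope(df$timeH, df$value, "injected")
    out[[r]] <- data.frame(replicate = r, slope = fit@slope,
                           slopeSEM = fit@slopeSEM, pValue = fit@pValue,
                           nCells = fit@nCells)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
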