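## End-to-end orchestration: run configuration, plate simulation, scene I/O
## (multi-page TIFF + JSON ground-truth sidecars + CSV manifests), and the
## reproducible pipeline run chaining generator -> segmentation ->
## colocalization -> flux statistics.

#' Run configuration
#'
#' Bundles every parameter block of a pipeline run under one object whose
#' hash is embedded in all outputs.
#'
#' @param outputDir directory for results.
#' @param seed master seed; all randomness derives from it.
#' @param scene a [sceneConfig()].
#' @param timecourse a [timeCourseConfig()].
#' @param segmentation a [segmentationParams()].
#' @param thresholdPercents range-threshold-mask percents reported side by
#'   side.
#' @param experiment simulated plate design: "inhibitor_panel" (control /
#'   chloroquine / CCCP / galactose colocalization shifts at one timepoint),
#'   "flux_timecourse" (genotypes x inhibitor timepoints), or
#'   "single_cell_tiles" (one-cell fields, imaging-flow-cytometry style).
#' @param wellsPerCondition simulated wells per condition.
#' @param conditionColoc named colocalization fractions for the
#'   inhibitor_panel design.
#' @return a named list of class \code{RunConfig}.
#' @export
runConfig <- function(outputDir = "mitoflux-results",
                      seed = 1L,
                      scene = sceneConfig(),
                      timecourse = timeCourseConfig(),
                      segmentation = segmentationParams(),
                      thresholdPercents = c(30, 70),
                      experiment = c("inhibitor_panel", "flux_timecourse",
                                     "single_cell_tiles"),
                      wellsPerCondition = 2L,
                      conditionColoc = c(control = 0.08, chloroquine = 0.25,
                                         cccp = 0.22, galactose = 0.12)) {
  experiment <- match.arg(experiment)
  structure(as.list(environment()), class = "RunConfig")
}

#' @export
print.RunConfig <- function(x, ...) {
  cat(sprintf("RunConfig [%s]: experiment %s, seed %d, output %s\n",
              analysisHash(x), x$experiment, x$seed, x$outputDir))
  invisible(x)
}

# hash of the analysis-relevant configuration: paths excluded so runs into
# different directories with identical parameters share a hash
analysisHash <- function(config) {
  configHash(unclass(config)[setdiff(names(config), "outputDir")])
}

#' Write a scene as multi-page TIFF plus ground-truth sidecar
#'
#' Pages are ordered red, green, blue; intensities are stored as 16-bit
#' counts. The JSON sidecar carries the object tables and per-cell truth
#' (masks are reproducible from the config and seed).
#'
#' @param stack an [ImageStack-class].
#' @param truth a [SceneGroundTruth-class] or NULL.
#' @param file TIFF path; the sidecar replaces the extension with
#'   \code{.json}.
#' @return \code{file}, invisibly.
#' @export
writeScene <- function(stack, truth = NULL, file) {
  pages <- lapply(c("red", "green", "blue"), function(ch)
    pmin(channelImage(stack, ch), 65535) / 65535)
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  if (!is.null(truth)) {
    side <- sub("\\.tiff?$", ".json", file, ignore.case = TRUE)
    jsonlite::write_json(
      list(pixelSizeUm = stack@pixelSizeUm,
           config = truth@config,
           mitoObjects = truth@mitoObjects,
           puncta = truth@puncta,
           perCell = truth@perCell),
      side, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(file)
}

#' Read a scene written by [writeScene()]
#'
#' @param file TIFF path (pages red, green, blue).
#' @param pixelSizeUm pixel size; when a JSON sidecar exists its recorded
#'   value is used.
#' @return an [ImageStack-class]; if the sidecar exists, its tables are
#'   attached as attribute \code{truth}.
#' @export
readScene <- function(file, pixelSizeUm = 0.65) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (length(pages) < 3L)
    stop(sprintf("readScene: %s: expected 3 channel pages, found %d",
                 file, length(pages)))
  side <- sub("\\.tiff?$", ".json", file, ignore.case = TRUE)
  truth <- NULL
  if (file.exists(side)) {
    truth <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(truth$pixelSizeUm)) pixelSizeUm <- truth$pixelSizeUm
  }
  toMat <- function(p) round(p * 65535)
  stack <- ImageStack(red = toMat(pages[[1L]]), green = toMat(pages[[2L]]),
                      blue = toMat(pages[[3L]]), pixelSizeUm = pixelSizeUm)
  attr(stack, "truth") <- truth
  stack
}

#' Simulate an experiment plate
#'
#' Writes a self-contained synthetic plate: one multi-page TIFF + JSON
#' ground-truth sidecar per well/field, and a CSV manifest (well, genotype,
#' treatment, timepoint, file). Designs: an inhibitor panel (colocalization
#' shifts under chloroquine / CCCP / galactose), a genotype x timepoint flux
#' time course under E64d/pepstatin-style inhibition, or single-cell tiles.
#'
#' @param config a [runConfig()].
#' @param dir output directory (default \code{config$outputDir}).
#' @return the manifest data.frame, invisibly; written as
#'   \code{manifest.csv} in \code{dir}.
#' @export
simulateExperiment <- function(config = runConfig(), dir = config$outputDir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scene <- config$scene
  rows <- list()
  addWell <- function(well, genotype, treatment, timeH, sc) {
    f <- file.path(dir, sprintf("%s.tiff", well))
    writeScene(sc$stack, sc$truth, f)
    rows[[length(rows) + 1L]] <<- data.frame(
      well = well, genotype = genotype, treatment = treatment,
      timepointH = timeH, file = basename(f))
  }
  idx <- 0L
  if (config$wellsPerCondition > 0L) {
    if (config$experiment == "inhibitor_panel") {
      for (cond in names(config$conditionColoc)) {
        for (w in seq_len(config$wellsPerCondition)) {
          idx <- idx + 1L
          cfg <- scene
          cfg$colocFraction <- config$conditionColoc[[cond]]
          sc <- generateScene(cfg, seed = deriveSeed(config$seed, idx))
          addWell(sprintf("%s_w%02d", cond, w), "wildtype", cond, 0, sc)
        }
      }
    } else if (config$experiment == "flux_timecourse") {
      tc <- config$timecourse
      for (g in names(tc$genotypeSlopes)) {
        for (t in tc$timepointsH) {
          mu <- (tc$baselinePercent + tc$genotypeSlopes[[g]] * t) / 100
          for (w in seq_len(config$wellsPerCondition)) {
            idx <- idx + 1L
            sSeed <- deriveSeed(config$seed, idx)
            set.seed(sSeed)
            targets <- drawCellTargets(scene$nCells, mu, tc$cellCV)
            sc <- generateScene(scene, seed = sSeed,
                                targetColocFraction = targets)
            addWell(sprintf("%s_t%02dh_w%02d", g, t, w), g,
                    "E64d_pepstatinA", t, sc)
          }
        }
      }
    } else {  # single_cell_tiles
      cfg <- scene
      cfg$nCells <- 1L
      cfg$imageSize <- c(64L, 64L)
      cfg$cellRadiusUm <- min(cfg$cellRadiusUm, 9)
      for (w in seq_len(config$wellsPerCondition)) {
        idx <- idx + 1L
        sc <- generateScene(cfg, seed = deriveSeed(config$seed, idx))
        addWell(sprintf("tile_%03d", w), "wildtype", "none", 0, sc)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(well = character(0), genotype = character(0),
               treatment = character(0), timepointH = numeric(0),
               file = character(0))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

emptyPerCellCsv <- function() {
  data.frame(well = character(0), genotype = character(0),
             treatment = character(0), timepointH = numeric(0),
             cell = integer(0), thresholdPercent = numeric(0),
             nPuncta = integer(0), nColocPuncta = integer(0),
             colocAreaFraction = numeric(0), colocAreaPct = numeric(0),
             summedPunctaAreaUm2 = numeric(0), mitoAreaUm2 = numeric(0),
             nShortMito = integer(0), nLongMito = integer(0),
             pearsonR = numeric(0), configHash = character(0))
}

#' Run the full analysis pipeline over a plate
#'
#' Reads the manifest, segments every stack, computes per-cell readouts and
#' range-threshold-mask colocalization records, aggregates per well, and
#' fits the flux statistics the design supports (per-genotype slopes and
#' their comparison when several timepoints exist; treatment t-tests and
#' log-ANOVA when several treatments exist). Deterministic given
#' (config, seed); a stack that fails to read is logged and skipped.
#'
#' @param config a [runConfig()].
#' @param dir directory containing \code{manifest.csv} (default
#'   \code{config$outputDir}).
#' @return list with \code{perCell}, \code{perWell}, \code{statistics}
#'   data.frames (also written as CSV into \code{dir}) and \code{log}, the
#'   path of the run log.
#' @export
runPipeline <- function(config = runConfig(), dir = config$outputDir) {
  manifestFile <- file.path(dir, "manifest.csv")
  if (!file.exists(manifestFile))
    stop("runPipeline: no manifest.csv in ", dir)
  manifest <- read.csv(manifestFile, stringsAsFactors = FALSE)
  hash <- analysisHash(config)
  logFile <- file.path(dir, "run.log")
  logCon <- file(logFile, open = "wt")
  on.exit(close(logCon), add = TRUE)
  logMsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    writeLines(line, logCon)
  }
  logMsg("run start, config ", hash, ", ", nrow(manifest), " wells")
  perCell <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      stack <- readScene(file.path(dir, row$file),
                         pixelSizeUm = config$scene$pixelSizeUm)
      obj <- segmentScene(stack, config$segmentation)
      rd <- perCellReadouts(obj, config$segmentation)
      rec <- colocalizationRecords(obj, stack, config$thresholdPercents,
                                   config$segmentation)
      merged <- merge(rec, rd[, c("cell", "colocAreaPct", "mitoAreaUm2",
                                  "nShortMito", "nLongMito")], by = "cell")
      if (nrow(merged)) {
        cbind(well = row$well, genotype = row$genotype,
              treatment = row$treatment, timepointH = row$timepointH,
              merged, configHash = hash)
      } else NULL
    }, error = function(e) {
      logMsg("ERROR well ", row$well, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      perCell[[length(perCell) + 1L]] <- res
      logMsg("well ", row$well, ": ", length(unique(res$cell)), " cells")
    }
  }
  perCell <- if (length(perCell)) do.call(rbind, perCell) else
    emptyPerCellCsv()
  # per-well aggregation (primary threshold variant listed first)
  perWell <- if (nrow(perCell)) {
    firstPct <- config$thresholdPercents[1L]
    sub <- perCell[perCell$thresholdPercent == firstPct, ]
    agg <- aggregate(cbind(colocAreaPct, nColocPuncta, nPuncta,
                           summedPunctaAreaUm2) ~
                       well + genotype + treatment + timepointH,
                     data = sub, FUN = mean, na.rm = TRUE, na.action = NULL)
    agg$nCells <- aggregate(cell ~ well, data = sub,
                            FUN = function(x) length(unique(x)))$cell
    agg$configHash <- hash
    agg
  } else {
    data.frame(well = character(0), genotype = character(0),
               treatment = character(0), timepointH = numeric(0),
               colocAreaPct = numeric(0), nColocPuncta = numeric(0),
               nPuncta = numeric(0), summedPunctaAreaUm2 = numeric(0),
               nCells = integer(0), configHash = character(0))
  }
  stats <- pipelineStatistics(perCell, config, logMsg)
  write.csv(perCell, file.path(dir, "per_cell.csv"), row.names = FALSE)
  write.csv(perWell, file.path(dir, "per_well.csv"), row.names = FALSE)
  write.csv(stats, file.path(dir, "statistics.csv"), row.names = FALSE)
  logMsg("run complete")
  list(perCell = perCell, perWell = perWell, statistics = stats,
       log = logFile)
}

# flux and comparison statistics supported by the analyzed design
pipelineStatistics <- function(perCell, config, logMsg = function(...) NULL) {
  empty <- data.frame(readout = character(0), comparison = character(0),
                      group = character(0), estimate = numeric(0),
                      se = numeric(0), statistic = numeric(0),
                      p = numeric(0), n = integer(0),
                      configHash = character(0))
  if (!nrow(perCell)) return(empty)
  hash <- analysisHash(config)
  firstPct <- config$thresholdPercents[1L]
  d <- perCell[perCell$thresholdPercent == firstPct &
                 is.finite(perCell$colocAreaPct), ]
  rows <- list()
  addRow <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
  if (length(unique(d$timepointH)) > 1L) {
    for (g in unique(d$genotype)) {
      dg <- d[d$genotype == g, ]
      if (length(unique(dg$timepointH)) < 2L) next
      fit <- fitFluxSlope(dg$timepointH, dg$colocAreaPct, g)
      addRow(readout = "colocAreaPct", comparison = "flux_slope",
             group = g, estimate = fit@slope, se = fit@slopeSEM,
             statistic = NA_real_, p = fit@pValue, n = fit@nCells,
             configHash = hash)
    }
    if (length(unique(d$genotype)) == 2L) {
      cmp <- compareFluxSlopes(data.frame(value = d$colocAreaPct,
                                          timeH = d$timepointH,
                                          genotype = d$genotype))
      addRow(readout = "colocAreaPct", comparison = "slope_difference",
             group = cmp$comparison,
             estimate = cmp$slopeDifference, se = cmp$interactionSE,
             statistic = NA_real_, p = cmp$interactionP, n = nrow(d),
             configHash = hash)
      av <- compareGenotypesANOVA(data.frame(value = d$colocAreaPct,
                                             genotype = d$genotype,
                                             timeH = d$timepointH))
      for (j in seq_len(nrow(av)))
        addRow(readout = "colocAreaPct", comparison = "log_anova",
               group = av$term[j], estimate = NA_real_, se = NA_real_,
               statistic = av$F[j], p = av$p[j], n = nrow(d),
               configHash = hash)
    }
  }
  treatments <- unique(d$treatment)
  if (length(treatments) > 1L && "control" %in% treatments) {
    ctrl <- d$colocAreaPct[d$treatment == "control"]
    for (tr in setdiff(treatments, "control")) {
      v <- d$colocAreaPct[d$treatment == tr]
      if (length(v) < 2L || length(ctrl) < 2L) next
      ht <- twoSampleTest(v, ctrl)
      addRow(readout = "colocAreaPct", comparison = "t_test_vs_control",
             group = tr, estimate = mean(v) - mean(ctrl), se = NA_real_,
             statistic = ht$statistic, p = ht$p, n = length(v) + length(ctrl),
             configHash = hash)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
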