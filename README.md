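# mitoflux

Quantification of mitophagy from two-channel fluorescence microscopy:
per-cell segmentation of red (mitochondria) / green (GFP-LC3
autophagosome) / blue (nucleus) images, object- and mask-based
colocalization scoring, and mitophagic-flux estimation from
lysosomal-inhibitor time courses. A ground-truthed synthetic scene
generator makes every stage of the pipeline verifiable by parameter
recovery.

## Who this is for

Labs quantifying mitophagy (or autophagy generally) with high-content
two-reporter imaging: mitochondrially targeted RFP plus GFP-LC3, DAPI
nuclei, fixed or live cells, plate-based acquisition. The package turns
image stacks into per-cell tables and genotype-level statistics, and
provides the simulation machinery to validate the whole chain against a
known truth.

## The core computation

Mitophagosomes appear where green LC3 puncta overlap red mitochondria.
Per cell, `mitoflux` reports the colocalized punctum count, the
**colocalized area as a proportion of mitochondrial area**
(|G∩M| / |M|), the summed LC3 punctum area, duplicate analyses at 30%
and 70% range-threshold masks, and a background-thresholded Pearson
correlation (threshold = background mean + 3 SD per channel).

Because a snapshot cannot separate activated mitophagy from a downstream
block, flux is measured under lysosomal inhibition: with degradation
stopped, the colocalized readout *y* accumulates linearly,

    y(t) = β0 + β t + ε,      β = mitophagic flux
                              [percentage points of mito area per hour]

fitted per genotype by OLS over pooled per-cell values (slope ± SEM of
the slope coefficient); genotype differences are tested through the
time × genotype interaction, log-transform ANOVA and Welch t-tests.

Mitochondrial morphology is classified per object by skeleton length
(Zhang–Suen thinning; "long" at ≥ 4 µm) to track the
fragmentation that accompanies induced mitophagy.

## Worked example

Simulate a small inhibitor time course with a known injected flux for two
"genotypes", analyze it blind, and compare slopes:

```r
library(mitoflux)

dir <- tempfile()
cfg <- runConfig(
  outputDir  = dir, seed = 5L, experiment = "flux_timecourse",
  scene      = sceneConfig(nCells = 16L, imageSize = c(260L, 260L)),
  timecourse = timeCourseConfig(
    genotypeSlopes = c(wildtype = 0, mutant = 1),  # %-points / h
    nCellsPerTimepoint = 16L),
  wellsPerCondition = 2L)

simulateExperiment(cfg)      # TIFFs + ground-truth JSON + manifest.csv
res <- runPipeline(cfg)      # per_cell.csv, per_well.csv, statistics.csv
subset(res$statistics, comparison %in% c("flux_slope", "slope_difference"),
       select = c(comparison, group, estimate, se, p))
```

```
        comparison             group    estimate         se            p
1       flux_slope          wildtype -0.01490463 0.01349346 2.721602e-01
2       flux_slope            mutant  0.95677051 0.04311298 3.801638e-39
3 slope_difference wildtype - mutant -0.97167514 0.05762923 1.855720e-39
```

The mutant's injected accumulation rate (1 percentage point of
mitochondrial area per hour) is recovered at 0.96 ± 0.04, the wild type's
zero flux at −0.01 ± 0.01 (indistinguishable from zero), and the genotype
difference is decisive — on a plate of only 16 cells per timepoint.

Single functions are available for each stage: `generateScene()`,
`segmentScene()`, `perCellReadouts()`, `colocalizationRecords()`,
`thresholdMask()`, `pearsonBackgroundThreshold()`, `fitFluxSlope()`,
`compareGenotypesANOVA()`. A thin CLI with `simulate` / `segment` /
`coloc` / `flux` / `run-all` subcommands lives at
`inst/scripts/mitoflux.R`. The methods vignette
(`vignettes/mitophagy-quantification.Rmd`) documents the model,
parameter choices and limitations.

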