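# Synthetic scene generator: determinism, containment, fragmentation dial,
# punctum placement statistics, optics model, time-course construction.

test_that("identical (config, seed) reproduces a bit-identical scene", {
  cfg <- sceneConfig(nCells = 4L, imageSize = c(140L, 140L), seed = 5L)
  a <- generateScene(cfg)
  b <- generateScene(cfg)
  expect_identical(a$stack@channels, b$stack@channels)
  expect_identical(a$truth@mitoLabels, b$truth@mitoLabels)
  expect_identical(a$truth@puncta, b$truth@puncta)
})

test_that("configuration invariants are enforced", {
  expect_error(sceneConfig(mitoFragmentation = 1.2), "\\[0, 1\\]")
  expect_error(sceneConfig(colocFraction = -0.1), "\\[0, 1\\]")
  expect_error(sceneConfig(pixelSizeUm = 0), "pixelSizeUm")
  expect_error(timeCourseConfig(timepointsH = c(0, 6, 6)),
               "strictly increasing")
  expect_error(timeCourseConfig(genotypeSlopes = c(g = 10),
                                baselinePercent = 20),
               "within \\[0, 100\\]")
})

test_that("all ground-truth objects lie inside their cell regions", {
  for (seed in 1:3) {
    sc <- generateScene(sceneConfig(nCells = 6L, imageSize = c(180L, 180L),
                                    seed = seed), render = FALSE)
    tr <- sc$truth
    expect_true(all(tr@cellLabels[tr@mitoLabels > 0L] > 0L))
    expect_true(all(tr@cellLabels[tr@punctaMask] > 0L))
    p <- tr@puncta
    ctr <- cbind(p$row, p$col)
    expect_identical(tr@cellLabels[ctr], p$cell)
    mm <- tr@mitoLabels > 0L
    expect_true(all(mm[ctr[p$isColocalized, , drop = FALSE]]))
    expect_false(any(mm[ctr[!p$isColocalized, , drop = FALSE]]))
  }
})

test_that("fragmentation dial spans one long tubule to all-short fragments", {
  cfg0 <- sceneConfig(mitoFragmentation = 0)
  region <- outer(1:60, 1:60, function(r, c) (r - 30)^2 + (c - 30)^2 <= 24^2)
  set.seed(1)
  net0 <- generateMitoNetwork(cfg0, region)
  expect_identical(nrow(net0$objects), 1L)
  expect_identical(net0$objects$class, "long")

  cfg1 <- sceneConfig(mitoFragmentation = 1)
  set.seed(2)
  net1 <- generateMitoNetwork(cfg1, region)
  expect_gt(nrow(net1$objects), 1L)
  expect_true(all(net1$objects$class == "short"))
  expect_true(all(net1$objects$skeletonLengthUm <=
                    cfg1$shortLongCutoffUm))
})

test_that("at fragmentation 0.5 the short-object fraction matches the dial", {
  # oracle: count the generator's own placements over 50 seeds
  cfg <- sceneConfig(mitoFragmentation = 0.5)
  region <- outer(1:60, 1:60, function(r, c) (r - 30)^2 + (c - 30)^2 <= 24^2)
  nShort <- 0L; nTot <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    net <- generateMitoNetwork(cfg, region)
    nShort <- nShort + sum(net$objects$class == "short")
    nTot <- nTot + nrow(net$objects)
  }
  se <- sqrt(0.25 / nTot)
  expect_lt(abs(nShort / nTot - 0.5), 3 * se)
})

test_that("degenerate cell regions are rejected", {
  tiny <- matrix(FALSE, 10L, 10L); tiny[5L, 5L] <- TRUE
  expect_error(generateMitoNetwork(sceneConfig(), tiny), "footprint|empty")
  expect_error(generateMitoNetwork(sceneConfig(),
                                   matrix(FALSE, 10L, 10L)), "empty")
})

test_that("punctum colocalization flags follow the requested fraction", {
  mask <- outer(1:80, 1:80, function(r, c) abs(r - 40) <= 2)
  cfg <- sceneConfig(minPunctumSeparationUm = 0)
  set.seed(1)
  all100 <- placePuncta(mask, 100L, 1, config = cfg)
  expect_true(all(mask[cbind(all100$row, all100$col)]))
  none <- placePuncta(mask, 50L, 0, config = cfg)
  expect_false(any(mask[cbind(none$row, none$col)]))
  # binomial closed form: 20 seeds at coloc fraction 0.3, n = 1000
  set.seed(99)
  frac <- replicate(20, mean(placePuncta(mask, 1000L, 0.3,
                                         config = cfg)$isColocalized))
  expect_lt(abs(mean(frac) - 0.3), 3 * sqrt(0.3 * 0.7 / (1000 * 20)))
  expect_error(placePuncta(matrix(FALSE, 10L, 10L), 5L, 0.5, config = cfg),
               "empty mitochondrial mask")
})

test_that("rendering is exact with optics disabled", {
  cfg <- sceneConfig(nCells = 4L, imageSize = c(140L, 140L), seed = 3L,
                     psfSigmaUm = 0, shotNoise = FALSE, readNoiseSd = 0,
                     backgroundLevel = c(red = 0, green = 0, blue = 0))
  sc <- generateScene(cfg)
  tr <- sc$truth
  painted <- cfg$amplitudes[["mito"]] * (tr@mitoLabels > 0L)
  expect_identical(channelImage(sc$stack, "red"), painted)

  cfgB <- sceneConfig(nCells = 4L, imageSize = c(140L, 140L), seed = 3L,
                      psfSigmaUm = 0, shotNoise = FALSE, readNoiseSd = 0)
  scB <- generateScene(cfgB)
  expect_equal(min(channelImage(scB$stack, "red")),
               cfgB$backgroundLevel[["red"]])
})

test_that("shot noise is mean-preserving (Poisson)", {
  cfg <- sceneConfig(nCells = 1L, imageSize = c(48L, 48L), seed = 7L,
                     psfSigmaUm = 0, readNoiseSd = 0, shotNoise = FALSE)
  clean <- generateScene(cfg)
  ref <- channelImage(clean$stack, "red")
  cfgN <- cfg; cfgN$shotNoise <- TRUE
  set.seed(11)
  acc <- matrix(0, 48L, 48L)
  nRep <- 200L
  for (i in seq_len(nRep))
    acc <- acc + channelImage(renderScene(clean$truth, cfgN), "red")
  avg <- acc / nRep
  se <- sqrt(pmax(ref, 1) / nRep)
  expect_true(all(abs(avg - ref) < 3 * se + 0.5))
})

test_that("noiseless invertibility: thresholding recovers every mask", {
  cfg <- sceneConfig(nCells = 4L, imageSize = c(140L, 140L), seed = 13L,
                     psfSigmaUm = 0, shotNoise = FALSE, readNoiseSd = 0)
  sc <- generateScene(cfg)
  tr <- sc$truth
  bg <- cfg$backgroundLevel
  expect_identical(channelImage(sc$stack, "red") > bg[["red"]],
                   tr@mitoLabels > 0L)
  expect_identical(channelImage(sc$stack, "blue") > bg[["blue"]],
                   tr@nucleiLabels > 0L)
  expect_identical(channelImage(sc$stack, "green") > bg[["green"]],
                   tr@cellLabels > 0L)
  expect_identical(channelImage(sc$stack, "green") >
                     bg[["green"]] + cfg$cytoLevelGreen,
                   tr@punctaMask)
})

test_that("colocalization flags are monotone in the requested fraction", {
  cfg <- sceneConfig(nCells = 3L, imageSize = c(140L, 140L), seed = 21L)
  counts <- vapply(c(0, 0.3, 0.7, 1), function(f) {
    cfg$colocFraction <- f
    sum(generateScene(cfg, render = FALSE)$truth@puncta$isColocalized)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("time-course targets lie exactly on baseline + slope * t", {
  tc <- timeCourseConfig(genotypeSlopes = c(g = 1.5), baselinePercent = 4,
                         nCellsPerTimepoint = 20L, cellCV = 0)
  scn <- noiselessConfig(nCells = 4L, imageSize = c(140L, 140L))
  recs <- generateTimeCourse(tc, scn, genotype = "g", mode = "images",
                             seed = 3L)
  for (rec in recs) {
    expected <- (4 + 1.5 * rec$timeH) / 100
    expect_true(all(abs(rec$truth@perCell$targetFraction - expected) < 1e-12))
  }
  # zero slope: identical targets at every timepoint
  tc0 <- timeCourseConfig(genotypeSlopes = c(g = 0), baselinePercent = 6,
                          nCellsPerTimepoint = 10L, cellCV = 0)
  vals <- generateTimeCourse(tc0, scn, genotype = "g", mode = "values",
                             seed = 4L)
  expect_true(all(vals$value == 6))
})

test_that("OLS on ground-truth values recovers the injected slope", {
  inj <- 1.2
  res <- fluxRecoveryStudy(inj, nReplicates = 20L,
                           tc = timeCourseConfig(nCellsPerTimepoint = 60L),
                           seed = 5L, mode = "values")
  se <- sd(res$slope) / sqrt(nrow(res))
  expect_lt(abs(mean(res$slope) - inj), 2 * se + 1e-9)
})
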