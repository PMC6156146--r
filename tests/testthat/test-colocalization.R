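# Colocalization metrics against hand-counted toys and brute-force oracles.

# brute-force oracle: per-punctum pixel enumeration
bruteForceColocCount <- function(punctaLabels, mitoMask, minOverlap) {
  n <- 0L
  for (lab in setdiff(unique(as.vector(punctaLabels)), 0L)) {
    px <- which(punctaLabels == lab)
    if (sum(mitoMask[px]) / length(px) >= minOverlap) n <- n + 1L
  }
  n
}

test_that("colocalized punctum counting matches trivial cases", {
  pl <- matrix(0L, 10L, 10L)
  pl[2:3, 2:3] <- 1L; pl[7:8, 7:8] <- 2L
  all <- matrix(TRUE, 10L, 10L)
  none <- matrix(FALSE, 10L, 10L)
  expect_identical(as.integer(countColocalizedPuncta(pl, all)), 2L)
  expect_identical(as.integer(countColocalizedPuncta(pl, none)), 0L)
  half <- matrix(FALSE, 10L, 10L); half[, 1:2] <- TRUE   # punctum 1: 2/4
  expect_identical(as.integer(countColocalizedPuncta(pl, half, 0.5)), 1L)
  expect_identical(as.integer(countColocalizedPuncta(pl, half, 0.6)), 0L)
  expect_error(countColocalizedPuncta(pl, matrix(TRUE, 3L, 3L)), "shape")
})

test_that("area fraction matches hand-counted toys and flags undefined", {
  mito <- matrix(FALSE, 4L, 4L); mito[1:2, 1:4] <- TRUE    # 8 px
  green <- matrix(FALSE, 4L, 4L); green[2L, 2:3] <- TRUE   # 2 px overlap
  expect_equal(colocalizedAreaFraction(green, mito), 0.25)
  expect_equal(colocalizedAreaFraction(mito, mito), 1.0)
  expect_equal(colocalizedAreaFraction(!mito, mito), 0.0)
  und <- colocalizedAreaFraction(green, matrix(FALSE, 4L, 4L))
  expect_true(is.na(und))
  expect_match(attr(und, "undefined"), "empty")
  expect_error(colocalizedAreaFraction(green, matrix(TRUE, 2L, 2L)), "shape")
})

test_that("area fraction is monotone under green-mask growth", {
  set.seed(8)
  mito <- matrix(runif(900) < 0.3, 30L, 30L)
  g1 <- matrix(runif(900) < 0.2, 30L, 30L)
  g2 <- g1 | matrix(runif(900) < 0.2, 30L, 30L)
  expect_gte(colocalizedAreaFraction(g2, mito),
             colocalizedAreaFraction(g1, mito))
})

test_that("counts and fractions agree with brute force on synthetic scenes", {
  for (seed in c(3L, 14L)) {
    sc <- smallScene(seed = seed)
    obj <- segmentScene(sc$stack)
    mm <- mitoMask(obj)
    fast <- countColocalizedPuncta(obj@punctaLabels, mm, 0.5)
    expect_identical(as.integer(fast),
                     bruteForceColocCount(obj@punctaLabels, mm, 0.5))
    inter <- sum((obj@punctaLabels > 0L) & mm)
    expect_equal(colocalizedAreaFraction(obj@punctaLabels > 0L, mm),
                 inter / sum(mm))
  }
})

test_that("summed punctum area per cell uses physical units", {
  pf <- data.frame(label = 1:3, cell = c(1L, 1L, 2L),
                   areaPx = c(12L, 8L, 5L))
  tot <- summedPunctaAreaPerCell(pf, cellIds = 1:3, pixelSizeUm = 1)
  expect_equal(unname(tot), c(20, 5, 0))
  tot2 <- summedPunctaAreaPerCell(pf, cellIds = 1L, pixelSizeUm = 2)
  expect_equal(unname(tot2), 80)   # 20 px * 4 um^2/px
  # no puncta: zero for every cell
  none <- summedPunctaAreaPerCell(pf[0, ], cellIds = 1:2)
  expect_equal(unname(none), c(0, 0))
})

test_that("summed punctum areas match generator truth on noiseless scenes", {
  sc <- smallScene(seed = 17L)
  obj <- segmentScene(sc$stack)
  map <- matchCellLabels(obj, sc$truth)
  px <- pixelSize(obj)
  measured <- summedPunctaAreaPerCell(obj@punctaFeatures,
                                      seq_len(max(obj@cellLabels)), px)
  tru <- sc$truth@puncta
  for (segId in seq_along(map)) {
    if (map[segId] == 0L) next
    expected <- sum(tru$areaPx[tru$cell == map[segId]]) * px^2
    expect_equal(unname(measured[as.character(segId)]), expected)
  }
})

test_that("background-thresholded Pearson matches the closed form", {
  set.seed(5)
  bgR <- matrix(FALSE, 12L, 12L); bgR[1:3, ] <- TRUE
  ch1 <- matrix(2, 12L, 12L)
  ch1[6:10, 6:10] <- matrix(seq(50, 100, length.out = 25), 5L, 5L)
  # affine positive relation -> r = 1
  expect_equal(pearsonBackgroundThreshold(ch1, 2 * ch1 + 5, bgR), 1)
  # perfect inversion -> r = -1
  expect_equal(pearsonBackgroundThreshold(ch1, max(ch1) - ch1, bgR), -1)
  # worked 5x5 arrays: agree with independent closed form
  ch2 <- matrix(2, 12L, 12L)
  set.seed(31)
  ch2[6:10, 6:10] <- matrix(runif(25, 40, 120), 5L, 5L)
  r <- pearsonBackgroundThreshold(ch1, ch2, bgR)
  x <- ch1[6:10, 6:10]; y <- ch2[6:10, 6:10]
  rRef <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, rRef, tolerance = 1e-12)
})

test_that("Pearson background threshold excludes sub-threshold pixels", {
  # background with known statistics; foreground straddles mean + 3 SD
  set.seed(6)
  bgR <- matrix(FALSE, 20L, 20L); bgR[, 1:8] <- TRUE
  ch1 <- matrix(0, 20L, 20L); ch2 <- matrix(0, 20L, 20L)
  bgVals <- rnorm(sum(bgR), 10, 2)
  ch1[bgR] <- bgVals; ch2[bgR] <- bgVals
  thr <- mean(bgVals) + 3 * sd(bgVals)
  fg <- !bgR
  set.seed(7)
  v1 <- runif(sum(fg), thr - 6, thr + 6)
  ch1[fg] <- v1
  ch2[fg] <- 2 * v1
  r <- pearsonBackgroundThreshold(ch1, ch2, bgR)
  sel <- ch1 > thr | ch2 > thr      # both channels share background stats
  x <- ch1[sel]; y <- ch2[sel]
  rRef <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, rRef, tolerance = 1e-12)
  expect_error(pearsonBackgroundThreshold(ch1, ch2,
                                          matrix(FALSE, 20L, 20L)),
               "empty background")
})

test_that("Pearson is invariant under joint positive affine rescaling", {
  set.seed(9)
  bgR <- matrix(FALSE, 15L, 15L); bgR[, 1:5] <- TRUE
  ch1 <- matrix(rnorm(225, 8, 1), 15L, 15L)
  ch1[8:12, 8:12] <- runif(25, 60, 140)
  ch2 <- matrix(rnorm(225, 8, 1), 15L, 15L)
  ch2[8:12, 8:12] <- runif(25, 60, 140)
  r1 <- pearsonBackgroundThreshold(ch1, ch2, bgR)
  r2 <- pearsonBackgroundThreshold(3 * ch1 + 7, ch2, bgR)
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("undefined Pearson cases are flagged, never silently zero", {
  bgR <- matrix(FALSE, 8L, 8L); bgR[, 1:4] <- TRUE
  flat <- matrix(1, 8L, 8L)
  r <- pearsonBackgroundThreshold(flat, flat, bgR)
  expect_true(is.na(r))
  expect_false(is.null(attr(r, "undefined")))
})

test_that("colocalized counts at 70% threshold never exceed those at 30%", {
  sc <- generateScene(sceneConfig(nCells = 4L, imageSize = c(140L, 140L),
                                  seed = 23L))
  obj <- segmentScene(sc$stack)
  rec <- colocalizationRecords(obj, sc$stack, c(30, 70))
  wide <- merge(rec[rec$thresholdPercent == 30,
                    c("cell", "nColocPuncta", "colocAreaFraction")],
                rec[rec$thresholdPercent == 70,
                    c("cell", "nColocPuncta", "colocAreaFraction")],
                by = "cell", suffixes = c("30", "70"))
  ok <- complete.cases(wide[, c("nColocPuncta30", "nColocPuncta70")])
  expect_true(all(wide$nColocPuncta70[ok] <= wide$nColocPuncta30[ok]))
})
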