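# Segmentation: nuclei, cell regions, mitochondria classification, puncta,
# and the range threshold mask.

discImage <- function(dims, centers, r, amplitude = 120, bg = 0) {
  m <- matrix(bg, dims[1L], dims[2L])
  for (i in seq_len(nrow(centers)))
    m[outer(seq_len(dims[1L]), seq_len(dims[2L]), function(rr, cc)
      (rr - centers[i, 1L])^2 + (cc - centers[i, 2L])^2 <= r^2)] <- amplitude
  m
}

test_that("threshold mask implements percent-of-range semantics", {
  img <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80, 90), 3L, 3L)
  start <- matrix(TRUE, 3L, 3L)
  m30 <- thresholdMask(img, start, 30)
  expect_identical(sum(m30), 6L)                    # >= 34: {40..90}
  expect_true(all(img[m30] >= 34))
  expect_identical(thresholdMask(img, start, 0), start)
  m100 <- thresholdMask(img, start, 100)
  expect_identical(which(m100), which(img == 90))
  expect_error(thresholdMask(img, matrix(FALSE, 3L, 3L), 30), "empty")
  expect_error(thresholdMask(img, start, 130), "\\[0, 100\\]")
})

test_that("threshold mask is antitone in percent", {
  set.seed(42)
  for (i in 1:5) {
    img <- matrix(runif(400, 0, 255), 20L, 20L)
    start <- matrix(runif(400) < 0.6, 20L, 20L)
    if (!any(start)) next
    m30 <- thresholdMask(img, start, 30)
    m70 <- thresholdMask(img, start, 70)
    expect_true(all(m70[m30 == FALSE] == FALSE))    # m70 subset of m30
    expect_true(all(!m70 | m30))
  }
})

test_that("nucleus detection finds separated nuclei and splits touching ones", {
  expect_identical(max(detectNuclei(matrix(5, 80L, 80L))), 0L)
  centers <- cbind(c(15, 15, 40, 65, 65), c(15, 60, 38, 15, 60))
  img <- discImage(c(80L, 80L), centers, 7)
  lab <- detectNuclei(img)
  expect_identical(max(lab), 5L)
  for (i in seq_len(5)) {
    px <- which(lab == i, arr.ind = TRUE)
    ctr <- colMeans(px)
    d <- sqrt(rowSums((t(t(centers) - ctr))^2))
    expect_lt(min(d), 1.5)
  }
  # two discs overlapping by 20% of the radius: split by watershed
  r <- 10
  two <- discImage(c(60L, 60L), cbind(c(30, 30), c(20, 20 + 1.8 * r)), r)
  expect_identical(max(detectNuclei(two)), 2L)
})

test_that("cell regions: one nucleus with uniform cytoplasm claims the whole foreground", {
  nuc <- matrix(0L, 60L, 60L)
  nuc[28:32, 28:32] <- 1L
  cyto <- discImage(c(60L, 60L), cbind(30, 30), 20, amplitude = 40, bg = 2)
  cells <- assignCellRegions(nuc, cyto * 0, cyto)
  fg <- cyto > 2
  expect_true(all(cells[fg] == 1L))
  zero <- assignCellRegions(matrix(0L, 30L, 30L), matrix(0, 30L, 30L),
                            matrix(0, 30L, 30L))
  expect_true(all(zero == 0L))
})

test_that("cell assignment recovers generator regions on a noiseless scene", {
  sc <- smallScene(seed = 2L)
  obj <- segmentScene(sc$stack)
  map <- matchCellLabels(obj, sc$truth)
  seg <- obj@cellLabels
  mapped <- matrix(0L, nrow(seg), ncol(seg))
  pos <- seg > 0L
  mapped[pos] <- map[seg[pos]]
  truthPx <- sc$truth@cellLabels > 0L
  expect_gt(mean(mapped[truthPx] == sc$truth@cellLabels[truthPx]), 0.95)
})

test_that("mitochondria are classified by skeleton length against the cutoff", {
  cells <- matrix(1L, 40L, 60L)
  px <- 0.65
  red <- matrix(0, 40L, 60L)
  red[19:21, 5:36] <- 150          # ~32 px of length = 20.8 um -> long
  red[33:34, 45:47] <- 150         # small blob -> short
  seg <- segmentMitochondria(red, cells, pixelSizeUm = px)
  expect_identical(nrow(seg$features), 2L)
  long <- seg$features[seg$features$skeletonLengthUm ==
                         max(seg$features$skeletonLengthUm), ]
  expect_identical(long$class, "long")
  short <- seg$features[seg$features$skeletonLengthUm ==
                          min(seg$features$skeletonLengthUm), ]
  expect_identical(short$class, "short")
  expect_lt(short$skeletonLengthUm, 4)
})

test_that("noiseless scenes reproduce generator masks and classes exactly", {
  for (seed in c(4L, 9L)) {
    sc <- smallScene(seed = seed)
    obj <- segmentScene(sc$stack)
    tr <- sc$truth
    expect_identical(mitoMask(obj), mitoMask(tr))
    expect_identical(obj@punctaLabels > 0L, tr@punctaMask)
    expect_identical(nrow(obj@mitoFeatures), nrow(tr@mitoObjects))
    expect_identical(table(obj@mitoFeatures$class),
                     table(tr@mitoObjects$class))
    expect_equal(sort(obj@mitoFeatures$skeletonLengthUm),
                 sort(tr@mitoObjects$skeletonLengthUm))
    # object masks stay inside assigned cell regions
    expect_true(all(obj@cellLabels[mitoMask(obj)] > 0L))
    expect_true(all(obj@cellLabels[obj@punctaLabels > 0L] > 0L))
  }
})

test_that("punctum detection is exact on clean scenes", {
  blank <- segmentScene(ImageStack(red = matrix(4, 90L, 90L),
                                   green = matrix(4, 90L, 90L),
                                   blue = matrix(4, 90L, 90L)))
  expect_identical(nrow(blank@punctaFeatures), 0L)

  sc <- smallScene(seed = 6L)
  obj <- segmentScene(sc$stack)
  det <- obj@punctaFeatures
  tru <- sc$truth@puncta
  # recall and precision 1 with a 2-px match radius
  dmat <- outer(det$row, tru$row, "-")^2 + outer(det$col, tru$col, "-")^2
  matched <- dmat <= 4
  expect_identical(nrow(det), nrow(tru))
  expect_true(all(rowSums(matched) >= 1))
  expect_true(all(colSums(matched) >= 1))
})

test_that("two distant puncta give exactly two detections", {
  g <- matrix(2, 60L, 60L)
  g[discImage(c(60L, 60L), cbind(c(20, 40), c(20, 44)), 2) > 0] <- 150
  cells <- matrix(1L, 60L, 60L)
  det <- detectPuncta(g, cells)
  expect_identical(nrow(det$features), 2L)
})

test_that("segmentation is deterministic", {
  sc <- generateScene(sceneConfig(nCells = 4L, imageSize = c(140L, 140L),
                                  seed = 31L))
  a <- segmentScene(sc$stack)
  b <- segmentScene(sc$stack)
  expect_identical(a@cellLabels, b@cellLabels)
  expect_identical(a@mitoLabels, b@mitoLabels)
  expect_identical(a@punctaLabels, b@punctaLabels)
})
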