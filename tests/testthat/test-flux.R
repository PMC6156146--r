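# Flux regression and genotype statistics against closed-form oracles.

test_that("flux slope matches closed-form OLS on toy data", {
  # exact line: slope 2, zero residuals
  t1 <- c(0, 0, 6, 6, 24, 24)
  fit <- fitFluxSlope(t1, 2 * t1)
  expect_equal(fit@slope, 2)
  expect_equal(fit@slopeSEM, 0)
  expect_true(fit@degenerate)
  # normal equations by hand: (0,1), (1,3), (2,5) -> slope 2, intercept 1
  fit2 <- fitFluxSlope(c(0, 1, 2), c(1, 3, 5))
  expect_equal(fit2@slope, 2)
  expect_equal(fit2@intercept, 1)
  # noisy toy: agree with the explicit normal-equation solution
  set.seed(3)
  tt <- rep(c(0, 6, 24), each = 30)
  y <- 5 + 0.8 * tt + rnorm(90, 0, 3)
  fit3 <- fitFluxSlope(tt, y)
  bHat <- sum((tt - mean(tt)) * (y - mean(y))) / sum((tt - mean(tt))^2)
  expect_equal(fit3@slope, bHat, tolerance = 1e-12)
  resid <- y - (mean(y) - bHat * mean(tt)) - bHat * tt
  seHat <- sqrt(sum(resid^2) / (90 - 2) / sum((tt - mean(tt))^2))
  expect_equal(fit3@slopeSEM, seHat, tolerance = 1e-12)
  expect_error(fitFluxSlope(rep(6, 5), rnorm(5)), "two distinct")
})

test_that("slope estimates are equivariant under readout rescaling", {
  set.seed(4)
  tt <- rep(c(0, 6, 24), each = 20)
  y <- 4 + 1.5 * tt + rnorm(60, 0, 4)
  f1 <- fitFluxSlope(tt, y)
  f3 <- fitFluxSlope(tt, 3 * y)
  expect_equal(f3@slope, 3 * f1@slope)
  expect_equal(f3@slopeSEM, 3 * f1@slopeSEM)
})

test_that("genotype ANOVA on log values matches brute-force sums of squares", {
  # identical groups: F = 0, p = 1
  same <- data.frame(value = rep(c(1, 2, 3, 4), 2),
                     genotype = rep(c("a", "b"), each = 4))
  av <- compareGenotypesANOVA(same)
  expect_equal(av$F[av$term == "genotype"], 0)
  expect_equal(av$p[av$term == "genotype"], 1)
  # two-group toy: F equals between/within mean-square ratio computed by hand
  d <- data.frame(value = c(1.2, 2.1, 3.3, 0.8, 5.0, 6.1, 7.2, 5.5),
                  genotype = rep(c("wt", "mut"), each = 4))
  offset <- min(d$value) * 1e-3
  lv <- log(d$value + offset)
  g <- split(lv, d$genotype)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - mean(lv))^2,
                    numeric(1)))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  fRef <- (ssb / 1) / (ssw / 6)
  av2 <- compareGenotypesANOVA(d)
  expect_equal(av2$F[av2$term == "genotype"], fRef, tolerance = 1e-10)
  expect_error(compareGenotypesANOVA(
    data.frame(value = 1:4, genotype = factor(rep("a", 4),
                                              levels = c("a", "b")))),
    "empty|two genotypes")
})

test_that("a 2.5-fold mean difference at n = 500 is detected reliably", {
  set.seed(11)
  hits <- 0L
  for (i in 1:100) {
    d <- data.frame(
      value = c(rgamma(500, shape = 4, rate = 4 / 2),
                rgamma(500, shape = 4, rate = 4 / 5)),
      genotype = rep(c("wt", "mut"), each = 500))
    av <- compareGenotypesANOVA(d)
    if (av$p[av$term == "genotype"] < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("two-sample test matches the closed-form Welch statistic", {
  same <- twoSampleTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  a <- c(3.1, 4.5, 2.8, 5.0, 3.9)
  b <- c(6.2, 7.0, 5.8, 6.6)
  ht <- twoSampleTest(a, b)
  tRef <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(ht$statistic, tRef, tolerance = 1e-12)
  dfRef <- (var(a) / 5 + var(b) / 4)^2 /
    ((var(a) / 5)^2 / 4 + (var(b) / 4)^2 / 3)
  expect_equal(ht$df, dfRef, tolerance = 1e-10)
  expect_equal(ht$p, 2 * pt(-abs(tRef), dfRef), tolerance = 1e-12)
  expect_error(twoSampleTest(1, c(1, 2)), "n >= 2")
})

test_that("slope comparison recovers the injected genotype difference", {
  tc <- timeCourseConfig(genotypeSlopes = c(wildtype = 0.5, opa1 = 1.5),
                         nCellsPerTimepoint = 300L)
  vals <- generateTimeCourse(tc, mode = "values", seed = 21L)
  cmp <- compareFluxSlopes(data.frame(value = vals$value,
                                      timeH = vals$timeH,
                                      genotype = vals$genotype))
  expect_lt(cmp$interactionP, 0.01)
  expect_equal(abs(cmp$slopeDifference), 1, tolerance = 0.25)
  expect_gt(cmp$fits[["opa1"]]@slope, cmp$fits[["wildtype"]]@slope)
})

test_that("ground-truth slope estimation is nearly unbiased at n = 500", {
  inj <- 1.0
  res <- fluxRecoveryStudy(inj, nReplicates = 20L,
                           tc = timeCourseConfig(nCellsPerTimepoint = 500L),
                           seed = 31L, mode = "values")
  expect_lt(abs(mean(res$slope) - inj), 0.1 * inj)
})
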