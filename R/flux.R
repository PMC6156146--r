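## Flux estimation and genotype comparisons: OLS of a per-cell mitophagy
## readout on time under lysosomal inhibition, log-transform ANOVA, and
## two-sample t-tests.

#' Fit a mitophagic-flux slope by ordinary least squares
#'
#' Regresses per-cell readout values on time (hours). The slope is the flux
#' (readout units per hour), reported with the OLS standard error of the
#' slope coefficient (the "slope +/- SEM" convention) and the regression
#' p-value.
#'
#' @param timeH numeric vector of time points (hours), one per observation.
#' @param values numeric readout values, same length.
#' @param genotype label stored in the result.
#' @return a [FluxFit-class].
#' @export
fitFluxSlope <- function(timeH, values, genotype = "") {
  ok <- is.finite(timeH) & is.finite(values)
  timeH <- timeH[ok]; values <- values[ok]
  tp <- sort(unique(timeH))
  if (length(tp) < 2L)
    stop("fitFluxSlope: need at least two distinct timepoints")
  fit <- lm(values ~ timeH)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  scale <- max(abs(values), 1e-300)
  degenerate <- sm$sigma <= 1e-10 * scale || nrow(co) < 2L
  slope <- unname(coef(fit)[2L])
  sem <- if (degenerate) 0 else unname(co["timeH", "Std. Error"])
  p <- if (degenerate) NA_real_ else unname(co["timeH", "Pr(>|t|)"])
  new("FluxFit", genotype = as.character(genotype), slope = slope,
      slopeSEM = sem, intercept = unname(coef(fit)[1L]),
      pValue = p, nCells = length(values), timepointsH = tp,
      degenerate = degenerate)
}

#' Compare flux slopes between genotypes
#'
#' Fits \code{value ~ time * genotype} and tests the time x genotype
#' interaction: the difference between the genotype-specific accumulation
#' slopes. The interaction is tested with heteroscedasticity-robust (White
#' HC3) standard errors: per-cell readout variance grows with its mean over
#' the time course, and the plain OLS standard error is anticonservative
#' there (empirically ~12 percent type-I error at nominal 5 percent).
#'
#' @param data data.frame with columns \code{value}, \code{timeH},
#'   \code{genotype}.
#' @return list: \code{fits} (one [FluxFit-class] per genotype),
#'   \code{slopeDifference} (second factor level minus first; see
#'   \code{comparison}), \code{comparison} (a "B - A" label),
#'   \code{interactionSE}, \code{interactionP}.
#' @export
compareFluxSlopes <- function(data) {
  stopifnot(all(c("value", "timeH", "genotype") %in% names(data)))
  data <- data[is.finite(data$value), , drop = FALSE]
  data$genotype <- factor(data$genotype)
  if (nlevels(data$genotype) != 2L)
    stop("compareFluxSlopes: exactly two genotypes required")
  fits <- lapply(levels(data$genotype), function(g) {
    d <- data[data$genotype == g, ]
    fitFluxSlope(d$timeH, d$value, g)
  })
  names(fits) <- levels(data$genotype)
  fit <- lm(value ~ timeH * genotype, data = data)
  est <- coef(fit)
  term <- names(est)[grepl("^timeH:", names(est))]
  vc <- sandwich::vcovHC(fit, type = "HC3")
  se <- sqrt(vc[term, term])
  tStat <- est[[term]] / se
  p <- 2 * pt(-abs(tStat), df = fit$df.residual)
  lv <- levels(data$genotype)
  list(fits = fits,
       slopeDifference = unname(est[[term]]),
       comparison = sprintf("%s - %s", lv[2L], lv[1L]),
       interactionSE = unname(se),
       interactionP = unname(p))
}

#' Genotype comparison by ANOVA on log-transformed readouts
#'
#' Readouts are normalized as \code{log(x + offset)} before a fixed-effects
#' ANOVA; with several time points the model is genotype * time (factor) and
#' both the genotype main effect and the genotype x time interaction are
#' reported. The default offset admits zero readouts: the smallest positive
#' observed value times 1e-3.
#'
#' @param data data.frame with columns \code{value}, \code{genotype} and
#'   optionally \code{timeH}.
#' @param offset additive offset before the log; default as above.
#' @return data.frame: term, df, F, p.
#' @export
compareGenotypesANOVA <- function(data, offset = NULL) {
  stopifnot(all(c("value", "genotype") %in% names(data)))
  data <- data[is.finite(data$value), , drop = FALSE]
  data$genotype <- factor(data$genotype)
  if (nlevels(data$genotype) < 2L)
    stop("compareGenotypesANOVA: need at least two genotypes")
  if (any(tabulate(data$genotype, nlevels(data$genotype)) == 0L))
    stop("compareGenotypesANOVA: empty genotype group")
  if (any(data$value < 0))
    stop("compareGenotypesANOVA: negative readouts")
  if (is.null(offset)) {
    pos <- data$value[data$value > 0]
    if (!length(pos)) stop("compareGenotypesANOVA: no positive values")
    offset <- min(pos) * 1e-3
  }
  data$logv <- log(data$value + offset)
  multiTime <- "timeH" %in% names(data) &&
    length(unique(data$timeH)) > 1L
  fit <- if (multiTime) {
    data$timeF <- factor(data$timeH)
    aov(logv ~ genotype * timeF, data = data)
  } else {
    aov(logv ~ genotype, data = data)
  }
  tab <- summary(fit)[[1L]]
  terms <- trimws(rownames(tab))
  keep <- terms != "Residuals"
  out <- data.frame(term = gsub("timeF", "time", terms[keep]),
                    df = tab[keep, "Df"],
                    F = tab[keep, "F value"],
                    p = tab[keep, "Pr(>F)"])
  rownames(out) <- NULL
  out
}

#' Two-sample comparison of readouts
#'
#' Welch's t-test by default (robust to unequal variances); Student's
#' variant selectable.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @param welch if FALSE, the equal-variance Student t-test.
#' @return list: statistic, p, df, method.
#' @export
twoSampleTest <- function(groupA, groupB, welch = TRUE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("twoSampleTest: each group needs n >= 2")
  ht <- t.test(groupA, groupB, var.equal = !welch)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), method = ht$method)
}
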