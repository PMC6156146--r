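#' @importFrom stats rpois rnorm runif rgamma median mad quantile coef lm
#'   anova aov pt t.test setNames complete.cases rexp sd var
#' @importFrom utils write.csv read.csv head
#' @importFrom sandwich vcovHC
NULL

#' Otsu threshold for a numeric vector
#'
#' Classic maximum between-class-variance threshold on a 256-bin histogram.
#' Operates on a plain numeric vector so it can be applied per cell region,
#' unlike whole-image implementations.
#'
#' @param v numeric vector of intensities.
#' @param nbins number of histogram bins.
#' @return threshold value; pixels strictly above it are foreground. For a
#'   constant vector the maximum is returned (empty foreground).
#' @export
otsuThreshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("otsuThreshold: no finite values")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)
  h <- as.numeric(
    tabulate(pmin(nbins, 1L + as.integer((v - lo) / (hi - lo) * nbins)),
             nbins = nbins))
  w <- cumsum(h)
  mids <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
  mu <- cumsum(h * mids)
  n <- w[nbins]; muT <- mu[nbins]
  w1 <- w[-nbins]; w2 <- n - w1
  ok <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[ok] <- (muT * w1[ok] - n * mu[-nbins][ok])^2 / (w1[ok] * w2[ok])
  k <- which.max(bcv)
  lo + k * (hi - lo) / nbins
}

#' Lower threshold of a two-threshold (three-class) Otsu split
#'
#' Maximizes the between-class variance over two thresholds and returns the
#' lower one: the background/cytoplasm cut in images whose histogram is
#' trimodal (background, diffuse cytoplasm, bright organelles), where a
#' single Otsu threshold can land above the cytoplasm level.
#'
#' @param v numeric vector of intensities.
#' @param nbins number of histogram bins.
#' @return the lower threshold value.
#' @export
otsuThreshold3 <- function(v, nbins = 128L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("otsuThreshold3: no finite values")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)
  h <- as.numeric(
    tabulate(pmin(nbins, 1L + as.integer((v - lo) / (hi - lo) * nbins)),
             nbins = nbins))
  W <- c(0, cumsum(h))
  M <- c(0, cumsum(h * (lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins)))
  n <- W[nbins + 1L]
  # class statistic between cut points a < b (1-based bin boundaries)
  term <- function(w, m) ifelse(w > 0, m^2 / w, 0)
  best <- -Inf; bestA <- 1L
  for (a in 1L:(nbins - 2L)) {
    b <- (a + 1L):(nbins - 1L)
    s <- term(W[a + 1L], M[a + 1L]) +
      term(W[b + 1L] - W[a + 1L], M[b + 1L] - M[a + 1L]) +
      term(n - W[b + 1L], M[nbins + 1L] - M[b + 1L])
    i <- which.max(s)
    if (s[i] > best) { best <- s[i]; bestA <- a }
  }
  lo + bestA * (hi - lo) / nbins
}

# integer (dr, dc) offsets of pixels within Euclidean radius r (pixels);
# always contains the origin
discOffsets <- function(r) {
  ri <- max(0L, as.integer(ceiling(r)))
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g <- g[g$dr^2 + g$dc^2 <= r^2 | (g$dr == 0L & g$dc == 0L), , drop = FALSE]
  as.matrix(g)
}

# linear indices of a disc stamped at (row, col), clipped to the matrix bounds
stampIndices <- function(row, col, offsets, dims) {
  rr <- row + offsets[, 1L]; cc <- col + offsets[, 2L]
  keep <- rr >= 1L & rr <= dims[1L] & cc >= 1L & cc <= dims[2L]
  rr <- rr[keep]; cc <- cc[keep]
  (cc - 1L) * dims[1L] + rr
}

# shift a matrix by (dr, dc), padding with `fill`
shiftMat <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  sr <- max(1L, 1L + dr):min(nrow(m), nrow(m) + dr)
  sc <- max(1L, 1L + dc):min(ncol(m), ncol(m) + dc)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

clampRange <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Short deterministic hash of a configuration
#'
#' Polynomial rolling hash (mod 2^31 - 1) of the canonical JSON serialization,
#' embedded in every results file so outputs can be traced to the exact
#' parameter set that produced them.
#'
#' @param config a list.
#' @return an 8-character hexadecimal string.
#' @export
configHash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# sub-stream seed derived from a master seed and an index; stays < 2^31
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}
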