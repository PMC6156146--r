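#' Morphological skeleton of a binary mask
#'
#' Zhang-Suen thinning: iteratively deletes boundary pixels that do not break
#' 8-connectivity until only a one-pixel-wide skeleton remains. Used to reduce
#' segmented mitochondria to their centerlines so that skeleton length can
#' separate "short" (fragmented) from "long" (tubular) objects.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of the same size containing the skeleton.
#' @export
thinMask <- function(mask) {
  nrp <- nrow(mask) + 2L
  m <- matrix(0L, nrp, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask != 0)
  # neighbor linear-index offsets in Zhang-Suen order P2..P9
  # (N, NE, E, SE, S, SW, W, NW); rows grow southwards, columns eastwards
  dN <- -1L; dS <- 1L; dW <- -nrp; dE <- nrp
  off <- c(dN, dN + dE, dE, dS + dE, dS, dS + dW, dW, dN + dW)
  idx <- which(m == 1L)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      if (length(idx) == 0L) break
      p <- matrix(m[rep(idx, times = 8L) + rep(off, each = length(idx))],
                  length(idx), 8L)
      b <- rowSums(p)
      pn <- cbind(p, p[, 1L])
      a <- rowSums(pn[, 1:8, drop = FALSE] == 0L &
                   pn[, 2:9, drop = FALSE] == 1L)
      cond <- b >= 2L & b <= 6L & a == 1L
      if (step == 1L) {
        cond <- cond & p[, 1L] * p[, 3L] * p[, 5L] == 0L &
          p[, 3L] * p[, 5L] * p[, 7L] == 0L
      } else {
        cond <- cond & p[, 1L] * p[, 3L] * p[, 7L] == 0L &
          p[, 1L] * p[, 5L] * p[, 7L] == 0L
      }
      if (any(cond)) {
        m[idx[cond]] <- 0L
        idx <- idx[!cond]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] == 1L] <- TRUE
  out
}

#' Skeleton length per labeled object
#'
#' Chain length of the skeleton restricted to each label: orthogonal neighbor
#' links count 1 pixel, diagonal links sqrt(2), and a diagonal link is skipped
#' when the two pixels already share an orthogonal skeleton neighbor (staircase
#' correction). Isolated single-pixel skeletons count 1 pixel.
#'
#' @param skeleton logical matrix (e.g. from [thinMask()]).
#' @param labels integer matrix of object labels (0 = background).
#' @param pixelSizeUm physical pixel size in micrometers.
#' @return named numeric vector of lengths in micrometers, one per label.
#' @export
skeletonLengthByLabel <- function(skeleton, labels, pixelSizeUm = 1) {
  sk <- skeleton & labels > 0L
  lab <- labels * sk
  maxLab <- max(lab)
  if (maxLab == 0L) return(setNames(numeric(0), character(0)))
  pairCount <- function(dr, dc) {
    a <- lab
    b <- shiftMat(lab, dr, dc)
    ok <- a > 0L & a == b
    if (dr != 0L && dc != 0L) {
      # skip diagonal links bridged by an orthogonal step
      o1 <- shiftMat(lab, dr, 0L); o2 <- shiftMat(lab, 0L, dc)
      ok <- ok & !(o1 == a & o1 > 0L) & !(o2 == a & o2 > 0L)
    }
    tabulate(a[ok], nbins = maxLab)
  }
  orth <- pairCount(1L, 0L) + pairCount(0L, 1L)
  diag <- pairCount(1L, 1L) + pairCount(1L, -1L)
  npix <- tabulate(lab[lab > 0L], nbins = maxLab)
  len <- orth + sqrt(2) * diag
  len[len == 0 & npix > 0] <- 1       # single-pixel object
  setNames(len * pixelSizeUm, as.character(seq_len(maxLab)))
}
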