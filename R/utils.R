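## Small numeric helpers shared across modules.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Linear interpolation matrix between two sampling densities
#'
#' Pixel-centre aligned: output pixel j samples input coordinate
#' (j - 0.5) * nIn/nOut + 0.5, clamped to the input range, so the physical
#' extent of the signal is preserved under resizing.
#' @param nIn,nOut input/output sample counts.
#' @return nOut x nIn weight matrix (rows sum to 1).
#' @keywords internal
interpMatrix <- function(nIn, nOut) {
  if (nIn == 1L) return(matrix(1, nOut, 1))
  pos <- (seq_len(nOut) - 0.5) * nIn / nOut + 0.5
  pos <- pmin(pmax(pos, 1), nIn)
  lo <- pmin(floor(pos), nIn - 1)
  w <- pos - lo
  M <- matrix(0, nOut, nIn)
  M[cbind(seq_len(nOut), lo)] <- M[cbind(seq_len(nOut), lo)] + (1 - w)
  M[cbind(seq_len(nOut), lo + 1)] <- M[cbind(seq_len(nOut), lo + 1)] + w
  M
}

applyAlongAxis <- function(a, M, axis) {
  d <- dim(a)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  ap <- aperm(a, perm)
  m <- M %*% matrix(ap, nrow = d[axis])
  dNew <- d
  dNew[axis] <- nrow(M)
  out <- array(m, dim = dNew[perm])
  aperm(out, order(perm))
}

#' Resize an array by separable linear interpolation
#'
#' @param a numeric array (2-D or 3-D).
#' @param newDim target dimensions.
#' @return Array of dimension \code{newDim}.
#' @export
resizeArray <- function(a, newDim) {
  d <- dim(a)
  stopifnot(length(d) == length(newDim))
  for (ax in seq_along(d)) {
    if (d[ax] != newDim[ax]) {
      a <- applyAlongAxis(a, interpMatrix(dim(a)[ax], newDim[ax]), ax)
    }
  }
  a
}

## interval intersection; NULL when empty
intersectInterval <- function(a, b) {
  lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
  if (lo >= hi) NULL else c(lo, hi)
}
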