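# Ensemble aggregation: Otsu binarization of the mean probability map and
# pixel-wise entropy of the discretized ensemble predictions.

#' Otsu's threshold of a probability map
#'
#' Global histogram threshold maximizing the between-class variance over a
#' \code{bins}-bin histogram of the map's values.  Ties are broken toward
#' the lower threshold.  The returned threshold is the upper edge of the
#' background class, on the scale of the input map.
#'
#' @param map numeric matrix (e.g. the ensemble mean probability map).
#' @param bins number of histogram bins (default 256).
#' @return a list with elements \code{value} (the threshold), \code{bins},
#'   and \code{source = "mean_map"}.
#' @section Degenerate input: a constant map carries no threshold
#'   information; a condition of class \code{sphereseg_degenerate_map} is
#'   signalled, which [binarizeEnsemble()] maps to an all-background mask.
#' @examples
#' m <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
#' otsuThreshold(m)$value
#' @export
otsuThreshold <- function(map, bins = 256L) {
  v <- as.numeric(map)
  if (any(!is.finite(v))) stop("map contains non-finite values")
  lo <- min(v); hi <- max(v)
  if (hi - lo <= .Machine$double.eps * max(abs(hi), 1)) {
    cond <- structure(
      class = c("sphereseg_degenerate_map", "error", "condition"),
      list(message = "constant map: no threshold information (no tumour evidence)",
           call = sys.call()))
    stop(cond)
  }
  edges <- seq(lo, hi, length.out = bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), bins),
    nbins = bins)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  n <- length(v)
  w0 <- cumsum(counts) / n
  mu0cum <- cumsum(counts * centers) / n
  muT <- mu0cum[bins]
  # between-class variance for a cut after bin t (t = 1..bins-1)
  t <- seq_len(bins - 1L)
  w0t <- w0[t]; w1t <- 1 - w0t
  valid <- w0t > 0 & w1t > 0
  sigmaB <- rep(-Inf, bins - 1L)
  sigmaB[valid] <- (muT * w0t[valid] - mu0cum[t][valid])^2 /
    (w0t[valid] * w1t[valid])
  best <- which.max(sigmaB)          # first max = lower threshold on ties
  list(value = edges[best + 1L], bins = as.integer(bins),
       source = "mean_map")
}

#' Pixel-wise mean of an ensemble stack
#'
#' @param stack a \linkS4class{ProbabilityStack}.
#' @return rows x cols matrix of mean probabilities.
#' @export
stackMean <- function(stack) {
  stopifnot(is(stack, "ProbabilityStack"))
  m <- stack@maps
  matrix(colMeans(matrix(m, dim(m)[1], dim(m)[2] * dim(m)[3])),
         dim(m)[2], dim(m)[3])
}

#' Binarize an ensemble by Otsu's method
#'
#' Computes the mean of the k probability maps, derives a global Otsu
#' threshold T from the mean map, and returns the final segmentation
#' \code{Z(i,j) = 1} iff the mean at (i,j) exceeds T.  The threshold is
#' computed on the same (mean) scale that is compared against it.
#'
#' @param stack a \linkS4class{ProbabilityStack}.
#' @param bins Otsu histogram bins (default 256).
#' @return list with \code{mask} (rows x cols 0/1 matrix) and
#'   \code{threshold} (as returned by [otsuThreshold()]; value NA for a
#'   degenerate constant mean map, which yields an all-background mask
#'   with a warning).
#' @export
binarizeEnsemble <- function(stack, bins = 256L) {
  mean_map <- stackMean(stack)
  thr <- tryCatch(otsuThreshold(mean_map, bins),
    sphereseg_degenerate_map = function(e) {
      warning("degenerate (constant) mean map: returning all-background mask")
      list(value = NA_real_, bins = as.integer(bins), source = "mean_map")
    })
  if (is.na(thr$value)) {
    mask <- matrix(0L, nrow(mean_map), ncol(mean_map))
  } else {
    mask <- matrix(as.integer(mean_map > thr$value),
                   nrow(mean_map), ncol(mean_map))
  }
  list(mask = mask, threshold = thr)
}

#' Pixel-wise entropy uncertainty of an ensemble
#'
#' For each pixel, the k ensemble probabilities are discretized into
#' \code{valueBins} classes over [0, 1], empirical class frequencies
#' \code{p_v} are formed over the k predictions, and the Shannon entropy
#' \code{U = -sum_v p_v log(p_v)} (nats) is returned, together with its
#' normalization to [0, 100] by the fixed theoretical maximum
#' \code{log(min(k, valueBins))}.
#'
#' The default \code{valueBins = 2} binarizes each map at 0.5, so U
#' measures the disagreement in the ensemble's tumour/background vote:
#' 0 when all k members agree, \code{log(2)} for an even split.
#'
#' @param stack a \linkS4class{ProbabilityStack}.
#' @param valueBins number of discretization classes (>= 2, default 2).
#' @return an \linkS4class{UncertaintyMap}.
#' @examples
#' maps <- array(c(1, 1, 0, 0), c(4, 1, 1))  # 2 votes each way
#' st <- new("ProbabilityStack", maps = maps,
#'           centers = new("ProjectionCenters",
#'                         centers = matrix(numeric(), 0, 2),
#'                         planarSize = 1L),
#'           sourceId = "toy")
#' pixelData(entropyMap(st))  # log(2)
#' @export
entropyMap <- function(stack, valueBins = 2L) {
  stopifnot(is(stack, "ProbabilityStack"), valueBins >= 2)
  m <- stack@maps
  k <- dim(m)[1]
  npix <- dim(m)[2] * dim(m)[3]
  flat <- matrix(m, k, npix)
  # class index in 0..valueBins-1; bin b covers [b/B, (b+1)/B), last closed
  idx <- pmin(floor(flat * valueBins), valueBins - 1L)
  H <- numeric(npix)
  for (b in 0:(valueBins - 1L)) {
    p <- .colSumsFast(idx == b, k, npix) / k
    nz <- p > 0
    H[nz] <- H[nz] - p[nz] * log(p[nz])
  }
  H[H < 0] <- 0
  ent <- matrix(H, dim(m)[2], dim(m)[3])
  hmax <- log(min(k, valueBins))
  norm <- if (hmax > 0) 100 * ent / hmax else ent * 0
  norm[norm > 100] <- 100
  new("UncertaintyMap", entropy = ent, normalized = norm,
      valueBins = as.integer(valueBins), support = as.integer(k))
}

.colSumsFast <- function(x, nr, nc) {
  if (nr == 1) as.numeric(x) else colSums(x)
}

#' Re-normalize an uncertainty map to [0, 100]
#'
#' Applies the fixed theoretical-maximum scaling
#' \code{100 * entropy / log(min(k, valueBins))}.  Idempotent; provided so
#' maps assembled from raw entropies can be brought onto the tau scale
#' used by [uscoreCurves()].
#'
#' @param map an \linkS4class{UncertaintyMap}.
#' @return the map with its \code{normalized} slot recomputed.
#' @export
normalizeUncertainty <- function(map) {
  stopifnot(is(map, "UncertaintyMap"))
  hmax <- log(min(map@support, map@valueBins))
  norm <- if (hmax > 0) 100 * map@entropy / hmax else map@entropy * 0
  norm[norm > 100] <- 100
  norm[norm < 0] <- 0
  initialize(map, normalized = norm)
}
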