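#' Structural similarity index (SSIM)
#'
#' Mean structural similarity between two single-channel images, using
#' the standard 11 x 11 Gaussian window (sigma = 1.5) and stabilizers
#' \code{C1 = (K1 L)^2}, \code{C2 = (K2 L)^2} with \code{K1 = 0.01},
#' \code{K2 = 0.03} and \code{L} the dynamic range.  Used here to
#' quantify round-trip degradation of the spherical projection.
#'
#' @param x,y numeric matrices of identical shape.
#' @param dataRange dynamic range L; defaults to the joint range of the
#'   inputs.
#' @param margin number of border pixels excluded from the mean (the
#'   projection fills out-of-domain samples near the border; default 0).
#' @return mean SSIM in [-1, 1].
#' @export
ssim <- function(x, y, dataRange = NULL, margin = 0L) {
  stopifnot(identical(dim(x), dim(y)))
  if (is.null(dataRange)) dataRange <- max(diff(range(x, y)), .Machine$double.eps)
  K1 <- 0.01; K2 <- 0.03
  C1 <- (K1 * dataRange)^2; C2 <- (K2 * dataRange)^2
  g <- outer(stats::dnorm(-5:5, sd = 1.5), stats::dnorm(-5:5, sd = 1.5))
  g <- g / sum(g)
  f <- function(m) EBImage::filter2(m, g, boundary = "replicate")
  mx <- f(x); my <- f(y)
  sxx <- f(x * x) - mx^2; syy <- f(y * y) - my^2; sxy <- f(x * y) - mx * my
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  if (margin > 0) {
    nr <- nrow(s); nc <- ncol(s)
    s <- s[(margin + 1):(nr - margin), (margin + 1):(nc - margin)]
  }
  mean(s)
}
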