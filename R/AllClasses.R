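#' @import methods
#' @importFrom stats rnorm runif quantile sd setNames
#' @importFrom utils head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib sphereseg, .registration = TRUE
NULL

#' Spherical projection geometry
#'
#' Describes the sphere/plane configuration governing the nonlinear
#' projection: a sphere of radius \code{r} centred at the origin \code{O},
#' with the image plane orthogonal to the pole axis at distance \code{d}
#' from \code{O} and spanning \code{[-h, h]} on each side.  Planar points
#' are projected onto the sphere along the ray from \code{O}, so local
#' scale is maximal on the pole axis (the projection centre) and falls off
#' with in-plane radial distance.  The spherical surface patch is laid out
#' on a Cartesian grid by azimuthal-equidistant coordinates about the pole
#' axis (grid radius proportional to polar angle, grid angle equal to
#' azimuth).
#'
#' The default design \code{h = 0.5, r = 1, d = 0.3} is the configuration
#' with the smallest round-trip image-quality degradation among the
#' designs considered for this family of methods.
#'
#' @slot h positive half-extent of the planar image in sphere units.
#' @slot r positive sphere radius (sphere units).
#' @slot d positive distance from the sphere centre to the image plane;
#'   must satisfy \code{d < r} so rays through plane points exit the
#'   sphere.
#' @slot sphericalSize side length, in pixels, of the spherical-grid image.
#' @slot planarSize side length, in pixels, of the planar image.
#' @slot interpolationOrder 0 (nearest neighbour) or 1 (bilinear).
#' @slot fillValue intensity used for samples falling outside the source
#'   image domain.
#'
#' @seealso [projectionGeometry()] for the user-facing constructor,
#'   [forwardProject()], [backwardProject()], [localScaleMap()].
#' @exportClass ProjectionGeometry
setClass("ProjectionGeometry",
  representation(
    h = "numeric", r = "numeric", d = "numeric",
    sphericalSize = "integer", planarSize = "integer",
    interpolationOrder = "integer", fillValue = "numeric"
  ),
  prototype(
    h = 0.5, r = 1, d = 0.3,
    sphericalSize = 256L, planarSize = 192L,
    interpolationOrder = 1L, fillValue = 0
  )
)

setValidity("ProjectionGeometry", function(object) {
  msg <- character()
  if (length(object@h) != 1 || !is.finite(object@h) || object@h <= 0)
    msg <- c(msg, "'h' (plane half-width) must be a single positive number")
  if (length(object@r) != 1 || !is.finite(object@r) || object@r <= 0)
    msg <- c(msg, "'r' (sphere radius) must be a single positive number")
  if (length(object@d) != 1 || !is.finite(object@d) || object@d <= 0)
    msg <- c(msg, "'d' (plane distance) must be a single positive number")
  if (length(object@d) == 1 && length(object@r) == 1 &&
      is.finite(object@d) && is.finite(object@r) && object@d >= object@r)
    msg <- c(msg, "'d' must be < 'r' (image plane must lie inside the sphere)")
  if (object@sphericalSize < 2L) msg <- c(msg, "'sphericalSize' must be >= 2")
  if (object@planarSize < 2L) msg <- c(msg, "'planarSize' must be >= 2")
  if (!object@interpolationOrder %in% c(0L, 1L))
    msg <- c(msg, "'interpolationOrder' must be 0 (nearest) or 1 (bilinear)")
  if (length(msg)) msg else TRUE
})

#' Construct a projection geometry
#'
#' @param h,r,d sphere design parameters (see [ProjectionGeometry-class]);
#'   defaults \code{(0.5, 1, 0.3)}.
#' @param sphericalSize pixels per side of the spherical-grid image
#'   (default 256).
#' @param planarSize pixels per side of the planar image (default 192).
#' @param interpolationOrder 0 = nearest neighbour, 1 = bilinear
#'   (default 1; masks should use 0).
#' @param fillValue value assigned to out-of-domain samples (default 0).
#' @return a validated \linkS4class{ProjectionGeometry}.
#' @examples
#' geom <- projectionGeometry()
#' geom
#' @export
projectionGeometry <- function(h = 0.5, r = 1, d = 0.3,
                               sphericalSize = 256L, planarSize = 192L,
                               interpolationOrder = 1L, fillValue = 0) {
  new("ProjectionGeometry",
    h = as.numeric(h), r = as.numeric(r), d = as.numeric(d),
    sphericalSize = as.integer(sphericalSize),
    planarSize = as.integer(planarSize),
    interpolationOrder = as.integer(interpolationOrder),
    fillValue = as.numeric(fillValue))
}

setMethod("show", "ProjectionGeometry", function(object) {
  cat("ProjectionGeometry\n")
  cat(sprintf("  sphere: h = %g, r = %g, d = %g\n",
    object@h, object@r, object@d))
  cat(sprintf("  grids: planar %d^2 -> spherical %d^2\n",
    object@planarSize, object@sphericalSize))
  cat(sprintf("  interpolation order %d, fill value %g\n",
    object@interpolationOrder, object@fillValue))
})

#' Set of projection centres
#'
#' An ordered set of k planar pixel locations used as projection centres
#' for the ensemble.  Coordinates are 0-based pixel-centre (row, col).
#'
#' @slot centers k x 2 numeric matrix, columns \code{row}, \code{col}.
#' @slot planarSize side length of the planar grid the centres live on.
#' @seealso [makeCenterGrid()]
#' @exportClass ProjectionCenters
setClass("ProjectionCenters",
  representation(centers = "matrix", planarSize = "integer"))

setValidity("ProjectionCenters", function(object) {
  ctr <- object@centers
  n <- object@planarSize
  if (ncol(ctr) != 2)
    return("'centers' must be a numeric k x 2 matrix (row, col)")
  if (nrow(ctr) == 0) return(TRUE)  # empty set: stack not built by projection
  if (any(!is.finite(ctr))) return("centres must be finite")
  if (any(ctr < 0) || any(ctr > n - 1))
    return("centres must lie inside the planar grid [0, planarSize - 1]")
  if (anyDuplicated(ctr)) return("centres must be distinct")
  TRUE
})

setMethod("show", "ProjectionCenters", function(object) {
  cat(sprintf("ProjectionCenters: k = %d on a %d^2 grid\n",
    nrow(object@centers), object@planarSize))
  cat(sprintf("  row range [%g, %g], col range [%g, %g]\n",
    min(object@centers[, 1]), max(object@centers[, 1]),
    min(object@centers[, 2]), max(object@centers[, 2])))
})

#' Number of projection centres / ensemble members
#' @param x a \linkS4class{ProjectionCenters} or
#'   \linkS4class{ProbabilityStack}.
#' @return integer k.
#' @export
setGeneric("nCenters", function(x) standardGeneric("nCenters"))

#' @rdname nCenters
#' @export
setMethod("nCenters", "ProjectionCenters", function(x) nrow(x@centers))

#' Centre coordinates
#' @param x a \linkS4class{ProjectionCenters} or \linkS4class{SphericalImage}.
#' @return numeric matrix (k x 2) or length-2 vector of (row, col).
#' @export
setGeneric("centerCoords", function(x) standardGeneric("centerCoords"))

#' @rdname centerCoords
#' @export
setMethod("centerCoords", "ProjectionCenters", function(x) x@centers)

#' Spherically projected image
#'
#' A planar image resampled onto the azimuthal-equidistant spherical grid,
#' carrying the geometry and projection centre needed to invert the
#' transform.
#'
#' @slot pixels array \code{sphericalSize x sphericalSize [x channels]}.
#' @slot center length-2 numeric, the planar (row, col) projection centre.
#' @slot geometry the \linkS4class{ProjectionGeometry} used.
#' @seealso [forwardProject()], [backwardProject()]
#' @exportClass SphericalImage
setClass("SphericalImage",
  representation(pixels = "array", center = "numeric",
                 geometry = "ProjectionGeometry"))

setValidity("SphericalImage", function(object) {
  d <- dim(object@pixels)
  s <- object@geometry@sphericalSize
  if (!length(d) %in% c(2, 3)) return("'pixels' must be a 2D or 3D array")
  if (d[1] != s || d[2] != s)
    return(sprintf("pixel grid %dx%d does not match sphericalSize %d",
                   d[1], d[2], s))
  if (length(object@center) != 2 || any(!is.finite(object@center)))
    return("'center' must be a finite (row, col) pair")
  TRUE
})

setMethod("show", "SphericalImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SphericalImage: %d x %d x %d, centre (%g, %g)\n",
    d[1], d[2], if (length(d) == 3) d[3] else 1L,
    object@center[1], object@center[2]))
})

#' @rdname centerCoords
#' @export
setMethod("centerCoords", "SphericalImage", function(x) x@center)

#' Pixel data accessor
#' @param x an object carrying an image array.
#' @return the underlying numeric array.
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname pixelData
#' @export
setMethod("pixelData", "SphericalImage", function(x) x@pixels)

#' Ensemble probability stack
#'
#' The k backward-projected per-pixel tumour-probability maps produced by
#' running the predictor on each projection of a slice, co-registered on
#' the planar grid.
#'
#' @slot maps array \code{k x rows x cols} of probabilities in [0, 1].
#' @slot centers the \linkS4class{ProjectionCenters} the maps correspond
#'   to, in order (may have 0 rows for stacks not produced by projection,
#'   e.g. test-time augmentation).
#' @slot sourceId character identifier of the source slice.
#' @seealso [runSPUNet()], [stackMean()], [binarizeEnsemble()],
#'   [entropyMap()]
#' @exportClass ProbabilityStack
setClass("ProbabilityStack",
  representation(maps = "array", centers = "ProjectionCenters",
                 sourceId = "character"))

setValidity("ProbabilityStack", function(object) {
  d <- dim(object@maps)
  if (length(d) != 3) return("'maps' must be a k x rows x cols array")
  if (d[1] < 1) return("stack must contain at least one map")
  rng <- range(object@maps)
  if (!all(is.finite(rng))) return("probabilities must be finite")
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("probabilities must lie in [0, 1]")
  k <- nrow(object@centers@centers)
  if (k > 0 && k != d[1])
    return("number of maps must equal number of centres")
  TRUE
})

setMethod("show", "ProbabilityStack", function(object) {
  d <- dim(object@maps)
  cat(sprintf("ProbabilityStack: k = %d maps of %d x %d (source '%s')\n",
    d[1], d[2], d[3], object@sourceId))
  cat(sprintf("  probability range [%.3f, %.3f]\n",
    min(object@maps), max(object@maps)))
})

#' @rdname nCenters
#' @export
setMethod("nCenters", "ProbabilityStack", function(x) dim(x@maps)[1])

#' @rdname pixelData
#' @export
setMethod("pixelData", "ProbabilityStack", function(x) x@maps)

#' Pixel-wise uncertainty map
#'
#' Shannon entropy (nats) of the discretized ensemble predictions at each
#' pixel, together with its fixed-scale normalization to [0, 100] used for
#' tau-thresholding in the uncertainty score.  The normalization divides
#' by the theoretical maximum \code{log(min(k, valueBins))} rather than by
#' a per-slice maximum, so thresholds are comparable across slices.
#'
#' @slot entropy rows x cols matrix, entropy in nats, >= 0.
#' @slot normalized rows x cols matrix in [0, 100].
#' @slot valueBins number of discretization classes used.
#' @slot support k, the number of ensemble members.
#' @seealso [entropyMap()], [normalizeUncertainty()], [uscoreCurves()]
#' @exportClass UncertaintyMap
setClass("UncertaintyMap",
  representation(entropy = "matrix", normalized = "matrix",
                 valueBins = "integer", support = "integer"))

setValidity("UncertaintyMap", function(object) {
  if (any(object@entropy < -1e-12)) return("entropy must be >= 0")
  hmax <- log(min(object@support, object@valueBins))
  if (hmax > 0 && max(object@entropy) > hmax + 1e-9)
    return("entropy exceeds log(min(k, valueBins))")
  if (length(object@normalized) &&
      (min(object@normalized) < -1e-9 || max(object@normalized) > 100 + 1e-9))
    return("normalized uncertainty must lie in [0, 100]")
  if (!identical(dim(object@entropy), dim(object@normalized)))
    return("entropy and normalized maps must have identical shape")
  TRUE
})

setMethod("show", "UncertaintyMap", function(object) {
  cat(sprintf(
    "UncertaintyMap: %d x %d, k = %d, %d value bins\n",
    nrow(object@entropy), ncol(object@entropy),
    object@support, object@valueBins))
  cat(sprintf("  entropy range [%.4f, %.4f] nats (max attainable %.4f)\n",
    min(object@entropy), max(object@entropy),
    log(min(object@support, object@valueBins))))
})

#' @rdname pixelData
#' @export
setMethod("pixelData", "UncertaintyMap", function(x) x@entropy)

#' Normalized (0-100) uncertainty accessor
#' @param x an \linkS4class{UncertaintyMap}.
#' @return rows x cols matrix in [0, 100].
#' @export
setGeneric("normalizedUncertainty",
  function(x) standardGeneric("normalizedUncertainty"))

#' @rdname normalizedUncertainty
#' @export
setMethod("normalizedUncertainty", "UncertaintyMap",
  function(x) x@normalized)

#' Pluggable probabilistic segmenter
#'
#' The contract every backbone must satisfy: \code{predictFun} maps a
#' 2-channel (or 1-channel) 2D array to a probability map in [0, 1] of the
#' same spatial shape, deterministically for a fixed seed.
#'
#' @slot predictFun function(image array) -> probability matrix.
#' @slot inputSize expected square input side in pixels (NA = any).
#' @slot name human-readable backbone description.
#' @slot model backbone state (an environment for the trainable reference
#'   U-Net, NULL for analytic mocks).
#' @seealso [buildReferenceUNet()], [mockPredictor()], [predictProbability()]
#' @exportClass SegPredictor
setClass("SegPredictor",
  representation(predictFun = "function", inputSize = "integer",
                 name = "character", model = "ANY"),
  prototype(model = NULL))

setMethod("show", "SegPredictor", function(object) {
  cat(sprintf("SegPredictor: %s (input %s)\n", object@name,
    if (is.na(object@inputSize)) "any size"
    else sprintf("%d^2", object@inputSize)))
})

#' Apply a predictor to one image
#'
#' Runs the backbone on a single slice and checks the output contract
#' (shape preserved, values in [0, 1]).
#'
#' @param predictor a \linkS4class{SegPredictor}.
#' @param image 2D matrix or rows x cols x channels array.
#' @return probability matrix with the spatial shape of \code{image}.
#' @export
predictProbability <- function(predictor, image) {
  stopifnot(is(predictor, "SegPredictor"))
  p <- predictor@predictFun(image)
  sp <- dim(image)[1:2]
  if (!identical(dim(p)[1:2], sp))
    stop("predictor violated contract: output shape != input shape")
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9)
    stop("predictor violated contract: probabilities outside [0, 1]")
  p[p < 0] <- 0; p[p > 1] <- 1
  p
}
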