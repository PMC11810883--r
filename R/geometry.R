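# Spherical projection: planar <-> azimuthal-equidistant spherical grid.
#
# Conventions: 0-based pixel-centre coordinates, (row, col) order.  The
# planar image spans [-h, h]^2 in sphere units relative to the projection
# centre (one plane unit per 2h/(planarSize-1) pixels); a planar point at
# in-plane radius rho maps to polar angle theta = atan(rho / d) along the
# ray from the sphere centre, and the spherical patch is laid out on the
# output grid with grid radius proportional to theta (azimuthal
# equidistant), scaled so the plane-edge midpoint (theta = atan(h/d))
# lands on the grid-edge midpoint.

# planar pixel (row, col) relative to `center` -> plane units (y, x)
.planeUnitsPerPixel <- function(geometry)
  2 * geometry@h / (geometry@planarSize - 1)

# spherical grid units: normalized coords in [-1, 1] across the grid
.sphGridScale <- function(geometry) (geometry@sphericalSize - 1) / 2

#' Map planar pixel coordinates to spherical grid coordinates
#'
#' The coordinate map underlying [backwardProject()]: planar pixel
#' (row, col) positions, taken relative to the projection centre, are
#' converted to polar angle \code{theta = atan(rho / d)} and laid out on
#' the azimuthal-equidistant spherical grid.  Exposed so the mapping (and
#' its Jacobian) can be examined directly.
#'
#' @param coords n x 2 matrix of planar (row, col) pixel coordinates.
#' @param geometry a \linkS4class{ProjectionGeometry}.
#' @param center length-2 planar (row, col) projection centre.
#' @return n x 2 matrix of spherical-grid (row, col) pixel coordinates.
#' @seealso [sphericalToPlanarCoords()] for the inverse,
#'   [localScaleMap()] for the areal Jacobian.
#' @export
planarToSphericalCoords <- function(coords, geometry, center) {
  coords <- .asCoordMatrix(coords)
  su <- .planeUnitsPerPixel(geometry)
  y <- (coords[, 1] - center[1]) * su
  x <- (coords[, 2] - center[2]) * su
  rho <- sqrt(x^2 + y^2)
  theta <- atan2(rho, geometry@d)
  thetaEdge <- atan2(geometry@h, geometry@d)
  R <- theta / thetaEdge                      # normalized grid radius
  # R/rho has limit 1/(d * thetaEdge) as rho -> 0 (theta ~ rho/d)
  scale <- ifelse(rho > 0, R / rho, 1 / (geometry@d * thetaEdge))
  gs <- .sphGridScale(geometry)
  c0 <- (geometry@sphericalSize - 1) / 2
  cbind(row = c0 + y * scale * gs, col = c0 + x * scale * gs)
}

#' Map spherical grid coordinates to planar pixel coordinates
#'
#' Inverse of [planarToSphericalCoords()]: grid radius is converted back
#' to polar angle, then to in-plane radius \code{rho = d * tan(theta)}.
#' Grid points whose polar angle reaches pi/2 have no planar preimage and
#' come back as NA.
#'
#' @inheritParams planarToSphericalCoords
#' @param coords n x 2 matrix of spherical-grid (row, col) coordinates.
#' @return n x 2 matrix of planar (row, col) pixel coordinates (NA where
#'   the ray never meets the plane).
#' @export
sphericalToPlanarCoords <- function(coords, geometry, center) {
  coords <- .asCoordMatrix(coords)
  gs <- .sphGridScale(geometry)
  c0 <- (geometry@sphericalSize - 1) / 2
  Y <- (coords[, 1] - c0) / gs
  X <- (coords[, 2] - c0) / gs
  R <- sqrt(X^2 + Y^2)
  thetaEdge <- atan2(geometry@h, geometry@d)
  theta <- R * thetaEdge
  rho <- ifelse(theta < pi / 2, geometry@d * tan(theta), NA_real_)
  scale <- ifelse(R > 0, rho / R, geometry@d * thetaEdge)
  su <- .planeUnitsPerPixel(geometry)
  cbind(row = center[1] + Y * scale / su, col = center[2] + X * scale / su)
}

.asCoordMatrix <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 2)
  stopifnot(ncol(coords) == 2)
  coords
}

# Vectorized bilinear / nearest sampling of `img` (matrix) at 0-based
# pixel-centre positions; positions outside [0, n-1] take `fill`.
.sampleImage <- function(img, rows, cols, order = 1L, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(rows))
  if (order == 0L) {
    ri <- round(rows); ci <- round(cols)
    ok <- !is.na(ri) & !is.na(ci) & ri >= 0 & ri <= nr - 1 &
      ci >= 0 & ci <= nc - 1
    out[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
  } else {
    ok <- !is.na(rows) & !is.na(cols) & rows >= 0 & rows <= nr - 1 &
      cols >= 0 & cols <= nc - 1
    r <- rows[ok]; c <- cols[ok]
    r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
    fr <- r - r0; fc <- c - c0
    i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r0 + 2, c0 + 1)
    i01 <- cbind(r0 + 1, c0 + 2); i11 <- cbind(r0 + 2, c0 + 2)
    out[ok] <- img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
      img[i01] * (1 - fr) * fc + img[i11] * fr * fc
  }
  out
}

.checkImage <- function(image, geometry = NULL) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (length(dim(image)) != 3)
    stop("image must be a 2D matrix or rows x cols x channels array")
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  if (!is.null(geometry) &&
      (dim(image)[1] != geometry@planarSize ||
       dim(image)[2] != geometry@planarSize))
    stop(sprintf("image is %d x %d but geometry expects %d^2; standardize first",
                 dim(image)[1], dim(image)[2], geometry@planarSize))
  image
}

#' Forward spherical projection
#'
#' Resamples a planar image onto the spherical grid about a projection
#' centre.  Local scale is maximal at the centre (which lands on the grid
#' centre) and decreases monotonically with planar distance from it, so
#' detail near the centre is magnified while the global field of view is
#' retained.  Samples falling outside the planar image take the
#' geometry's fill value; intensities are interpolated, never
#' extrapolated.
#'
#' @param image planar image: rows x cols matrix or rows x cols x channels
#'   array (channels 1 or 2), already standardized to
#'   \code{geometry@planarSize}.
#' @param geometry a \linkS4class{ProjectionGeometry}.
#' @param center length-2 planar (row, col) projection centre, inside the
#'   image.
#' @param order interpolation order override (0 nearest / 1 bilinear);
#'   defaults to the geometry's. Use 0 for binary masks.
#' @return a \linkS4class{SphericalImage}.  A \code{gt} attribute on
#'   \code{image} (a ground-truth mask, as attached by test fixtures) is
#'   projected alongside with nearest-neighbour interpolation and carried
#'   on the result.
#' @examples
#' geom <- projectionGeometry(planarSize = 64, sphericalSize = 96)
#' img <- matrix(rnorm(64^2), 64, 64)
#' sph <- forwardProject(img, geom, c(31.5, 31.5))
#' dim(pixelData(sph))
#' @export
forwardProject <- function(image, geometry, center,
                           order = geometry@interpolationOrder) {
  image <- .checkImage(image, geometry)
  gt <- attr(image, "gt")
  n <- geometry@planarSize
  if (length(center) != 2 || any(center < 0) || any(center > n - 1))
    stop("projection centre must lie inside the image [0, planarSize - 1]")
  s <- geometry@sphericalSize
  grid <- cbind(rep(0:(s - 1), times = s), rep(0:(s - 1), each = s))
  src <- sphericalToPlanarCoords(grid, geometry, center)
  out <- array(0, c(s, s, dim(image)[3]))
  for (ch in seq_len(dim(image)[3]))
    out[, , ch] <- matrix(.sampleImage(image[, , ch], src[, 1], src[, 2],
      order, geometry@fillValue), s, s)
  res <- new("SphericalImage", pixels = out, center = as.numeric(center),
             geometry = geometry)
  if (!is.null(gt)) {
    pg <- matrix(.sampleImage(gt, src[, 1], src[, 2], 0L, 0), s, s)
    attr(res@pixels, "gt") <- pg
  }
  res
}

#' Backward spherical projection
#'
#' Inverse of [forwardProject()]: resamples a spherical-grid image back
#' onto the planar grid using the geometry and projection centre carried
#' by the input.  The composed coordinate map is the exact analytic
#' inverse, so the round trip is lossless up to interpolation error.
#'
#' @param spherical a \linkS4class{SphericalImage}, or a plain array
#'   accompanied by \code{geometry} and \code{center}.
#' @param geometry,center required only when \code{spherical} is a bare
#'   array.
#' @param order interpolation order override (0 / 1).
#' @return planar rows x cols matrix (single channel) or
#'   rows x cols x channels array.
#' @export
backwardProject <- function(spherical, geometry = NULL, center = NULL,
                            order = NULL) {
  if (is(spherical, "SphericalImage")) {
    geometry <- spherical@geometry
    center <- spherical@center
    pix <- spherical@pixels
  } else {
    if (is.null(geometry) || is.null(center))
      stop("a bare array needs explicit 'geometry' and 'center' metadata")
    pix <- spherical
  }
  if (is.null(order)) order <- geometry@interpolationOrder
  if (is.matrix(pix)) pix <- array(pix, c(dim(pix), 1L))
  n <- geometry@planarSize
  grid <- cbind(rep(0:(n - 1), times = n), rep(0:(n - 1), each = n))
  src <- planarToSphericalCoords(grid, geometry, center)
  out <- array(0, c(n, n, dim(pix)[3]))
  for (ch in seq_len(dim(pix)[3]))
    out[, , ch] <- matrix(.sampleImage(pix[, , ch], src[, 1], src[, 2],
      order, geometry@fillValue), n, n)
  if (dim(out)[3] == 1L) out[, , 1] else out
}

#' Uniform lattice of projection centres
#'
#' Generates a sqrt(count) x sqrt(count) Cartesian lattice of projection
#' centres, symmetric about the image centre and spanning
#' \code{extentFraction} of the image side.  \code{count = 1} returns the
#' image centre alone.
#'
#' @param planarSize side length of the planar grid in pixels.
#' @param count number of centres; must be 1 or a perfect square.
#' @param extentFraction fraction of the image side the lattice spans
#'   (default 0.5: the central half of the field of view).
#' @return a \linkS4class{ProjectionCenters}.
#' @examples
#' makeCenterGrid(192, 9)
#' @export
makeCenterGrid <- function(planarSize, count, extentFraction = 0.5) {
  stopifnot(planarSize >= 2, count >= 1,
            extentFraction > 0, extentFraction <= 1)
  mid <- (planarSize - 1) / 2
  if (count == 1) {
    ctr <- cbind(row = mid, col = mid)
  } else {
    side <- sqrt(count)
    if (side != round(side))
      stop(sprintf(
        "count = %d is not a perfect square; nearest squares are %d and %d",
        count, floor(side)^2, ceiling(side)^2))
    side <- as.integer(round(side))
    half <- extentFraction * (planarSize - 1) / 2
    ax <- seq(mid - half, mid + half, length.out = side)
    ctr <- cbind(row = rep(ax, times = side), col = rep(ax, each = side))
  }
  new("ProjectionCenters", centers = ctr,
      planarSize = as.integer(planarSize))
}

#' Local magnification map of the projection
#'
#' Per-planar-pixel magnitude of the areal Jacobian determinant of the
#' planar-to-spherical coordinate map (spherical grid pixels per planar
#' pixel).  Strictly positive, maximal at the projection centre, and
#' radially symmetric about it; useful for visualizing where the
#' transform magnifies detail.
#'
#' For a plane at distance d, the polar angle obeys
#' \code{dtheta/drho = d / (d^2 + rho^2)}, so magnification decays
#' monotonically with in-plane radius rho.
#'
#' @inheritParams forwardProject
#' @return planarSize x planarSize matrix of Jacobian magnitudes.
#' @export
localScaleMap <- function(geometry, center) {
  n <- geometry@planarSize
  su <- .planeUnitsPerPixel(geometry)
  grid <- cbind(rep(0:(n - 1), times = n), rep(0:(n - 1), each = n))
  y <- (grid[, 1] - center[1]) * su
  x <- (grid[, 2] - center[2]) * su
  rho <- sqrt(x^2 + y^2)
  d <- geometry@d
  thetaEdge <- atan2(geometry@h, d)
  theta <- atan2(rho, d)
  # areal Jacobian in plane units: (dtheta/drho) * (theta / rho), with the
  # rho -> 0 limit (1/d) * (1/d); normalized to grid units via thetaEdge
  # and converted to pixel^2 / pixel^2.
  radial <- d / (d^2 + rho^2)
  tangential <- ifelse(rho > 0, theta / rho, 1 / d)
  gs <- .sphGridScale(geometry)
  matrix(radial * tangential / thetaEdge^2 * (su * gs)^2, n, n)
}
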