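# The core workflow: forward-project the slice about each of k centres,
# segment each spherical image, backward-project the k probability maps
# into a co-registered planar stack.

#' Construct a probability stack
#'
#' @param maps k x rows x cols array of probabilities in [0, 1].
#' @param centers optional \linkS4class{ProjectionCenters} (empty for
#'   stacks not produced by projection, e.g. test-time augmentation).
#' @param sourceId identifier of the source slice.
#' @return a \linkS4class{ProbabilityStack}.
#' @export
probabilityStack <- function(maps, centers = NULL, sourceId = "slice") {
  if (is.null(centers))
    centers <- new("ProjectionCenters",
                   centers = matrix(numeric(), 0, 2),
                   planarSize = max(2L, dim(maps)[2]))
  maps[maps < 0] <- 0; maps[maps > 1] <- 1
  new("ProbabilityStack", maps = maps, centers = centers,
      sourceId = as.character(sourceId))
}

#' Run the spherical-projection ensemble on one slice
#'
#' For each projection centre: forward-project the planar slice onto the
#' spherical grid, apply the predictor, and backward-project the
#' probability map to the planar grid.  The resulting stack of k
#' co-registered maps is the input to [binarizeEnsemble()] and
#' [entropyMap()].  Results are identical to sequential execution by
#' construction and deterministic given the predictor's seed.
#'
#' @param image planar rows x cols x channels array (standardized).
#' @param predictor a \linkS4class{SegPredictor} accepting
#'   \code{geometry@sphericalSize} inputs.
#' @param geometry a \linkS4class{ProjectionGeometry}.
#' @param centers a \linkS4class{ProjectionCenters}.
#' @param sourceId identifier stored on the stack.
#' @return a \linkS4class{ProbabilityStack} of shape k x rows x cols.
#' @examples
#' geom <- projectionGeometry(planarSize = 64L, sphericalSize = 64L)
#' case <- generatePhantom(phantomSpec(gridSize = 64, seed = 3,
#'                                     lesionRadiusRange = c(6, 9),
#'                                     tailLengthRange = c(4, 6)))
#' st <- runSPUNet(case$image, mockPredictor("perfect"), geom,
#'                 makeCenterGrid(64, 4L))
#' st
#' @export
runSPUNet <- function(image, predictor, geometry, centers,
                      sourceId = "slice") {
  stopifnot(is(predictor, "SegPredictor"),
            is(geometry, "ProjectionGeometry"),
            is(centers, "ProjectionCenters"))
  if (!is.na(predictor@inputSize) &&
      predictor@inputSize != geometry@sphericalSize)
    stop(sprintf("predictor expects %d-pixel inputs but geometry produces %d",
                 predictor@inputSize, geometry@sphericalSize))
  image <- .checkImage(image, geometry)
  k <- nCenters(centers)
  n <- geometry@planarSize
  maps <- array(0, c(k, n, n))
  for (i in seq_len(k)) {
    sph <- forwardProject(image, geometry, centers@centers[i, ])
    p <- predictProbability(predictor, sph@pixels)
    m <- backwardProject(p, geometry, centers@centers[i, ], order = 1L)
    m[m < 0] <- 0; m[m > 1] <- 1
    maps[i, , ] <- m
  }
  probabilityStack(maps, centers, sourceId)
}
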