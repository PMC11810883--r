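# Configuration loading and NIfTI slice I/O.

.configDefaults <- function() list(
  geometry = list(h = 0.5, r = 1, d = 0.3, sphericalSize = 256L,
                  planarSize = 192L, interpolationOrder = 1L,
                  fillValue = 0),
  centers = list(count = 121L, extentFraction = 0.5),
  predictor = list(depth = 3L, baseChannels = 6L, epochs = 12L,
                   batchSize = 4L, learningRate = 1e-3, seed = 42L,
                   cropSize = 128L),
  uq = list(valueBins = 2L, otsuBins = 256L),
  scoring = list(spacingMM = 1),
  seed = 1L,
  logLevel = "info")

.mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop(sprintf("unknown configuration key(s): %s",
                 paste0(path, bad, collapse = ", ")))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML configuration and merges it over the package defaults
#' (sphere design \code{h = 0.5, r = 1, d = 0.3}, \code{k = 121} centres,
#' 192-pixel planar and 256-pixel spherical grids).  Unknown keys are
#' rejected with a message listing them; the geometry block is validated
#' (in particular \code{d < r}).
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return nested configuration list of class \code{RunConfig}, with the
#'   validated \linkS4class{ProjectionGeometry} attached as
#'   \code{$geometryObject}.
#' @export
loadConfig <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
  }
  cfg <- .mergeConfig(.configDefaults(), user)
  g <- cfg$geometry
  cfg$geometryObject <- projectionGeometry(
    h = g$h, r = g$r, d = g$d, sphericalSize = g$sphericalSize,
    planarSize = g$planarSize, interpolationOrder = g$interpolationOrder,
    fillValue = g$fillValue)
  structure(cfg, class = "RunConfig")
}

#' Read slice images from a NIfTI file
#'
#' Accepts 2D (one slice), 3D (slices along the third dimension) or 4D
#' (slices x channels) volumes and returns a list of per-slice
#' rows x cols x channels arrays.  Intensities are standardized per slice
#' and channel to zero mean and unit variance unless
#' \code{standardize = FALSE} (use that for masks).  The in-plane pixel
#' spacing is attached as attribute \code{spacingMM}.
#'
#' @param path NIfTI file (.nii or .nii.gz), 1 or 2 channels.
#' @param standardize z-score each slice/channel (default TRUE).
#' @return list of arrays with attribute \code{spacingMM}.
#' @export
readSlices <- function(path, standardize = TRUE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (any(!is.finite(arr))) stop("non-finite voxels in ", path)
  d <- dim(arr)
  if (length(d) == 2) arr <- array(arr, c(d, 1, 1))
  else if (length(d) == 3) arr <- array(arr, c(d, 1))
  d <- dim(arr)
  if (d[4] > 2) stop("expected 1 or 2 channels, found ", d[4])
  spacing <- tryCatch(RNifti::pixdim(img)[1], error = function(e) 1)
  if (!length(spacing) || !is.finite(spacing) || spacing <= 0) spacing <- 1
  out <- lapply(seq_len(d[3]), function(s) {
    sl <- array(arr[, , s, ], c(d[1], d[2], d[4]))
    if (standardize) {
      for (ch in seq_len(d[4])) {
        v <- sl[, , ch]
        mu <- mean(v); sdv <- sd(as.numeric(v))
        sl[, , ch] <- if (sdv > 0) (v - mu) / sdv else v - mu
      }
    }
    attr(sl, "spacingMM") <- spacing
    sl
  })
  attr(out, "spacingMM") <- spacing
  out
}

.stackSlices <- function(x) {
  if (is.matrix(x)) x <- list(x)
  if (is.list(x)) {
    d <- dim(x[[1]])
    arr <- array(0, c(d[1], d[2], length(x)))
    for (i in seq_along(x)) arr[, , i] <- x[[i]]
    arr
  } else x
}

#' Write masks / maps to NIfTI
#'
#' Masks are written as uint8, continuous maps (probabilities,
#' uncertainty) as float32; pixel spacing is recorded in the header.
#'
#' @param x matrix, list of matrices (stacked slice-wise) or 3D array.
#' @param path output file (.nii or .nii.gz).
#' @param spacingMM in-plane pixel spacing in mm.
#' @return the path, invisibly.
#' @export
writeMask <- function(x, path, spacingMM = 1) {
  arr <- .stackSlices(x)
  if (!all(arr %in% c(0, 1))) stop("mask must be binary")
  attr(arr, "pixdim") <- c(spacingMM, spacingMM, 1)
  ni <- RNifti::asNifti(arr, datatype = "uint8")
  RNifti::writeNifti(ni, path, datatype = "uint8")
  invisible(path)
}

#' @rdname writeMask
#' @export
writeMap <- function(x, path, spacingMM = 1) {
  arr <- .stackSlices(x)
  attr(arr, "pixdim") <- c(spacingMM, spacingMM, 1)
  ni <- RNifti::asNifti(arr, datatype = "float")
  RNifti::writeNifti(ni, path, datatype = "float")
  invisible(path)
}

#' Write a provenance record
#'
#' Serializes the configuration, seeds and package version next to a
#' CLI output so deterministic stages can be reproduced bit-for-bit.
#'
#' @param path output JSON path.
#' @param config a \code{RunConfig} (or any list).
#' @param extra named list of additional fields (seeds, inputs).
#' @return the path, invisibly.
#' @export
writeProvenance <- function(path, config, extra = list()) {
  config$geometryObject <- NULL
  rec <- c(list(
    package = "sphereseg",
    version = as.character(utils::packageVersion("sphereseg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config)), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
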