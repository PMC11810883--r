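# End-to-end desk-scale study on synthetic phantoms: generate a cohort,
# train the tiny reference U-Net on spherically projected slices, run the
# projection ensemble on held-out subjects, and score segmentation
# quality and uncertainty behaviour.

.boundaryBand <- function(gt, width = 2L) {
  b <- EBImage::makeBrush(2L * width + 1L, shape = "disc")
  dil <- EBImage::dilate(gt, b)
  ero <- EBImage::erode(gt, b)
  dil > 0 & ero == 0
}

#' Mean uncertainty in the boundary band vs elsewhere
#'
#' Pools normalized uncertainty over all supplied slices and contrasts
#' the mean inside a band of \code{width} pixels around the ground-truth
#' boundary with the mean over all remaining pixels (lesion interior
#' beyond the band plus far exterior).  A well-behaved ensemble
#' concentrates its disagreement at ambiguous boundaries, making this
#' ratio large.
#'
#' @param uncertainties list of \linkS4class{UncertaintyMap} (or 0-100
#'   matrices).
#' @param gts list of binary ground-truth matrices.
#' @param width band half-width in pixels (default 2).
#' @return list with \code{bandMean}, \code{outsideMean}, \code{ratio}.
#' @export
boundaryUncertaintyRatio <- function(uncertainties, gts, width = 2L) {
  stopifnot(length(uncertainties) == length(gts))
  bandVals <- numeric(0); outVals <- numeric(0)
  for (i in seq_along(gts)) {
    u <- uncertainties[[i]]
    if (is(u, "UncertaintyMap")) u <- u@normalized
    band <- .boundaryBand(gts[[i]], width)
    bandVals <- c(bandVals, u[band])
    outVals <- c(outVals, u[!band])
  }
  bm <- mean(bandVals); om <- mean(outVals)
  list(bandMean = bm, outsideMean = om,
       ratio = if (om > 0) bm / om else Inf)
}

#' Desk-scale phantom study of the projection ensemble
#'
#' Runs the whole pipeline on synthetic phantoms: a cohort of
#' \code{nCases} slices is generated and split 7:3 by subject; the
#' reference U-Net is trained on spherically projected training slices
#' (projection centres cycling through the ensemble grid, ground truth
#' projected alongside); the k-centre projection ensemble segments each
#' test slice, is Otsu-binarized, and entropy uncertainty is computed;
#' finally segmentation metrics, the uncertainty score and the
#' boundary-band uncertainty contrast are reported.
#'
#' @param nCases cohort size (slices).
#' @param k ensemble size (perfect square).
#' @param config a \code{RunConfig} from [loadConfig()]; its predictor
#'   block sizes the network and training.
#' @param spec a [phantomSpec()] describing the imaging conditions.
#' @param seed master seed for cohort, split, training and ensemble.
#' @param verbose print progress.
#' @return list with \code{evaluation} (from [evaluateCase()]),
#'   \code{uscoreMean}, \code{boundary} (from
#'   [boundaryUncertaintyRatio()]), \code{trainHistory}, \code{nTrain},
#'   \code{nTest}, and \code{masks}/\code{uncertainties} for the test
#'   slices.
#' @export
runPhantomStudy <- function(nCases = 240L, k = 25L,
                            config = loadConfig(), spec = NULL,
                            seed = 1L, verbose = interactive()) {
  geom <- config$geometryObject
  if (is.null(spec)) spec <- phantomSpec(gridSize = geom@planarSize)
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating %d phantom slices", nCases)
  cohort <- generateCohort(spec, nCases, baseSeed = seed)
  split <- splitCohort(cohort$subject, 0.7, seed = seed + 1L)
  centers <- makeCenterGrid(geom@planarSize, k,
                            config$centers$extentFraction)

  say("projecting %d training slices", length(split$train))
  trainImgs <- vector("list", length(split$train))
  trainMasks <- vector("list", length(split$train))
  for (j in seq_along(split$train)) {
    i <- split$train[j]
    ctr <- centers@centers[(j - 1) %% k + 1, ]
    sph <- forwardProject(cohort$cases[[i]]$image, geom, ctr)
    trainImgs[[j]] <- sph@pixels
    trainMasks[[j]] <- attr(sph@pixels, "gt")
    attr(trainImgs[[j]], "gt") <- NULL
  }

  p <- config$predictor
  tc <- trainConfig(depth = p$depth, baseChannels = p$baseChannels,
                    epochs = p$epochs, batchSize = p$batchSize,
                    learningRate = p$learningRate, seed = seed + 2L,
                    cropSize = p$cropSize)
  say("training reference U-Net (%d epochs on %d slices)",
      tc$epochs, length(trainImgs))
  net <- buildReferenceUNet(tc)
  net <- trainPredictor(net, trainImgs, trainMasks, tc)
  hist <- trainingHistory(net)
  say("final training BCE %.4f", tail(hist$loss, 1))

  nTest <- length(split$test)
  masks <- vector("list", nTest)
  uncs <- vector("list", nTest)
  gts <- vector("list", nTest)
  say("running %d-centre ensemble on %d test slices", k, nTest)
  for (j in seq_len(nTest)) {
    i <- split$test[j]
    case <- cohort$cases[[i]]
    img <- case$image
    attr(img, "gt") <- NULL         # the network must not see the truth
    st <- runSPUNet(img, net, geom, centers,
                    sourceId = sprintf("case%03d", i))
    masks[[j]] <- binarizeEnsemble(st, config$uq$otsuBins)$mask
    uncs[[j]] <- entropyMap(st, config$uq$valueBins)
    gts[[j]] <- case$gt
    if (verbose && j %% 10 == 0) say("  %d / %d slices", j, nTest)
  }

  ev <- evaluateCase(masks, gts, uncertainty = uncs,
                     spacingMM = config$scoring$spacingMM)
  bnd <- boundaryUncertaintyRatio(uncs, gts)
  say("test DSC %.3f, U-score %.3f, boundary uncertainty ratio %.1f",
      ev$aggregate$mean[ev$aggregate$metric == "dsc"],
      ev$uscoreMean, bnd$ratio)
  list(evaluation = ev, uscoreMean = ev$uscoreMean, boundary = bnd,
       trainHistory = hist, nTrain = length(split$train), nTest = nTest,
       masks = masks, uncertainties = uncs, gts = gts,
       predictor = net, centers = centers)
}

#' Compare the projection ensemble with the TTA baseline
#'
#' Runs both the k-centre projection ensemble and the 8-augmentation
#' test-time-augmentation baseline through the identical
#' binarization / uncertainty / scoring path on the supplied slices and
#' returns a side-by-side report (optionally written as JSON).
#'
#' @param images list of planar slices.
#' @param gts list of binary ground-truth masks.
#' @param predictor the shared backbone \linkS4class{SegPredictor}.
#' @param geometry a \linkS4class{ProjectionGeometry}.
#' @param centers a \linkS4class{ProjectionCenters}.
#' @param augmentations TTA transform set (default the 8 standard ones).
#' @param valueBins entropy discretization (default 2).
#' @param jsonPath optional path; when given the report is written as
#'   JSON.
#' @return list with \code{projection} and \code{tta} blocks, each the
#'   metric aggregate plus mean uncertainty score.
#' @export
compareWithTTA <- function(images, gts, predictor, geometry, centers,
                           augmentations = defaultAugmentations(),
                           valueBins = 2L, jsonPath = NULL) {
  runPath <- function(stacks) {
    masks <- lapply(stacks, function(s)
      suppressWarnings(binarizeEnsemble(s)$mask))
    uncs <- lapply(stacks, entropyMap, valueBins = valueBins)
    ev <- evaluateCase(masks, gts, uncertainty = uncs)
    list(aggregate = ev$aggregate, uscoreMean = ev$uscoreMean,
         nFlagged = ev$nFlagged)
  }
  proj <- runPath(lapply(seq_along(images), function(i) {
    img <- images[[i]]; attr(img, "gt") <- NULL
    runSPUNet(img, predictor, geometry, centers)
  }))
  tta <- runPath(lapply(seq_along(images), function(i) {
    img <- images[[i]]; attr(img, "gt") <- NULL
    predictTTA(predictor, img, augmentations)
  }))
  report <- list(projection = proj, tta = tta,
                 k = nCenters(centers),
                 nAugmentations = length(augmentations),
                 nSlices = length(images))
  if (!is.null(jsonPath))
    jsonlite::write_json(report, jsonPath, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  report
}
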