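# Segmentation metrics and the uncertainty score:
# filtered-DSC/FTP/FTN curves over tau = 1..100, their AUCs, and the
# composite U-score; plus accuracy/sensitivity/specificity/Dice and
# mean / 95th-percentile Hausdorff surface distances.

.checkMaskPair <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("prediction and ground truth shapes differ")
  if (any(!(pred %in% c(0, 1))) || any(!(gt %in% c(0, 1))))
    stop("masks must be strictly binary (0/1)")
}

#' Confusion counts between two binary masks
#'
#' @param pred,gt binary matrices of identical shape.
#' @param include optional logical/0-1 matrix selecting the pixels that
#'   enter the tally (all pixels when absent).
#' @return named integer vector \code{c(TP, TN, FP, FN)} summing to the
#'   number of included pixels.
#' @export
confusionCounts <- function(pred, gt, include = NULL) {
  .checkMaskPair(pred, gt)
  if (is.null(include)) include <- TRUE
  else {
    if (!identical(dim(include), dim(gt)))
      stop("inclusion mask shape differs")
    include <- include > 0
  }
  p <- pred == 1; g <- gt == 1
  c(TP = sum(p & g & include), TN = sum(!p & !g & include),
    FP = sum(p & !g & include), FN = sum(!p & g & include))
}

#' Dice similarity coefficient
#'
#' \code{2 TP / (2 TP + FP + FN)} over the included pixels.  When both
#' masks are empty on the included region the DSC is 1 by convention
#' (nothing to segment, nothing segmented).
#'
#' @inheritParams confusionCounts
#' @return DSC in [0, 1].
#' @export
diceCoefficient <- function(pred, gt, include = NULL) {
  cc <- confusionCounts(pred, gt, include)
  denom <- 2 * cc["TP"] + cc["FP"] + cc["FN"]
  if (denom == 0) return(1)
  unname(2 * cc["TP"] / denom)
}

#' Filtered DSC / FTP / FTN curves over uncertainty thresholds
#'
#' For each integer threshold tau in 1..100, pixels with normalized
#' uncertainty \code{U < tau} are retained and the Dice coefficient,
#' true-positive count and true-negative count are computed over the
#' retained pixels; tau = 100 retains every pixel, so \code{TP_100} and
#' \code{TN_100} are the unfiltered counts.  The filtered-out fractions
#' are \code{FTP_tau = (TP_100 - TP_tau) / TP_100} and
#' \code{FTN_tau = (TN_100 - TN_tau) / TN_100}.  Excluded pixels are
#' removed from the evaluation entirely (not reassigned to background).
#'
#' @param pred,gt binary matrices.
#' @param uncertainty an \linkS4class{UncertaintyMap} (its normalized
#'   0-100 slot is used) or a bare matrix already on the 0-100 scale.
#' @return list with \code{tau} (1..100), \code{dsc}, \code{ftp},
#'   \code{ftn}, \code{tp}, \code{tn}, \code{unfiltered = c(TP, TN)} and
#'   \code{degenerate} (TRUE when TP_100 or TN_100 is 0, in which case the
#'   corresponding curve is reported as 0 with a warning).
#' @export
uscoreCurves <- function(pred, gt, uncertainty) {
  u <- if (is(uncertainty, "UncertaintyMap")) uncertainty@normalized
       else uncertainty
  .checkMaskPair(pred, gt)
  if (!identical(dim(u), dim(gt)))
    stop("uncertainty map shape differs")
  p <- pred == 1; g <- gt == 1
  uTP <- u[p & g]; uTN <- u[!p & !g]; uFP <- u[p & !g]; uFN <- u[!p & g]
  tau <- 1:100
  countBelow <- function(x) {
    # counts of x < tau for tau = 1..99; tau = 100 includes everything
    c(vapply(1:99, function(t) sum(x < t), numeric(1)), length(x))
  }
  tp <- countBelow(uTP); tn <- countBelow(uTN)
  fp <- countBelow(uFP); fn <- countBelow(uFN)
  denom <- 2 * tp + fp + fn
  dsc <- ifelse(denom > 0, 2 * tp / denom, 1)
  tp100 <- tp[100]; tn100 <- tn[100]
  degenerate <- tp100 == 0 || tn100 == 0
  ftp <- if (tp100 > 0) (tp100 - tp) / tp100 else rep(0, 100)
  ftn <- if (tn100 > 0) (tn100 - tn) / tn100 else rep(0, 100)
  if (degenerate)
    warning("no unfiltered TP (or TN) pixels: FTP/FTN reported as 0")
  list(tau = tau, dsc = dsc, ftp = ftp, ftn = ftn,
       tp = tp, tn = tn, unfiltered = c(TP = tp100, TN = tn100),
       degenerate = degenerate)
}

.trapz01 <- function(y) {
  # trapezoidal area under y sampled at tau = 1..100 rescaled to x in [0,1]
  x <- (seq_along(y) - 1) / (length(y) - 1)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Composite uncertainty score
#'
#' \code{AUC1} is the area under DSC(tau) (confidence in correct
#' predictions), \code{AUC2} under FTP(tau) and \code{AUC3} under
#' FTN(tau) (confident-correct pixels should not be filtered), each by
#' trapezoidal integration over tau rescaled to [0, 1].  The score is
#' \deqn{U = (AUC_1 + (1 - AUC_2) + (1 - AUC_3)) / 3,}
#' in [0, 1]; 1 is attained by a perfect segmentation with zero
#' uncertainty everywhere.
#'
#' @param curves output of [uscoreCurves()].
#' @return list with \code{auc1}, \code{auc2}, \code{auc3},
#'   \code{uscore}.
#' @export
uscore <- function(curves) {
  auc1 <- .trapz01(curves$dsc)
  auc2 <- .trapz01(curves$ftp)
  auc3 <- .trapz01(curves$ftn)
  list(auc1 = auc1, auc2 = auc2, auc3 = auc3,
       uscore = (auc1 + (1 - auc2) + (1 - auc3)) / 3)
}

#' Boundary (surface) pixels of a binary mask
#'
#' Foreground pixels that are 4-adjacent to at least one background pixel
#' or lie on the image border.
#'
#' @param mask binary matrix.
#' @return n x 2 matrix of 0-based (row, col) coordinates (0 rows for an
#'   empty mask).
#' @export
surfacePoints <- function(mask) {
  stopifnot(all(mask %in% c(0, 1)))
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb <- pad[1:nr, 2:(nc + 1)] * pad[3:(nr + 2), 2:(nc + 1)] *
    pad[2:(nr + 1), 1:nc] * pad[2:(nr + 1), 3:(nc + 2)]
  surf <- core == 1 & nb == 0     # some 4-neighbour (or border pad) is 0
  w <- which(surf, arr.ind = TRUE)
  cbind(row = w[, 1] - 1, col = w[, 2] - 1)
}

.nearestDistances <- function(a, b) {
  # for each point in a (n x 2), distance to nearest point of b (m x 2)
  if (nrow(a) == 0) return(numeric(0))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  jmin <- max.col(-d2, ties.method = "first")
  sqrt(pmax(d2[cbind(seq_len(nrow(d2)), jmin)], 0))
}

#' Mean and 95th-percentile Hausdorff surface distances
#'
#' Pools the directed nearest-surface distances prediction-to-truth and
#' truth-to-prediction; the mean of the pooled distances is the mean
#' Hausdorff distance (mHD) and their 95th percentile (linear
#' interpolation) is HD95.  Pixel distances are scaled by
#' \code{spacingMM} and reported in cm.
#'
#' @param pred,gt binary matrices.
#' @param spacingMM in-plane pixel spacing in mm (default 1).
#' @return list with \code{mhd_cm}, \code{hd95_cm} and \code{flagged}
#'   (TRUE with infinite distances when either mask is empty; flagged
#'   slices are excluded from aggregates by [evaluateCase()]).
#' @export
hausdorffDistances <- function(pred, gt, spacingMM = 1) {
  .checkMaskPair(pred, gt)
  sp <- surfacePoints(pred); sg <- surfacePoints(gt)
  if (nrow(sp) == 0 || nrow(sg) == 0)
    return(list(mhd_cm = Inf, hd95_cm = Inf, flagged = TRUE))
  pooled <- c(.nearestDistances(sp, sg), .nearestDistances(sg, sp))
  pooled <- pooled * spacingMM / 10     # px -> mm -> cm
  list(mhd_cm = mean(pooled),
       hd95_cm = unname(quantile(pooled, 0.95, type = 7)),
       flagged = FALSE)
}

.sliceMetrics <- function(pred, gt, spacingMM) {
  cc <- confusionCounts(pred, gt)
  hd <- hausdorffDistances(pred, gt, spacingMM)
  data.frame(
    accuracy = unname((cc["TP"] + cc["TN"]) / sum(cc)),
    sensitivity = if (cc["TP"] + cc["FN"] > 0)
      unname(cc["TP"] / (cc["TP"] + cc["FN"])) else NA_real_,
    specificity = if (cc["TN"] + cc["FP"] > 0)
      unname(cc["TN"] / (cc["TN"] + cc["FP"])) else NA_real_,
    dsc = diceCoefficient(pred, gt),
    mhd_cm = hd$mhd_cm, hd95_cm = hd$hd95_cm,
    hd_flagged = hd$flagged)
}

#' Evaluate predictions against ground truth
#'
#' Per-slice accuracy, sensitivity, specificity, Dice and Hausdorff
#' distances, aggregated as mean and SD across slices.  Slices with an
#' empty ground truth have undefined sensitivity (recorded as NA and
#' excluded from that aggregate); slices where either mask is empty carry
#' an infinite-distance flag and are excluded from the distance
#' aggregates (the count of such slices is reported).  When uncertainty
#' maps are supplied the filtered-DSC uncertainty score is computed per
#' slice and aggregated alongside.
#'
#' @param pred,gt a binary matrix or a list of binary matrices.
#' @param uncertainty optional \linkS4class{UncertaintyMap} (or list of).
#' @param spacingMM in-plane pixel spacing in mm.
#' @return list with \code{perSlice} (data.frame), \code{aggregate}
#'   (data.frame of mean/sd per metric), \code{nFlagged}, and, when
#'   uncertainty is given, \code{uscorePerSlice} and \code{uscoreMean}.
#' @export
evaluateCase <- function(pred, gt, uncertainty = NULL, spacingMM = 1) {
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(gt)) gt <- list(gt)
  stopifnot(length(pred) == length(gt))
  per <- do.call(rbind, Map(.sliceMetrics, pred, gt,
                            MoreArgs = list(spacingMM = spacingMM)))
  rownames(per) <- NULL
  num <- c("accuracy", "sensitivity", "specificity", "dsc")
  agg <- lapply(per[num], function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  })
  ok <- !per$hd_flagged
  for (dcol in c("mhd_cm", "hd95_cm")) {
    x <- per[[dcol]][ok]
    agg[[dcol]] <- c(mean = if (length(x)) mean(x) else NA_real_,
                     sd = if (length(x) > 1) sd(x) else 0)
  }
  aggregate <- data.frame(metric = names(agg),
                          mean = vapply(agg, `[[`, numeric(1), "mean"),
                          sd = vapply(agg, `[[`, numeric(1), "sd"),
                          row.names = NULL)
  out <- list(perSlice = per, aggregate = aggregate,
              nFlagged = sum(per$hd_flagged))
  if (!is.null(uncertainty)) {
    if (is(uncertainty, "UncertaintyMap") || is.matrix(uncertainty))
      uncertainty <- list(uncertainty)
    us <- mapply(function(p, g, u) {
      uscore(suppressWarnings(uscoreCurves(p, g, u)))$uscore
    }, pred, gt, uncertainty)
    out$uscorePerSlice <- us
    out$uscoreMean <- mean(us)
    out$uscoreSD <- if (length(us) > 1) sd(us) else 0
  }
  out
}
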