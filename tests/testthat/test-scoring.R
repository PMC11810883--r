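# Segmentation metrics, the filtered-DSC curves and the uncertainty score.

test_that("confusion counts and Dice match their definitions", {
  gt <- diskMask(16, 8, 8, 4)
  expect_equal(unname(confusionCounts(gt, gt)),
               c(sum(gt), 256 - sum(gt), 0, 0))
  expect_equal(unname(confusionCounts(1 - gt, gt)),
               c(0, 0, 256 - sum(gt), sum(gt)))
  set.seed(9)
  for (i in 1:10) {
    p <- matrix(rbinom(256, 1, 0.4), 16, 16)
    g <- matrix(rbinom(256, 1, 0.5), 16, 16)
    inc <- if (i %% 2) matrix(rbinom(256, 1, 0.7), 16, 16) else NULL
    expect_equal(confusionCounts(p, g, inc), bruteConfusion(p, g, inc))
  }
  expect_equal(diceCoefficient(gt, gt), 1)
  disjoint <- matrix(0, 16, 16); disjoint[1:2, 1:2] <- 1
  other <- matrix(0, 16, 16); other[10:12, 10:12] <- 1
  expect_equal(diceCoefficient(disjoint, other), 0)
  # |pred| = 4, |gt| = 4, overlap 2 -> 2*2 / (4 + 4)
  a <- matrix(0, 4, 4); a[1, 1:4] <- 1
  b <- matrix(0, 4, 4); b[1, 3:4] <- 1; b[2, 1:2] <- 1
  expect_equal(diceCoefficient(a, b), 0.5)
  expect_equal(diceCoefficient(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  expect_error(confusionCounts(matrix(0, 3, 3), matrix(0, 4, 4)), "shape")
})

test_that("filtered curves match the brute-force per-tau oracle", {
  # zero uncertainty: nothing filtered at any tau
  pred <- diskMask(12, 6, 6, 3); gt <- diskMask(12, 6, 5, 3)
  cv <- uscoreCurves(pred, gt, matrix(0, 12, 12))
  expect_equal(cv$dsc, rep(diceCoefficient(pred, gt), 100))
  expect_equal(cv$ftp, rep(0, 100))
  expect_equal(cv$ftn, rep(0, 100))
  expect_equal(cv$ftp[100], 0)

  # 4x4 worked fixture with structured uncertainty
  p4 <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 1), 4, 4)
  g4 <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0), 4, 4)
  u4 <- matrix(c(5, 10, 95, 0, 20, 80, 15, 3, 50, 99, 1, 7,
                 30, 60, 42, 88), 4, 4)
  cv4 <- uscoreCurves(p4, g4, u4)
  oracle <- bruteCurves(p4, g4, u4)
  expect_equal(cv4$dsc, oracle$dsc)
  expect_equal(cv4$ftp, oracle$ftp)
  expect_equal(cv4$ftn, oracle$ftn)
  expect_equal(unname(cv4$tp), oracle$tp)
  expect_equal(unname(cv4$tn), oracle$tn)

  # random fixtures, including non-integer uncertainties
  set.seed(13)
  for (i in 1:5) {
    p <- matrix(rbinom(100, 1, 0.45), 10, 10)
    g <- matrix(rbinom(100, 1, 0.5), 10, 10)
    u <- matrix(runif(100, 0, 100), 10, 10)
    cv <- suppressWarnings(uscoreCurves(p, g, u))
    oracle <- bruteCurves(p, g, u)
    expect_equal(cv$dsc, oracle$dsc)
    expect_equal(cv$ftp, oracle$ftp)
    expect_equal(cv$ftn, oracle$ftn)
  }
})

test_that("FTP/FTN are non-increasing and curves degrade gracefully", {
  set.seed(14)
  p <- matrix(rbinom(144, 1, 0.4), 12, 12)
  g <- matrix(rbinom(144, 1, 0.5), 12, 12)
  u <- matrix(runif(144, 0, 100), 12, 12)
  cv <- uscoreCurves(p, g, u)
  expect_true(all(diff(cv$ftp) <= 1e-12))
  expect_true(all(diff(cv$ftn) <= 1e-12))
  expect_true(all(cv$ftp >= 0 & cv$ftp <= 1))
  # degenerate: no true positives at all
  expect_warning(
    cvd <- uscoreCurves(matrix(0, 5, 5), diskMask(5, 2, 2, 1),
                        matrix(0, 5, 5)),
    "no unfiltered TP")
  expect_true(cvd$degenerate)
  expect_equal(cvd$ftp, rep(0, 100))
})

test_that("the uncertainty score rewards confident correct predictions", {
  pred <- diskMask(10, 5, 5, 3)
  us <- uscore(uscoreCurves(pred, pred, matrix(0, 10, 10)))
  expect_identical(us$uscore, 1)       # exactly 1, no tolerance
  expect_identical(us$auc1, 1)
  expect_identical(us$auc2, 0)

  # constant curves integrate to their level
  cv <- list(dsc = rep(0.5, 100), ftp = rep(0, 100), ftn = rep(0, 100))
  expect_equal(uscore(cv)$uscore, (0.5 + 1 + 1) / 3, tolerance = 1e-12)

  # trapezoidal AUC against a high-resolution rectangle-rule oracle on the
  # piecewise-linear interpolant
  set.seed(15)
  y <- cumsum(runif(100)); y <- y / max(y)
  fine <- approx(seq(0, 1, length.out = 100), y, n = 2e5)
  expect_equal(uscore(list(dsc = y, ftp = y, ftn = y))$auc1,
               mean(fine$y), tolerance = 1e-6)

  # raising uncertainty only on erroneous pixels never lowers the score
  set.seed(16)
  p <- matrix(rbinom(100, 1, 0.4), 10, 10)
  g <- matrix(rbinom(100, 1, 0.5), 10, 10)
  u <- matrix(runif(100, 0, 50), 10, 10)
  base <- uscore(suppressWarnings(uscoreCurves(p, g, u)))$uscore
  u2 <- u; err <- p != g
  u2[err] <- pmin(u[err] + 40, 100)
  bumped <- uscore(suppressWarnings(uscoreCurves(p, g, u2)))$uscore
  expect_gte(bumped, base - 1e-12)
})

test_that("surface extraction matches the naive neighbourhood scan", {
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_equal(surfacePoints(single), cbind(row = 2, col = 2),
               ignore_attr = TRUE)
  sq <- matrix(0, 8, 8); sq[3:6, 3:6] <- 1
  sp <- surfacePoints(sq)
  expect_equal(nrow(sp), 12)           # 4x4 square: 12 perimeter pixels
  expect_false(any(sp[, 1] == 3 & sp[, 2] == 3))  # interior excluded
  set.seed(17)
  for (i in 1:5) {
    blob <- randomBlob(20, seed = 40 + i)
    a <- surfacePoints(blob); b <- bruteSurface(blob)
    expect_equal(a[order(a[, 1], a[, 2]), , drop = FALSE],
                 unname(b[order(b[, 1], b[, 2]), , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("Hausdorff distances match the all-pairs oracle and its symmetries", {
  g <- diskMask(30, 15, 15, 8)
  expect_equal(hausdorffDistances(g, g)$mhd_cm, 0)
  expect_equal(hausdorffDistances(g, g)$hd95_cm, 0)
  # two single-pixel masks 30 px apart at 1 mm spacing: 3 cm exactly
  a <- matrix(0, 40, 40); a[5, 3] <- 1
  b <- matrix(0, 40, 40); b[5, 33] <- 1
  hd <- hausdorffDistances(a, b)
  expect_equal(hd$mhd_cm, 3)
  expect_equal(hd$hd95_cm, 3)
  # shifted squares and random blobs against the O(n^2) oracle
  sq <- matrix(0, 20, 20); sq[4:12, 4:12] <- 1
  sq3 <- matrix(0, 20, 20); sq3[7:15, 4:12] <- 1
  hd2 <- hausdorffDistances(sq, sq3)
  or2 <- bruteHausdorff(sq, sq3)
  expect_equal(hd2$mhd_cm, or2$mhd_cm, tolerance = 1e-12)
  expect_equal(hd2$hd95_cm, or2$hd95_cm, tolerance = 1e-12)
  set.seed(19)
  for (i in 1:6) {
    p <- randomBlob(24, seed = 60 + i)
    g2 <- randomBlob(24, seed = 80 + i)
    impl <- hausdorffDistances(p, g2)
    oracle <- bruteHausdorff(p, g2)
    expect_equal(impl$mhd_cm, oracle$mhd_cm, tolerance = 1e-12)
    expect_equal(impl$hd95_cm, oracle$hd95_cm, tolerance = 1e-12)
    # symmetry in the arguments
    sym <- hausdorffDistances(g2, p)
    expect_equal(impl$mhd_cm, sym$mhd_cm)
    # invariance under a common integer translation
    pt <- matrix(0, 24, 24); pt[3:24, 1:22] <- p[1:22, 3:24]
    gt2 <- matrix(0, 24, 24); gt2[3:24, 1:22] <- g2[1:22, 3:24]
    if (sum(pt) == sum(p) && sum(gt2) == sum(g2)) {
      tr <- hausdorffDistances(pt, gt2)
      expect_equal(impl$mhd_cm, tr$mhd_cm, tolerance = 1e-12)
    }
  }
  # doubling the pixel spacing doubles the reported distances
  hd1 <- hausdorffDistances(sq, sq3, spacingMM = 1)
  hd2mm <- hausdorffDistances(sq, sq3, spacingMM = 2)
  expect_equal(hd2mm$mhd_cm, 2 * hd1$mhd_cm)
  # empty masks are flagged with infinite distances
  expect_true(hausdorffDistances(matrix(0, 5, 5), g[1:5, 1:5])$flagged)
})

test_that("case evaluation aggregates per-slice metrics correctly", {
  gt <- diskMask(24, 12, 12, 6)
  perfect <- evaluateCase(gt, gt)
  expect_equal(perfect$perSlice$accuracy, 1)
  expect_equal(perfect$perSlice$sensitivity, 1)
  expect_equal(perfect$perSlice$specificity, 1)
  expect_equal(perfect$perSlice$dsc, 1)
  expect_equal(perfect$perSlice$mhd_cm, 0)

  allbg <- evaluateCase(matrix(0, 24, 24), gt)
  expect_equal(allbg$perSlice$sensitivity, 0)
  expect_equal(allbg$perSlice$specificity, 1)
  expect_equal(allbg$nFlagged, 1)      # empty prediction: distances flagged

  # batch of slices: aggregates equal independently computed mean/sd
  set.seed(23)
  preds <- list(); gts <- list()
  for (i in 1:6) {
    gts[[i]] <- randomBlob(20, seed = 200 + i)
    noisyPred <- gts[[i]]
    flip <- sample(400, 30)
    noisyPred[flip] <- 1 - noisyPred[flip]
    preds[[i]] <- noisyPred
  }
  ev <- evaluateCase(preds, gts)
  manual <- sapply(1:6, function(i) diceCoefficient(preds[[i]], gts[[i]]))
  expect_equal(ev$aggregate$mean[ev$aggregate$metric == "dsc"],
               mean(manual), tolerance = 1e-12)
  expect_equal(ev$aggregate$sd[ev$aggregate$metric == "dsc"],
               sd(manual), tolerance = 1e-12)
  manualAcc <- sapply(1:6, function(i) mean(preds[[i]] == gts[[i]]))
  expect_equal(ev$aggregate$mean[ev$aggregate$metric == "accuracy"],
               mean(manualAcc), tolerance = 1e-12)
  # empty ground truth: sensitivity undefined, excluded from aggregates
  ev2 <- evaluateCase(c(preds, list(matrix(0, 20, 20))),
                      c(gts, list(matrix(0, 20, 20))))
  expect_true(is.na(ev2$perSlice$sensitivity[7]))
  expect_equal(ev2$aggregate$mean[ev2$aggregate$metric == "sensitivity"],
               mean(ev$perSlice$sensitivity), tolerance = 1e-12)
})
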