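# Reference U-Net contract, training behaviour, mocks and the TTA stack.

test_that("the network honours the predictor contract at both grid sizes", {
  tc <- trainConfig(depth = 3, baseChannels = 2, seed = 5)
  net <- buildReferenceUNet(tc)
  for (n in c(192L, 256L)) {
    x <- array(rnorm(n * n * 2), c(n, n, 2))
    p <- predictProbability(net, x)
    expect_equal(dim(p), c(n, n))
    expect_gte(min(p), 0)
    expect_lte(max(p), 1)
  }
  # identical seeds give identical outputs; different seeds differ
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  net2 <- buildReferenceUNet(tc)
  expect_identical(predictProbability(net, x), predictProbability(net2, x))
  net3 <- buildReferenceUNet(trainConfig(depth = 3, baseChannels = 2,
                                         seed = 6))
  expect_false(identical(predictProbability(net, x),
                         predictProbability(net3, x)))
  # indivisible input size is a configuration error
  bad <- array(0, c(100, 100, 2))
  expect_error(predictProbability(net, bad), "divisible")
})

test_that("backpropagation matches central finite differences", {
  tc <- trainConfig(depth = 2, baseChannels = 3, seed = 11)
  net <- buildReferenceUNet(tc)@model
  # move biases off zero so no preactivation sits exactly on the ReLU kink
  set.seed(12)
  for (nm in grep("[.]b$", names(net$w), value = TRUE))
    net$w[[nm]] <- rnorm(length(net$w[[nm]]), sd = 0.3)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  y <- matrix(rbinom(256, 1, 0.4), 16, 16)
  fwd <- sphereseg:::.unetForward(net, x, cache = TRUE)
  lg <- sphereseg:::.bceLossGrad(fwd$logit, y)
  g <- sphereseg:::.unetBackward(net, fwd, lg$dlogit)
  lossAt <- function() {
    f <- sphereseg:::.unetForward(net, x)
    sphereseg:::.bceLossGrad(f$logit, y)$loss
  }
  eps <- 1e-6
  for (nm in names(net$w)) {
    p <- net$w[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      orig <- p[i]
      net$w[[nm]][i] <- orig + eps; lp <- lossAt()
      net$w[[nm]][i] <- orig - eps; lm <- lossAt()
      net$w[[nm]][i] <- orig
      fd <- (lp - lm) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss deterministically and learns easy phantoms", {
  cohort <- generateCohort(easyPhantomSpec(96), 40, baseSeed = 77)
  imgs <- lapply(cohort$cases, function(cs) {
    im <- cs$image; attr(im, "gt") <- NULL; im
  })
  gts <- lapply(cohort$cases, `[[`, "gt")
  tc <- trainConfig(depth = 3, baseChannels = 6, epochs = 20, batchSize = 2,
                    seed = 3, cropSize = 64, learningRate = 2e-3)
  net <- trainPredictor(buildReferenceUNet(tc), imgs[1:32], gts[1:32], tc)
  hist <- trainingHistory(net)
  expect_equal(nrow(hist), 20)
  expect_lt(tail(hist$loss, 1), hist$loss[1])
  # determinism: two short runs from scratch give identical weights
  tcd <- trainConfig(depth = 3, baseChannels = 4, epochs = 2, batchSize = 2,
                     seed = 9, cropSize = 64)
  netA <- trainPredictor(buildReferenceUNet(tcd), imgs[1:8], gts[1:8], tcd)
  netB <- trainPredictor(buildReferenceUNet(tcd), imgs[1:8], gts[1:8], tcd)
  expect_identical(netA@model$w, netB@model$w)
  # held-out slices from unseen subjects segment well at the 0.5 threshold
  ds <- sapply(33:40, function(i) {
    p <- (predictProbability(net, imgs[[i]]) >= 0.5) * 1
    diceCoefficient(p, gts[[i]])
  })
  expect_gte(mean(ds), 0.8)
  # error handling
  expect_error(trainPredictor(net, list(), list(), tc), "empty")
  expect_error(trainPredictor(net, imgs[1], list(matrix(0.5, 96, 96)), tc),
               "binary")
  expect_error(trainPredictor(mockPredictor("perfect"), imgs, gts, tc),
               "no trainable model")
})

test_that("mock predictors derive their output from the attached truth", {
  case <- generatePhantom(easyPhantomSpec(96, seed = 4))
  img <- case$image
  expect_identical(predictProbability(mockPredictor("perfect"), img),
                   case$gt * 1)
  # blurred: interior stays high, far exterior stays low
  pb <- predictProbability(mockPredictor("blurred", param = 2), img)
  inner <- EBImage::erode(case$gt, EBImage::makeBrush(7, "disc")) == 1
  outer <- EBImage::dilate(case$gt, EBImage::makeBrush(15, "disc")) == 0
  expect_gt(min(pb[inner]), max(pb[outer]))
  # noisy: reproducible for a fixed seed
  pn1 <- predictProbability(mockPredictor("noisy", 0.2, seed = 8), img)
  pn2 <- predictProbability(mockPredictor("noisy", 0.2, seed = 8), img)
  expect_identical(pn1, pn2)
  expect_gte(min(pn1), 0); expect_lte(max(pn1), 1)
  # missing truth is an error
  bare <- img; attr(bare, "gt") <- NULL
  expect_error(predictProbability(mockPredictor("perfect"), bare), "gt")
})

test_that("TTA stacks invert their transforms exactly", {
  case <- generatePhantom(easyPhantomSpec(96, seed = 14))
  pred <- mockPredictor("perfect")
  idOnly <- defaultAugmentations()[1]
  st1 <- predictTTA(pred, case$image, c(idOnly, idOnly, idOnly))
  expect_equal(dim(pixelData(st1)), c(3L, 96L, 96L))
  expect_identical(pixelData(st1)[1, , ], pixelData(st1)[2, , ])
  expect_identical(pixelData(st1)[1, , ], case$gt * 1)

  augs <- defaultAugmentations()
  expect_length(augs, 8)
  # every rotation/flip inverts exactly on the grid; the perfect mock sees
  # the transformed truth, so the inverse-mapped prediction is the truth
  st8 <- predictTTA(pred, case$image, augs)
  expect_equal(dim(pixelData(st8)), c(8L, 96L, 96L))
  for (i in 1:6)                       # identity + 3 rotations + 2 flips
    expect_identical(pixelData(st8)[i, , ], case$gt * 1)
  # translations lose only the shifted-out border band
  for (i in 7:8) {
    diff <- pixelData(st8)[i, , ] != case$gt
    pos <- which(diff, arr.ind = TRUE)
    if (nrow(pos) > 0)
      expect_true(all(pos <= 8 | pos >= 89))
  }
  expect_gte(min(pixelData(st8)), 0)
  expect_lte(max(pixelData(st8)), 1)
})
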