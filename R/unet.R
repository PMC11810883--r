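# Reference U-Net backbone: encoder of ReLU double-convolutions with 2x2
# max pooling, a double-convolution bottleneck, decoder of 2x2
# transposed convolutions with skip concatenations and double
# convolutions, and a final 1x1 convolution + sigmoid producing the
# per-pixel tumour probability.  Deliberately small: the package's claim
# is the projection/uncertainty machinery, which is agnostic to the
# backbone, so the default is sized for desk-scale CPU experiments.

#' Training configuration for the reference U-Net
#'
#' @param depth number of encoder levels / poolings (default 3; input
#'   sides must be divisible by \code{2^depth}).
#' @param baseChannels channels of the first encoder level, doubling per
#'   level (default 6).
#' @param epochs training epochs (default 12).
#' @param batchSize gradient-accumulation batch (default 4).
#' @param learningRate Adam step size (default 1e-3).
#' @param seed RNG seed controlling weight init and data order.
#' @param cropSize optional square crop side used during training; crops
#'   are sampled preferentially around foreground.  NULL trains on whole
#'   images.
#' @return list of class \code{TrainConfig}; the loss is always binary
#'   cross-entropy and is recorded in the returned metadata.
#' @export
trainConfig <- function(depth = 3L, baseChannels = 6L, epochs = 12L,
                        batchSize = 4L, learningRate = 1e-3, seed = 42L,
                        cropSize = NULL) {
  stopifnot(depth >= 1, baseChannels >= 1, epochs >= 1, batchSize >= 1,
            learningRate > 0)
  structure(list(depth = as.integer(depth),
                 baseChannels = as.integer(baseChannels),
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, loss = "binary_cross_entropy",
                 seed = as.integer(seed),
                 cropSize = if (is.null(cropSize)) NULL else as.integer(cropSize)),
            class = "TrainConfig")
}

.heConv <- function(cin, cout) {
  matrix(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))), 9 * cin, cout)
}

.unetInitWeights <- function(depth, base, inChannels) {
  w <- list()
  cin <- inChannels
  for (l in seq_len(depth)) {
    c <- base * 2^(l - 1)
    w[[sprintf("enc%da.W", l)]] <- .heConv(cin, c)
    w[[sprintf("enc%da.b", l)]] <- numeric(c)
    w[[sprintf("enc%db.W", l)]] <- .heConv(c, c)
    w[[sprintf("enc%db.b", l)]] <- numeric(c)
    cin <- c
  }
  cb <- base * 2^depth
  w[["bota.W"]] <- .heConv(cin, cb); w[["bota.b"]] <- numeric(cb)
  w[["botb.W"]] <- .heConv(cb, cb); w[["botb.b"]] <- numeric(cb)
  cup <- cb
  for (l in rev(seq_len(depth))) {
    c <- base * 2^(l - 1)
    w[[sprintf("up%d.W", l)]] <-
      array(rnorm(cup * c * 4, sd = sqrt(2 / cup)), c(cup, c, 4))
    w[[sprintf("up%d.b", l)]] <- numeric(c)
    w[[sprintf("dec%da.W", l)]] <- .heConv(2 * c, c)
    w[[sprintf("dec%da.b", l)]] <- numeric(c)
    w[[sprintf("dec%db.W", l)]] <- .heConv(c, c)
    w[[sprintf("dec%db.b", l)]] <- numeric(c)
    cup <- c
  }
  w[["out.W"]] <- matrix(rnorm(cup, sd = sqrt(1 / cup)), cup, 1)
  w[["out.b"]] <- 0
  w
}

.unetForward <- function(net, x, cache = FALSE) {
  w <- net$w; depth <- net$cfg$depth
  d <- dim(x)
  if (d[1] %% 2^depth != 0 || d[2] %% 2^depth != 0)
    stop(sprintf("input %dx%d not divisible by 2^depth = %d",
                 d[1], d[2], 2^depth))
  if (d[3] != net$cfg$inChannels)
    stop(sprintf("input has %d channels, model expects %d",
                 d[3], net$cfg$inChannels))
  cc <- list()
  skips <- list()
  h <- x
  for (l in seq_len(depth)) {
    a <- .convForward(h, w[[sprintf("enc%da.W", l)]],
                      w[[sprintf("enc%da.b", l)]], cache = cache)
    b <- .convForward(a$out, w[[sprintf("enc%db.W", l)]],
                      w[[sprintf("enc%db.b", l)]], cache = cache)
    skips[[l]] <- b$out
    p <- .maxpool2(b$out)
    if (cache) cc[[sprintf("enc%d", l)]] <-
      list(a = a, b = b, take = p$take, dimIn = dim(h), dimB = dim(b$out))
    h <- p$out
  }
  a <- .convForward(h, w[["bota.W"]], w[["bota.b"]], cache = cache)
  b <- .convForward(a$out, w[["botb.W"]], w[["botb.b"]], cache = cache)
  if (cache) cc[["bot"]] <- list(a = a, b = b, dimIn = dim(h))
  h <- b$out
  for (l in rev(seq_len(depth))) {
    u <- .upconvForward(h, w[[sprintf("up%d.W", l)]],
                        w[[sprintf("up%d.b", l)]], cache = cache)
    cat_ <- array(c(skips[[l]], u$out),
                  c(dim(u$out)[1], dim(u$out)[2],
                    dim(skips[[l]])[3] + dim(u$out)[3]))
    a <- .convForward(cat_, w[[sprintf("dec%da.W", l)]],
                      w[[sprintf("dec%da.b", l)]], cache = cache)
    b <- .convForward(a$out, w[[sprintf("dec%db.W", l)]],
                      w[[sprintf("dec%db.b", l)]], cache = cache)
    if (cache) cc[[sprintf("dec%d", l)]] <-
      list(u = u, a = a, b = b, dimUp = dim(h), dimCat = dim(cat_))
    h <- b$out
  }
  logitm <- matrix(h, ncol = dim(h)[3]) %*% w[["out.W"]]
  logit <- matrix(logitm + w[["out.b"]], dim(h)[1], dim(h)[2])
  res <- list(logit = logit, prob = 1 / (1 + exp(-logit)))
  if (cache) { res$cache <- cc; res$last <- h }
  res
}

.unetBackward <- function(net, fwd, dlogit) {
  w <- net$w; depth <- net$cfg$depth; cc <- fwd$cache
  g <- lapply(w, function(p) p * 0)
  lastm <- matrix(fwd$last, ncol = dim(fwd$last)[3])
  dlv <- as.numeric(dlogit)
  g[["out.W"]] <- crossprod(lastm, dlv)
  g[["out.b"]] <- sum(dlv)
  dh <- array(matrix(dlv, ncol = 1) %*% t(w[["out.W"]]), dim(fwd$last))
  for (l in seq_len(depth)) {                     # decoder, bottom-up order 1..depth
    nm <- sprintf("dec%d", l); s <- cc[[nm]]
    C <- dim(s$b$out)[3]
    bb <- .convBackward(dh, s$b, w[[sprintf("dec%db.W", l)]],
                        Cin = C, H = dim(dh)[1], Wd = dim(dh)[2])
    g[[sprintf("dec%db.W", l)]] <- bb$dW
    g[[sprintf("dec%db.b", l)]] <- bb$db
    Ccat <- s$dimCat[3]
    ba <- .convBackward(bb$dx, s$a, w[[sprintf("dec%da.W", l)]],
                        Cin = Ccat, H = dim(dh)[1], Wd = dim(dh)[2])
    g[[sprintf("dec%da.W", l)]] <- ba$dW
    g[[sprintf("dec%da.b", l)]] <- ba$db
    Cskip <- Ccat - dim(s$u$out)[3]
    dskip <- ba$dx[, , seq_len(Cskip), drop = FALSE]
    dup <- ba$dx[, , (Cskip + 1):Ccat, drop = FALSE]
    bu <- .upconvBackward(dup, s$u, w[[sprintf("up%d.W", l)]])
    g[[sprintf("up%d.W", l)]] <- bu$dW
    g[[sprintf("up%d.b", l)]] <- bu$db
    cc[[sprintf("skipgrad%d", l)]] <- dskip
    dh <- bu$dx
  }
  s <- cc[["bot"]]
  Cb <- dim(s$b$out)[3]
  bb <- .convBackward(dh, s$b, w[["botb.W"]], Cin = Cb,
                      H = dim(dh)[1], Wd = dim(dh)[2])
  g[["botb.W"]] <- bb$dW; g[["botb.b"]] <- bb$db
  ba <- .convBackward(bb$dx, s$a, w[["bota.W"]], Cin = s$dimIn[3],
                      H = dim(dh)[1], Wd = dim(dh)[2])
  g[["bota.W"]] <- ba$dW; g[["bota.b"]] <- ba$db
  dh <- ba$dx
  for (l in rev(seq_len(depth))) {                # encoder, deepest first
    s <- cc[[sprintf("enc%d", l)]]
    dpool <- .maxpool2Backward(dh, s$take, s$dimB[1], s$dimB[2], s$dimB[3])
    dpool <- dpool + cc[[sprintf("skipgrad%d", l)]]
    bb <- .convBackward(dpool, s$b, w[[sprintf("enc%db.W", l)]],
                        Cin = s$dimB[3], H = s$dimB[1], Wd = s$dimB[2])
    g[[sprintf("enc%db.W", l)]] <- bb$dW
    g[[sprintf("enc%db.b", l)]] <- bb$db
    ba <- .convBackward(bb$dx, s$a, w[[sprintf("enc%da.W", l)]],
                        Cin = s$dimIn[3], H = s$dimIn[1], Wd = s$dimIn[2],
                        needDx = l > 1)
    g[[sprintf("enc%da.W", l)]] <- ba$dW
    g[[sprintf("enc%da.b", l)]] <- ba$db
    dh <- ba$dx                      # NULL at the top level
  }
  g
}

#' Build the scaled-down reference U-Net
#'
#' Constructs the untrained network with deterministically seeded weights
#' and wraps it in the \linkS4class{SegPredictor} contract.  The network
#' is fully convolutional, so it accepts any square input whose side is
#' divisible by \code{2^depth} (e.g. both the 192-pixel planar and the
#' 256-pixel spherical grids).
#'
#' @param config a [trainConfig()].
#' @param inChannels input channels (default 2: T1-like and T1ce-like).
#' @return a \linkS4class{SegPredictor} whose \code{model} slot holds the
#'   mutable network state used by [trainPredictor()].
#' @export
buildReferenceUNet <- function(config = trainConfig(), inChannels = 2L) {
  stopifnot(inherits(config, "TrainConfig"))
  net <- new.env(parent = emptyenv())
  net$cfg <- c(config, list(inChannels = as.integer(inChannels)))
  .withSeed(config$seed,
    net$w <- .unetInitWeights(config$depth, config$baseChannels, inChannels))
  net$history <- data.frame(epoch = integer(), loss = numeric())
  fn <- function(image) {
    if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
    .unetForward(net, image)$prob
  }
  new("SegPredictor", predictFun = fn, inputSize = NA_integer_,
      name = sprintf("reference U-Net (depth %d, base %d)",
                     config$depth, config$baseChannels),
      model = net)
}

.sampleCrop <- function(img, mask, cropSize) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (is.null(cropSize) || (cropSize >= H && cropSize >= W))
    return(list(img = img, mask = mask))
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) > 0 && runif(1) < 0.8) {
    p <- fg[sample.int(nrow(fg), 1), ]
    r0 <- p[1] - sample.int(cropSize, 1) + 1
    c0 <- p[2] - sample.int(cropSize, 1) + 1
  } else {
    r0 <- sample.int(H - cropSize + 1, 1)
    c0 <- sample.int(W - cropSize + 1, 1)
  }
  r0 <- min(max(r0, 1), H - cropSize + 1)
  c0 <- min(max(c0, 1), W - cropSize + 1)
  list(img = img[r0:(r0 + cropSize - 1), c0:(c0 + cropSize - 1), ,
                 drop = FALSE],
       mask = mask[r0:(r0 + cropSize - 1), c0:(c0 + cropSize - 1)])
}

#' Train a predictor with binary cross-entropy and Adam
#'
#' Mini-batch (gradient-accumulation) training of the reference U-Net on
#' paired slices and binary masks.  The per-epoch mean binary
#' cross-entropy is logged in the model's history; training is
#' deterministic given \code{config$seed}.
#'
#' @param predictor a \linkS4class{SegPredictor} built by
#'   [buildReferenceUNet()].
#' @param images list of rows x cols x channels arrays.
#' @param masks list of binary matrices, same lengths and shapes.
#' @param config a [trainConfig()]; defaults to the configuration the
#'   network was built with.
#' @return the predictor (same mutable model, updated weights), with the
#'   loss history accessible via \code{trainingHistory()}.
#' @export
trainPredictor <- function(predictor, images, masks,
                           config = predictor@model$cfg) {
  net <- predictor@model
  if (is.null(net) || !is.environment(net))
    stop("predictor carries no trainable model")
  if (length(images) == 0) stop("empty training set")
  if (length(images) != length(masks))
    stop("images and masks must have equal length")
  for (m in masks) if (!all(m %in% c(0, 1))) stop("masks must be binary")
  lr <- config$learningRate
  .withSeed(config$seed + 1L, {
    if (is.null(net$opt)) { net$opt <- .adamInit(net$w); net$optT <- 0L }
    n <- length(images)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      epLoss <- 0; nb <- 0
      bs <- config$batchSize
      for (start in seq(1, n, bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        gacc <- NULL
        bloss <- 0
        for (i in idx) {
          s <- .sampleCrop(images[[i]], masks[[i]], config$cropSize)
          fwd <- .unetForward(net, s$img, cache = TRUE)
          lg <- .bceLossGrad(fwd$logit, s$mask)
          if (!is.finite(lg$loss))
            stop(sprintf("NaN/Inf loss at epoch %d: lower the learning rate or check inputs", ep))
          bloss <- bloss + lg$loss
          g <- .unetBackward(net, fwd, lg$dlogit)
          gacc <- if (is.null(gacc)) g
                  else Map(`+`, gacc, g)
        }
        net$optT <- net$optT + 1L
        for (nm in names(net$w)) {
          upd <- .adamStep(net$w[[nm]], gacc[[nm]] / length(idx),
                           net$opt[[nm]], lr, net$optT)
          net$w[[nm]] <- upd$p
          net$opt[[nm]] <- upd$st
        }
        epLoss <- epLoss + bloss / length(idx); nb <- nb + 1
      }
      net$history <- rbind(net$history,
                           data.frame(epoch = ep, loss = epLoss / nb))
    }
  })
  predictor
}

#' Training-loss history of a predictor
#' @param predictor a trained \linkS4class{SegPredictor}.
#' @return data.frame with columns \code{epoch}, \code{loss} (binary
#'   cross-entropy).
#' @export
trainingHistory <- function(predictor) {
  if (is.null(predictor@model)) stop("predictor carries no model")
  predictor@model$history
}

#' Analytic mock predictors for pipeline testing
#'
#' Predictors that derive their output from the ground-truth mask
#' attached to the input image (attribute \code{gt}, as produced by
#' [generatePhantom()] and propagated through [forwardProject()]),
#' enabling tests of the ensemble and uncertainty machinery without any
#' training: \describe{
#'   \item{perfect}{returns the ground truth as 0/1 probabilities;}
#'   \item{blurred}{returns the ground truth smoothed by a Gaussian of
#'     width \code{param} (boundary-graded probabilities);}
#'   \item{noisy}{adds seeded Gaussian noise of SD \code{param} to the
#'     ground truth, clipped to [0, 1].}
#' }
#'
#' @param mode one of \code{"perfect"}, \code{"blurred"}, \code{"noisy"}.
#' @param param blur sigma (px) or noise SD, by mode.
#' @param seed seed for the noisy mode (the same noise is drawn at every
#'   call, keeping the predictor deterministic).
#' @return a \linkS4class{SegPredictor}.
#' @export
mockPredictor <- function(mode = c("perfect", "blurred", "noisy"),
                          param = 2, seed = 1L) {
  mode <- match.arg(mode)
  fn <- function(image) {
    gt <- attr(image, "gt")
    if (is.null(gt))
      stop("mock predictor requires a 'gt' attribute on the input image")
    gt <- gt * 1
    switch(mode,
      perfect = gt,
      blurred = { p <- .gauss2(gt, param); p[p < 0] <- 0; p[p > 1] <- 1; p },
      noisy = .withSeed(seed, {
        p <- gt + rnorm(length(gt), sd = param)
        p[p < 0] <- 0; p[p > 1] <- 1
        matrix(p, nrow(gt), ncol(gt))
      }))
  }
  new("SegPredictor", predictFun = fn, inputSize = NA_integer_,
      name = sprintf("mock (%s)", mode), model = NULL)
}
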