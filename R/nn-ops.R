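# Minimal dense-prediction CNN primitives.  All tensors are H x W x C
# double arrays.  3x3 same-padding convolution runs through the compiled
# im2col kernel in src/conv3.cpp with the matrix product in BLAS; pooling
# is 2x2 max, upsampling a 2x2 stride-2 transposed convolution.  Nothing
# here is exported; the reference U-Net in unet.R is built from these.
# Weight layout for a 3x3 conv: (9*Cin) x Cout, offset blocks ordered
# with the row offset cycling fastest (di = -1,0,1 within dj = -1,0,1).

# 3x3 conv + optional ReLU.  W: (9*Cin) x Cout (block o = offset o), b: Cout.
.convForward <- function(x, W, b, relu = TRUE, cache = FALSE) {
  d <- dim(x)
  res <- .conv3ForwardC(x, W, as.numeric(b), relu, cache)
  out <- res$out
  dim(out) <- c(d[1], d[2], ncol(W))
  if (cache)
    list(out = out, col = res$col,
         act = matrix(out, ncol = ncol(W)))
  else list(out = out)
}

.convBackward <- function(dout, cache, W, relu = TRUE, needDx = TRUE,
                          Cin, H, Wd) {
  dz <- matrix(dout, ncol = dim(dout)[3])
  if (relu) dz <- dz * (cache$act > 0)
  dW <- crossprod(cache$col, dz)
  db <- colSums(dz)
  dx <- NULL
  if (needDx) {
    dcol <- tcrossprod(dz, W)
    dx <- .col2im3C(dcol, H, Wd, Cin)
    dim(dx) <- c(H, Wd, Cin)
  }
  list(dW = dW, db = db, dx = dx)
}

.maxpool2 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  ro <- seq(1, H, 2); re <- seq(2, H, 2)
  co <- seq(1, W, 2); ce <- seq(2, W, 2)
  a1 <- x[ro, co, , drop = FALSE]; a2 <- x[re, co, , drop = FALSE]
  a3 <- x[ro, ce, , drop = FALSE]; a4 <- x[re, ce, , drop = FALSE]
  out <- pmax(a1, a2, a3, a4)
  t1 <- a1 == out
  t2 <- (a2 == out) & !t1
  t3 <- (a3 == out) & !t1 & !t2
  t4 <- !t1 & !t2 & !t3
  list(out = out, take = list(t1, t2, t3, t4))
}

.maxpool2Backward <- function(dout, take, H, W, C) {
  dx <- array(0, c(H, W, C))
  ro <- seq(1, H, 2); re <- seq(2, H, 2)
  co <- seq(1, W, 2); ce <- seq(2, W, 2)
  dx[ro, co, ] <- dout * take[[1]]
  dx[re, co, ] <- dout * take[[2]]
  dx[ro, ce, ] <- dout * take[[3]]
  dx[re, ce, ] <- dout * take[[4]]
  dx
}

# 2x2 stride-2 transposed conv + ReLU.  W: array Cin x Cout x 4, b: Cout.
.upconvForward <- function(x, W, b, cache = FALSE) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]
  Cout <- dim(W)[2]
  xm <- matrix(x, H * Wd, Cin)
  out <- array(0, c(2 * H, 2 * Wd, Cout))
  zs <- vector("list", 4)
  pos <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (p in 1:4) {
    z <- xm %*% W[, , p] + matrix(b, H * Wd, Cout, byrow = TRUE)
    z <- z * (z > 0)
    zs[[p]] <- z
    out[seq(pos[[p]][1], 2 * H, 2), seq(pos[[p]][2], 2 * Wd, 2), ] <-
      array(z, c(H, Wd, Cout))
  }
  if (cache) list(out = out, xm = xm, zs = zs) else list(out = out)
}

.upconvBackward <- function(dout, cache, W) {
  Cin <- dim(W)[1]; Cout <- dim(W)[2]
  H2 <- dim(dout)[1]; W2 <- dim(dout)[2]
  H <- H2 / 2; Wd <- W2 / 2
  pos <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  dW <- array(0, dim(W)); db <- numeric(Cout)
  dxm <- matrix(0, H * Wd, Cin)
  for (p in 1:4) {
    dz <- matrix(dout[seq(pos[[p]][1], H2, 2), seq(pos[[p]][2], W2, 2), ,
                      drop = FALSE], H * Wd, Cout)
    dz <- dz * (cache$zs[[p]] > 0)
    dW[, , p] <- crossprod(cache$xm, dz)
    db <- db + colSums(dz)
    dxm <- dxm + tcrossprod(dz, W[, , p])
  }
  list(dW = dW, db = db, dx = array(dxm, c(H, Wd, Cin)))
}

# stable binary cross-entropy on logits; returns loss and dL/dlogit
.bceLossGrad <- function(logit, y) {
  n <- length(logit)
  loss <- mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
  p <- 1 / (1 + exp(-logit))
  list(loss = loss, dlogit = (p - y) / n)
}

# weights live in a flat named list of arrays; optimizer state mirrors it
.adamInit <- function(w) lapply(w, function(p) list(m = p * 0, v = p * 0))

.adamStep <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g * g
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}
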