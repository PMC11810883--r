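# Fixtures and independent brute-force oracles used across the suite.
# Oracles are deliberately naive (loops, all-pairs scans) and never share
# code with the implementation they check.

# band-limited smooth test image: sum of broad Gaussians
smoothImage <- function(n, seed, ngauss = 8) {
  set.seed(seed)
  rows <- matrix(0:(n - 1), n, n); cols <- t(rows)
  img <- matrix(0, n, n)
  for (i in seq_len(ngauss)) {
    cr <- runif(1, 0.15 * n, 0.85 * n); cc <- runif(1, 0.15 * n, 0.85 * n)
    sg <- runif(1, 0.06 * n, 0.25 * n)
    img <- img + runif(1, -1, 1) *
      exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * sg^2))
  }
  img
}

diskMask <- function(n, cr, cc, radius) {
  rows <- matrix(0:(n - 1), n, n); cols <- t(rows)
  ((rows - cr)^2 + (cols - cc)^2 <= radius^2) * 1
}

easyPhantomSpec <- function(gridSize = 96, seed = 1) {
  phantomSpec(gridSize = gridSize, nLesions = 1,
              lesionRadiusRange = c(8, 14), tailProbability = 0.7,
              tailLengthRange = c(6, 12), tailWidth = 2,
              nVessels = 2, noiseSigma = 0.03, contrastRatio = 2,
              seed = seed)
}

# exhaustive between-class-variance scan over all histogram cut points
bruteOtsu <- function(v, bins = 256) {
  edges <- seq(min(v), max(v), length.out = bins + 1)
  centers <- (edges[-1] + edges[-(bins + 1)]) / 2
  cnt <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE),
                            1), bins), bins)
  best <- -Inf; thr <- NA
  for (t in 1:(bins - 1)) {
    n0 <- sum(cnt[1:t]); n1 <- sum(cnt) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(cnt[1:t] * centers[1:t]) / n0
    mu1 <- sum(cnt[(t + 1):bins] * centers[(t + 1):bins]) / n1
    s <- (n0 / sum(cnt)) * (n1 / sum(cnt)) * (mu0 - mu1)^2
    if (s > best + 1e-15) { best <- s; thr <- edges[t + 1] }
  }
  thr
}

bruteConfusion <- function(pred, gt, include = NULL) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (!is.null(include) && include[i, j] == 0) next
    if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1L
    else if (pred[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1L
    else if (pred[i, j] == 1) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# naive per-tau masking and tallying of the filtered curves
bruteCurves <- function(pred, gt, u) {
  dsc <- ftp <- ftn <- tp <- tn <- numeric(100)
  inc100 <- matrix(1, nrow(pred), ncol(pred))
  cc100 <- bruteConfusion(pred, gt, inc100)
  for (tau in 1:100) {
    inc <- if (tau == 100) inc100 else (u < tau) * 1
    cc <- bruteConfusion(pred, gt, inc)
    tp[tau] <- cc["TP"]; tn[tau] <- cc["TN"]
    denom <- 2 * cc["TP"] + cc["FP"] + cc["FN"]
    dsc[tau] <- if (denom > 0) 2 * cc["TP"] / denom else 1
    ftp[tau] <- if (cc100["TP"] > 0) (cc100["TP"] - cc["TP"]) / cc100["TP"] else 0
    ftn[tau] <- if (cc100["TN"] > 0) (cc100["TN"] - cc["TN"]) / cc100["TN"] else 0
  }
  list(dsc = dsc, ftp = ftp, ftn = ftn, tp = tp, tn = tn)
}

bruteSurface <- function(mask) {
  pts <- NULL
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] != 1) next
    onBorder <- i == 1 || i == nr || j == 1 || j == nc
    bgNb <- (i > 1 && mask[i - 1, j] == 0) ||
      (i < nr && mask[i + 1, j] == 0) ||
      (j > 1 && mask[i, j - 1] == 0) ||
      (j < nc && mask[i, j + 1] == 0)
    if (onBorder || bgNb) pts <- rbind(pts, c(i - 1, j - 1))
  }
  if (is.null(pts)) matrix(numeric(), 0, 2) else pts
}

# O(n^2) all-pairs pooled nearest-surface distances
bruteHausdorff <- function(pred, gt, spacingMM = 1) {
  a <- bruteSurface(pred); b <- bruteSurface(gt)
  da <- apply(a, 1, function(p)
    min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2)))
  db <- apply(b, 1, function(p)
    min(sqrt((a[, 1] - p[1])^2 + (a[, 2] - p[2])^2)))
  pooled <- c(da, db) * spacingMM / 10
  list(mhd_cm = mean(pooled),
       hd95_cm = unname(quantile(pooled, 0.95, type = 7)))
}

randomBlob <- function(n, seed, p = 0.45, minPix = 3) {
  set.seed(seed)
  repeat {
    m <- (smoothImage(n, sample.int(1e6, 1), 4) >
            quantile(smoothImage(n, sample.int(1e6, 1), 4), p)) * 1
    m <- diskMask(n, runif(1, n * 0.3, n * 0.7), runif(1, n * 0.3, n * 0.7),
                  runif(1, 2, n * 0.3))
    if (sum(m) >= minPix && sum(m) < n * n) return(m)
  }
}

tinyStack <- function(maps) {
  k <- length(maps)
  arr <- array(0, c(k, nrow(maps[[1]]), ncol(maps[[1]])))
  for (i in seq_len(k)) arr[i, , ] <- maps[[i]]
  probabilityStack(arr)
}

# distance from every pixel to the nearest ground-truth boundary pixel
.distToBoundary <- function(mask) {
  surf <- surfacePoints(mask)
  n <- nrow(mask)
  rows <- matrix(0:(n - 1), n, n); cols <- t(rows)
  dmin <- matrix(Inf, n, n)
  for (i in seq_len(nrow(surf)))
    dmin <- pmin(dmin, (rows - surf[i, 1])^2 + (cols - surf[i, 2])^2)
  sqrt(dmin)
}
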