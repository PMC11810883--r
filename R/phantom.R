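# Synthetic 2-channel mpMRI-like slice generator with ground truth.
#
# The phantom emulates the structural features the segmentation method
# exercises: a bright quasi-elliptical contrast-enhancing mass on the
# T1ce-like channel, an optional thin curvilinear "dural tail" appendage
# attached to the mass boundary, bright vessel-like curvilinear
# distractors that are NOT part of the ground truth, smooth background
# anatomy, and additive Gaussian noise.  It is an explicit stand-in for
# clinical data: realism is limited to these features.

#' Phantom specification
#'
#' @param gridSize image side in pixels (default 192).
#' @param nLesions number of lesions (>= 0; several lesions emulate
#'   multi-focal disease).
#' @param lesionRadiusRange min/max semi-axis of the elliptical mass, px.
#' @param tailProbability probability a lesion carries a dural-tail
#'   appendage (default 0.7, matching the high prevalence of dural tails
#'   in contrast-enhanced meningioma imaging).
#' @param tailLengthRange min/max tail length, px.
#' @param tailWidth tail half-structure width, px (default 2).
#' @param nVessels number of vessel-like curvilinear distractors.
#' @param vesselIntensity vessel brightness relative to the lesion
#'   enhancement (default 0.8).
#' @param noiseSigma additive Gaussian noise SD, in units of the ~[0,1]
#'   dynamic range (default 0.05).
#' @param contrastRatio T1ce-over-T1 enhancement factor of lesion tissue
#'   (default 2).
#' @param seed RNG seed making the case reproducible.
#' @return a list of class \code{PhantomSpec}.
#' @export
phantomSpec <- function(gridSize = 192L, nLesions = 1L,
                        lesionRadiusRange = pmax(2, round(
                          c(0.052, 0.115) * gridSize)),
                        tailProbability = 0.7,
                        tailLengthRange = round(c(0.052, 0.135) * gridSize),
                        tailWidth = 2,
                        nVessels = 3L, vesselIntensity = 0.8,
                        noiseSigma = 0.05, contrastRatio = 2,
                        seed = 1L) {
  stopifnot(gridSize >= 32, nLesions >= 0, min(lesionRadiusRange) >= 2,
            tailProbability >= 0, tailProbability <= 1,
            tailWidth > 0, nVessels >= 0, noiseSigma >= 0,
            contrastRatio >= 1)
  structure(list(
    gridSize = as.integer(gridSize), nLesions = as.integer(nLesions),
    lesionRadiusRange = lesionRadiusRange,
    tailProbability = tailProbability,
    tailLengthRange = tailLengthRange, tailWidth = tailWidth,
    nVessels = as.integer(nVessels), vesselIntensity = vesselIntensity,
    noiseSigma = noiseSigma, contrastRatio = contrastRatio,
    seed = as.integer(seed)), class = "PhantomSpec")
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# mask of pixels within `width` of a polyline, computed on the curve's
# bounding box only (exact Euclidean distance to the sampled points)
.curveBandMask <- function(gridSize, pts, width) {
  lo <- pmax(floor(apply(pts, 2, min)) - ceiling(width) - 1, 0)
  hi <- pmin(ceiling(apply(pts, 2, max)) + ceiling(width) + 1, gridSize - 1)
  rr <- lo[1]:hi[1]; cc <- lo[2]:hi[2]
  rows <- matrix(rr, length(rr), length(cc))
  cols <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  dmin <- matrix(Inf, length(rr), length(cc))
  for (i in seq_len(nrow(pts)))
    dmin <- pmin(dmin, (rows - pts[i, 1])^2 + (cols - pts[i, 2])^2)
  out <- matrix(FALSE, gridSize, gridSize)
  out[rr + 1, cc + 1] <- dmin <= width^2
  out
}

# rasterize a densely sampled curve into a binary matrix
.rasterCurve <- function(gridSize, pts) {
  m <- matrix(0, gridSize, gridSize)
  ri <- round(pts[, 1]); ci <- round(pts[, 2])
  ok <- ri >= 0 & ri <= gridSize - 1 & ci >= 0 & ci <= gridSize - 1
  m[cbind(ri[ok] + 1, ci[ok] + 1)] <- 1
  m
}

.quadBezier <- function(p0, p1, p2, n = 120) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

.gauss2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma)
}

#' Generate one synthetic 2-channel slice with ground truth
#'
#' Deterministic given \code{spec$seed}.  The T1-like channel shows
#' smooth background anatomy with mildly visible lesion tissue; the
#' T1ce-like channel additionally enhances lesion and tail tissue by
#' \code{contrastRatio} and paints vessel distractors at
#' \code{vesselIntensity}.  The ground truth is the union of lesion and
#' tail supports; vessels are never part of it.
#'
#' @param spec a [phantomSpec()].
#' @return list of class \code{PhantomCase} with \code{image}
#'   (gridSize x gridSize x 2 array, channels T1, T1ce; carries the
#'   ground truth as attribute \code{gt} so mock predictors can use it),
#'   \code{gt} (binary matrix), \code{spec} and \code{realized} (per-
#'   lesion parameters and area bookkeeping).
#' @examples
#' case <- generatePhantom(phantomSpec(gridSize = 96, seed = 7))
#' sum(case$gt)
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  .withSeed(spec$seed, {
    n <- spec$gridSize
    rows <- matrix(0:(n - 1), n, n)
    cols <- t(rows)
    mid <- (n - 1) / 2

    # smooth background anatomy: elliptical head with low-frequency field
    headR <- 0.46 * n
    headMask <- ((rows - mid) / (1.05 * headR))^2 +
      ((cols - mid) / headR)^2 <= 1
    field <- matrix(0, n, n)
    for (i in 1:6) {
      cr <- runif(1, 0.2 * n, 0.8 * n); cc <- runif(1, 0.2 * n, 0.8 * n)
      sg <- runif(1, 0.15 * n, 0.35 * n); amp <- runif(1, -0.08, 0.12)
      field <- field + amp * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * sg^2))
    }
    t1 <- (0.35 + field) * headMask

    gt <- matrix(0L, n, n)
    lesionSoft <- matrix(0, n, n)
    realized <- list()
    margin <- max(spec$lesionRadiusRange) + max(spec$tailLengthRange) + 4
    if (spec$nLesions > 0 && margin > mid * 0.9)
      stop("infeasible placement: lesion radius + tail length exceed the field of view")
    for (li in seq_len(spec$nLesions)) {
      placed <- FALSE
      for (try in 1:50) {
        a <- runif(1, spec$lesionRadiusRange[1], spec$lesionRadiusRange[2])
        b <- runif(1, 0.6, 1) * a
        ang <- runif(1, 0, pi)
        cr <- runif(1, margin, n - 1 - margin)
        cc <- runif(1, margin, n - 1 - margin)
        dr <- rows - cr; dc <- cols - cc
        u <- dr * cos(ang) + dc * sin(ang)
        v <- -dr * sin(ang) + dc * cos(ang)
        les <- (u / a)^2 + (v / b)^2 <= 1
        if (sum(les & gt) == 0 && all(headMask[les])) { placed <- TRUE; break }
      }
      if (!placed)
        stop("infeasible placement: could not fit a non-overlapping lesion inside the head after 50 tries")
      tail_len <- 0; tailMask <- matrix(FALSE, n, n)
      if (runif(1) < spec$tailProbability) {
        tail_len <- runif(1, spec$tailLengthRange[1], spec$tailLengthRange[2])
        tdir <- runif(1, 0, 2 * pi)
        # start on the ellipse boundary along tdir, curve gently outward
        tstep <- c(cos(tdir), sin(tdir))
        rb <- 1 / sqrt((cos(tdir - ang) / a)^2 + (sin(tdir - ang) / b)^2)
        p0 <- c(cr, cc) + 0.9 * rb * tstep
        p2 <- c(cr, cc) + (rb + tail_len) * tstep
        perp <- c(-tstep[2], tstep[1])
        p1 <- (p0 + p2) / 2 + runif(1, -0.25, 0.25) * tail_len * perp
        tailMask <- .curveBandMask(n, .quadBezier(p0, p1, p2),
                                   spec$tailWidth / 2 + 0.5)
      }
      sup <- les | tailMask
      gt[sup] <- 1L
      lesionSoft <- pmax(lesionSoft, .gauss2(sup * 1, 1.2))
      realized[[li]] <- list(center = c(cr, cc), semiAxes = c(a, b),
                             angle = ang, tailLength = tail_len,
                             lesionArea = sum(les), gtArea = sum(sup))
    }

    vessels <- matrix(0, n, n)
    for (vi in seq_len(spec$nVessels)) {
      th <- runif(1, 0, 2 * pi)
      p0 <- c(mid, mid) + headR * c(cos(th), 1.0 * sin(th)) * runif(1, 0.55, 0.9)
      th2 <- th + runif(1, 1.6, 3.5)
      p2 <- c(mid, mid) + headR * c(cos(th2), sin(th2)) * runif(1, 0.55, 0.9)
      p1 <- c(mid, mid) + runif(2, -0.3, 0.3) * headR
      ras <- .rasterCurve(n, .quadBezier(p0, p1, p2, n = 6 * n))
      w <- runif(1, 0.8, 1.4)
      v <- .gauss2(ras, w)
      if (max(v) > 0) v <- v / max(v)
      vessels <- pmax(vessels, v)
    }
    vessels[gt == 1] <- 0          # vessels never overlap ground truth
    vessels <- vessels * headMask

    lesionLevel <- 0.35            # reference tissue signal for vessel scaling
    t1 <- t1 + 0.15 * lesionSoft
    # multiplicative enhancement: lesion tissue reaches contrastRatio x its
    # T1 signal on the T1ce channel; vessels enhance comparably but are
    # not ground truth
    t1ce <- t1 * (1 + (spec$contrastRatio - 1) * lesionSoft) +
      spec$vesselIntensity * lesionLevel * spec$contrastRatio * vessels
    if (spec$noiseSigma > 0) {
      t1 <- t1 + rnorm(n * n, sd = spec$noiseSigma)
      t1ce <- t1ce + rnorm(n * n, sd = spec$noiseSigma)
    }
    img <- array(c(t1, t1ce), c(n, n, 2))
    attr(img, "gt") <- gt
    structure(list(image = img, gt = gt, spec = spec,
                   realized = realized),
              class = "PhantomCase")
  })
}

#' Generate a reproducible cohort of phantom cases
#'
#' Case seeds are derived deterministically from \code{baseSeed}; cases
#' are grouped into subjects (\code{slicesPerSubject} consecutive slices
#' each) so train/test splitting can honour per-subject grouping.
#'
#' @param spec a [phantomSpec()] (its \code{seed} field is overridden per
#'   case).
#' @param nCases number of slices to generate.
#' @param baseSeed integer master seed.
#' @param slicesPerSubject slices attributed to one synthetic subject
#'   (default 3).
#' @return list with \code{cases} (list of \code{PhantomCase}),
#'   \code{subject} (character vector of subject IDs per case) and
#'   \code{seeds}.
#' @export
generateCohort <- function(spec, nCases, baseSeed = 1L,
                           slicesPerSubject = 3L) {
  stopifnot(nCases >= 1)
  seeds <- (as.integer(baseSeed) + 7919L * seq_len(nCases)) %% 2147483629L
  cases <- lapply(seeds, function(s) {
    sp <- spec; sp$seed <- s
    generatePhantom(sp)
  })
  subject <- sprintf("S%03d", (seq_len(nCases) - 1) %/% slicesPerSubject + 1)
  list(cases = cases, subject = subject, seeds = seeds)
}

#' Per-subject train/test split
#'
#' Randomizes whole subjects into train and test so that no subject
#' straddles the two groups.
#'
#' @param subject character vector of subject IDs, one per case.
#' @param trainFraction fraction of subjects assigned to training
#'   (default 0.7).
#' @param seed RNG seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
splitCohort <- function(subject, trainFraction = 0.7, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  .withSeed(seed, {
    subj <- unique(subject)
    ntr <- max(1, round(trainFraction * length(subj)))
    trSubj <- sample(subj, ntr)
    list(train = which(subject %in% trSubj),
         test = which(!subject %in% trSubj))
  })
}
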