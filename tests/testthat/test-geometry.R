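# Forward/backward spherical projection and the centre-magnification law.

geomDefault <- projectionGeometry()

test_that("constant and impulse images project as the geometry predicts", {
  img <- matrix(7, 192, 192)
  sph <- forwardProject(img, geomDefault, c(95.5, 95.5))
  px <- pixelData(sph)
  # interpolation of a constant: every sampled pixel is 7 or the fill value
  expect_true(all(abs(px - 7) < 1e-12 | abs(px - 0) < 1e-12))
  expect_equal(px[128, 128, 1], 7)
  # round trip of the constant restores it away from the border band
  back <- backwardProject(sph)
  expect_equal(back[5:188, 5:188], img[5:188, 5:188], tolerance = 1e-10)

  # a single bright pixel at the projection centre lands on the pole axis
  imp <- matrix(0, 192, 192); imp[96, 96] <- 1
  sph2 <- forwardProject(imp, geomDefault, c(95, 95))
  px2 <- pixelData(sph2)[, , 1]
  w <- which(px2 == max(px2), arr.ind = TRUE)
  expect_true(all(abs(w - 128) <= 1))
})

test_that("input validation rejects bad centres, sizes and non-finite pixels", {
  img <- matrix(0, 192, 192)
  expect_error(forwardProject(img, geomDefault, c(-3, 10)), "centre")
  expect_error(forwardProject(matrix(0, 64, 64), geomDefault, c(3, 3)),
               "standardize")
  img[1, 1] <- NA
  expect_error(forwardProject(img, geomDefault, c(95.5, 95.5)), "finite")
  expect_error(backwardProject(matrix(0, 256, 256)), "metadata")
  expect_error(projectionGeometry(d = 1.2, r = 1), "inside the sphere")
})

test_that("local magnification follows d/(d^2 + rho^2)", {
  # worked ratio: centre vs rho = 0.5 sphere units under (0.5, 1, 0.3)
  su <- 2 * 0.5 / 191                      # sphere units per pixel
  ctr <- c(95.5, 95.5)
  fdScale <- function(rhoPx) {
    p1 <- planarToSphericalCoords(c(95.5, 95.5 + rhoPx), geomDefault, ctr)
    p2 <- planarToSphericalCoords(c(95.5, 95.5 + rhoPx + 1e-3), geomDefault, ctr)
    (p2[2] - p1[2]) / 1e-3
  }
  ratio <- fdScale(0) / fdScale(0.5 / su)
  expect_equal(ratio, (1 / 0.3) / (0.3 / (0.3^2 + 0.5^2)), tolerance = 1e-3)

  # the radial derivative matches the analytic law at 50 sampled radii
  d <- geomDefault@d
  set.seed(42)
  rhoPx <- runif(50, 0, 90)
  for (r in rhoPx) {
    fd <- fdScale(r)
    rho <- r * su
    analytic <- d / (d^2 + rho^2) / atan2(0.5, d) * (255 / 2) * su
    expect_lt(abs(fd - analytic) / analytic, 0.02)
  }
})

test_that("round trip on smooth images keeps SSIM high", {
  for (s in 1:4) {
    img <- smoothImage(192, seed = 100 + s)
    rt <- backwardProject(forwardProject(img, geomDefault, c(95.5, 95.5)))
    expect_gt(ssim(img, rt, margin = 4), 0.95)
  }
})

test_that("nearest-neighbour mask round trip errs only in a 1-pixel band", {
  mask <- diskMask(192, 90, 100, 40)
  sph <- forwardProject(mask, geomDefault, c(95.5, 95.5), order = 0L)
  back <- backwardProject(sph, order = 0L)
  expect_true(all(back %in% c(0, 1)))
  diff <- which(back != mask, arr.ind = TRUE)
  if (nrow(diff) > 0) {
    surf <- surfacePoints(mask) + 1   # to 1-based
    for (r in seq_len(nrow(diff))) {
      dmin <- min(sqrt((surf[, 1] - diff[r, 1])^2 +
                       (surf[, 2] - diff[r, 2])^2))
      expect_lte(dmin, 1.5)
    }
  }
})

test_that("projection centres form symmetric uniform lattices", {
  c1 <- makeCenterGrid(192, 1)
  expect_equal(unname(centerCoords(c1)), matrix(c(95.5, 95.5), 1))
  c121 <- makeCenterGrid(192, 121, 0.5)
  expect_equal(nCenters(c121), 121L)
  expect_equal(unname(colMeans(centerCoords(c121))), c(95.5, 95.5))
  # explicit 3x3 lattice over the central half of the side
  c9 <- makeCenterGrid(192, 9, 0.5)
  ax <- c(95.5 - 47.75, 95.5, 95.5 + 47.75)
  expect_equal(sort(unique(centerCoords(c9)[, 1])), ax)
  expect_equal(sort(unique(centerCoords(c9)[, 2])), ax)
  expect_error(makeCenterGrid(192, 10), "perfect square")
  expect_error(makeCenterGrid(192, 10), "9 and 16")
})

test_that("local scale map peaks at the centre, is symmetric, matches FD", {
  ctr <- c(95.5, 95.5)
  m <- localScaleMap(geomDefault, ctr)
  expect_true(all(m > 0))
  w <- which(m == max(m), arr.ind = TRUE)
  expect_true(all(abs(w - 96.5) <= 1))     # the 4 pixels around 95.5
  # rotational symmetry about the centre
  expect_equal(m, m[192:1, 192:1], tolerance = 1e-12)
  expect_equal(m, t(m), tolerance = 1e-12)
  # FD areal Jacobian of the coordinate map at 50 random pixels
  set.seed(7)
  eps <- 1e-3
  for (t in 1:50) {
    p <- c(sample(20:170, 1), sample(20:170, 1))
    j00 <- planarToSphericalCoords(p, geomDefault, ctr)
    jr <- planarToSphericalCoords(p + c(eps, 0), geomDefault, ctr)
    jc <- planarToSphericalCoords(p + c(0, eps), geomDefault, ctr)
    J <- abs(det(cbind(t(jr - j00) / eps, t(jc - j00) / eps)))
    expect_lt(abs(J - m[p[1] + 1, p[2] + 1]) / m[p[1] + 1, p[2] + 1], 0.02)
  }
})

test_that("magnification is non-increasing along rays from the centre", {
  ctr <- c(95.5, 95.5)
  m <- localScaleMap(geomDefault, ctr)
  for (ang in seq(0, 2 * pi, length.out = 9)[-9]) {
    r <- seq(0, 90, by = 3)
    pr <- round(95.5 + r * cos(ang)); pc <- round(95.5 + r * sin(ang))
    vals <- m[cbind(pr + 1, pc + 1)]
    expect_true(all(diff(vals) <= 1e-9))
  }
})

test_that("projection is centre-covariant and channel-independent", {
  img <- smoothImage(192, seed = 11)
  img[c(1:40, 153:192), ] <- 0; img[, c(1:40, 153:192)] <- 0  # interior support
  off <- c(12, -8)
  a <- pixelData(forwardProject(img, geomDefault, c(95.5, 95.5) + off))
  shifted <- matrix(0, 192, 192)
  shifted[(1 + 0):(192 - 12), (1 + 8):192] <- img[13:192, 1:184]
  b <- pixelData(forwardProject(shifted, geomDefault, c(95.5, 95.5)))
  # both projections see the same physical content (zero outside the
  # interior support), so they agree up to floating point everywhere
  expect_lt(max(abs(a - b)), 1e-9)

  two <- array(c(img, img * 2), c(192, 192, 2))
  pr <- pixelData(forwardProject(two, geomDefault, c(95.5, 95.5)))
  p1 <- pixelData(forwardProject(img, geomDefault, c(95.5, 95.5)))[, , 1]
  expect_equal(pr[, , 1], p1, tolerance = 1e-12)
  expect_equal(pr[, , 2], 2 * p1, tolerance = 1e-12)
})
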