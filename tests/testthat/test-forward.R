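test_that("TIRF matrix matches element-wise evaluation of the exponential law", {
  set.seed(11)
  grid <- gridSpec(4, 4, nz = 7, dz_nm = 15, z0_nm = 5)
  i0 <- runif(3, 0.5, 2)
  p <- sort(runif(3, 1e-3, 2e-2))
  Tz <- buildTirfMatrix(list(i0 = i0, p = p), grid)
  expect_equal(Tz, bruteTirfMatrix(i0, p, zCenters(grid), grid@dz_nm),
               tolerance = 1e-14)
  expect_true(all(Tz > 0))
  # rows strictly decreasing with depth
  expect_true(all(apply(Tz, 1, function(r) all(diff(r) < 0))))

  # widefield limit p = 0: constant row = i0 * dz (axial sum projection)
  Tw <- buildTirfMatrix(list(i0 = c(1, 2), p = c(0, 0)), grid)
  expect_equal(Tw, matrix(c(1, 2), 2, 7) * grid@dz_nm, tolerance = 1e-14)

  # entry at z = 1/p equals i0 * dz / e
  p1 <- 1 / zCenters(grid)[4]
  T1 <- buildTirfMatrix(list(i0 = c(1, 1), p = c(p1, 2 * p1)), grid)
  expect_equal(T1[1, 4], grid@dz_nm / exp(1), tolerance = 1e-14)

  # exact per-slab quadrature agrees with numeric integration
  Te <- buildTirfMatrix(list(i0 = i0, p = p), grid, quadrature = "exact")
  for (m in 1:3) for (j in 1:7) {
    zj <- zCenters(grid)[j]
    q <- integrate(function(z) i0[m] * exp(-z * p[m]),
                   zj - grid@dz_nm / 2, zj + grid@dz_nm / 2)$value
    expect_equal(Te[m, j], q, tolerance = 1e-10)
  }
})

test_that("T and its adjoint agree with brute-force loops and each other", {
  set.seed(12)
  ex <- smallExcitation(2)
  grid <- gridSpec(4, 4, nz = 3)
  Tz <- buildTirfMatrix(ex, grid)
  f <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(applyTirf(Tz, f), bruteApplyT(Tz, f), tolerance = 1e-12)

  # impulse: unit voxel at (x, y, j) lights pixel (x, y) with Tz[m, j]
  f1 <- array(0, c(4, 4, 3)); f1[2, 3, 2] <- 1
  g1 <- applyTirf(Tz, f1)
  expect_equal(g1[2, 3, ], Tz[, 2])
  g1[2, 3, ] <- 0
  expect_true(all(g1 == 0))

  expect_true(all(applyTirf(Tz, array(0, c(4, 4, 3))) == 0))

  # adjoint identity and dense-matrix transpose oracle
  for (rep in 1:5) {
    f <- array(runif(4 * 4 * 3), c(4, 4, 3))
    g <- array(runif(4 * 4 * 2), c(4, 4, 2))
    expect_lt(abs(sum(applyTirf(Tz, f) * g) -
                    sum(f * applyTirfAdjoint(Tz, g))) /
                abs(sum(f * applyTirfAdjoint(Tz, g))), 1e-12)
  }
  # vectorized dense oracle: out[i, ] = t(Tz) %*% g[i, ]
  G <- matrix(array(runif(32), c(4, 4, 2)), 16, 2)
  dense <- G %*% Tz
  expect_equal(matrix(applyTirfAdjoint(Tz, array(G, c(4, 4, 2))), 16, 3),
               dense, tolerance = 1e-13)

  expect_error(applyTirf(Tz, array(0, c(4, 4, 5))), "slices")
  expect_error(applyTirfAdjoint(Tz, array(0, c(4, 4, 5))), "pages")
})

test_that("slice-wise PSF convolution matches a sliding-window oracle", {
  set.seed(13)
  k <- matrix(runif(9), 3, 3); k <- k / sum(k)
  psf <- makePsf(NULL, "user_supplied", kernel = k)
  v <- array(runif(8 * 8 * 2), c(8, 8, 2))

  # plain periodic convolution (pad 0) against the brute-force wrap
  hv <- applyPsf(v, psf, pad = 0L)
  for (j in 1:2)
    expect_equal(hv[, , j], bruteConv2Periodic(v[, , j], k),
                 tolerance = 1e-12)

  # delta kernel is the identity
  dpsf <- makePsf(NULL, "delta")
  expect_identical(applyPsf(v, dpsf), v)

  # sum-normalized kernel preserves a constant slice (DC preservation)
  vc <- array(3.7, c(6, 6, 1))
  expect_equal(applyPsf(vc, psf, pad = 0L), vc, tolerance = 1e-12)

  # adjoint identity under the default padded scheme
  for (rep in 1:5) {
    a <- array(runif(7 * 6 * 3), c(7, 6, 3))
    b <- array(runif(7 * 6 * 3), c(7, 6, 3))
    lhs <- sum(applyPsf(a, psf) * b)
    rhs <- sum(a * applyPsfAdjoint(b, psf))
    expect_lt(abs(lhs - rhs) / abs(rhs), 1e-12)
  }

  expect_error(applyPsf(array(0, c(2, 2, 1)), psf, pad = 0L), "larger")
})

test_that("the composed forward model follows g = T H f + b", {
  set.seed(14)
  ex <- smallExcitation(3)
  grid <- gridSpec(6, 6, nz = 4)
  Tz <- buildTirfMatrix(ex, grid)
  k <- matrix(runif(9), 3, 3); k <- k / sum(k)
  psf <- makePsf(NULL, "user_supplied", kernel = k)

  # f = 0 with constant background c gives flat images at c
  g0 <- tirfForward(array(0, c(6, 6, 4)), Tz, psf, background = 2.5)
  expect_true(all(g0 == 2.5))

  # delta PSF reduces forward to T plus background
  f <- array(runif(6 * 6 * 4), c(6, 6, 4))
  b <- c(0.1, 0.2, 0.3)
  gd <- tirfForward(f, Tz, makePsf(NULL, "delta"), b)
  gT <- applyTirf(Tz, f)
  for (m in 1:3) expect_equal(gd[, , m], gT[, , m] + b[m], tolerance = 1e-13)

  # composition against the two brute-force oracles (padded H on the
  # internally extended grid, cropped back)
  gfull <- tirfForward(f, Tz, psf, b)
  hv <- applyPsf(f, psf)
  gref <- bruteApplyT(Tz, hv)
  for (m in 1:3)
    expect_equal(gfull[, , m], gref[, , m] + b[m], tolerance = 1e-12)

  # positivity preservation
  expect_true(all(gfull >= 0))
})

test_that("widefield limit reduces every angle image to the axial sum", {
  set.seed(15)
  grid <- gridSpec(5, 5, nz = 6, dz_nm = 20)
  Tz <- buildTirfMatrix(list(i0 = c(1, 1, 1), p = c(0, 0, 0)), grid)
  f <- array(runif(5 * 5 * 6), c(5, 5, 6))
  g <- tirfForward(f, Tz, makePsf(NULL, "delta"), 0.5)
  proj <- apply(f, 1:2, sum) * grid@dz_nm + 0.5
  for (m in 1:3) expect_equal(g[, , m], proj, tolerance = 1e-12)
})

test_that("total intensity of a buried source decreases with incident angle", {
  ex <- smallExcitation(6)
  grid <- gridSpec(4, 4, nz = 10, dz_nm = 20)
  Tz <- buildTirfMatrix(ex, grid)
  f <- array(0, c(4, 4, 10)); f[2, 2, 6] <- 1    # source at z = 100 nm
  g <- applyTirf(Tz, f)
  totals <- apply(g, 3, sum)
  expect_true(all(diff(totals) < 0))
})

test_that("background estimation is the masked per-angle mean", {
  g <- array(0, c(4, 4, 2))
  g[, , 1] <- 7; g[, , 2] <- 1
  mask <- matrix(FALSE, 4, 4); mask[1:2, 1] <- TRUE
  g[1, 1, 2] <- 1; g[2, 1, 2] <- 3
  bg <- estimateBackground(g, mask)
  expect_equal(bg@level_per_angle, c(7, 2))

  set.seed(16)
  gr <- array(runif(4 * 4 * 3), c(4, 4, 3))
  maskr <- matrix(runif(16) > 0.5, 4, 4)
  bgr <- estimateBackground(gr, maskr)
  for (m in 1:3) expect_equal(bgr@level_per_angle[m], mean(gr[, , m][maskr]))

  expect_error(estimateBackground(gr, matrix(FALSE, 4, 4)), "empty")
})

test_that("PSF construction is normalized, centered and correctly scaled", {
  cfg <- smallOptics()
  psf <- makePsf(cfg, "gaussian")
  expect_equal(sum(psf@kernel), 1, tolerance = 1e-13)
  # isotropy: symmetric under 90 degree rotation
  expect_equal(psf@kernel, t(psf@kernel[nrow(psf@kernel):1, ]),
               tolerance = 1e-13)
  # sigma from adjacent-sample ratio: 0.21 * 491 / 1.49 / 107 ~ 0.647 px
  h <- (nrow(psf@kernel) + 1) / 2
  sigma_px <- sqrt(-0.5 / log(psf@kernel[h + 1, h] / psf@kernel[h, h]))
  expect_equal(sigma_px, 0.21 * 491 / 1.49 / 107, tolerance = 1e-10)
  expect_equal(sigma_px, 0.647, tolerance = 1e-3)

  airy <- makePsf(cfg, "airy")
  expect_equal(sum(airy@kernel), 1, tolerance = 1e-13)
  expect_true(validObject(airy))

  expect_error(makePsf(NULL, "user_supplied", kernel = matrix(0, 3, 3)),
               "normalizable")
  expect_error(makePsf(NULL, "user_supplied", kernel = matrix(1, 2, 2)),
               "odd")
  expect_error(makePsf(cfg, "gaussian", size = 8), "odd")
})
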