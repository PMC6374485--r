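test_that("gradient operator: constants, ramps and the adjoint identity", {
  va <- 20 / 107
  expect_true(all(gradientOp(array(5, c(4, 5, 3)), va) == 0))

  # linear ramp along x: x-component constant at the slope (periodic seam
  # excepted)
  n <- 6; s <- 0.7
  ramp <- array(rep(s * (0:(n - 1)), 4 * 3), c(n, 4, 3))
  gx <- gradientOp(ramp, va)[, , , 1]
  expect_true(all(abs(gx[1:(n - 1), , ] - s) < 1e-12))

  set.seed(21)
  for (rep in 1:5) {
    f <- array(runif(5 * 5 * 3), c(5, 5, 3))
    w <- array(runif(5 * 5 * 3 * 3), c(5, 5, 3, 3))
    lhs <- sum(gradientOp(f, va) * w)
    rhs <- sum(f * gradientAdjoint(w, va))
    expect_lt(abs(lhs - rhs) / abs(rhs), 1e-12)
  }
})

test_that("Hessian operator: affine kernels, quadratics and the weighted adjoint", {
  va <- 0.5
  # affine volumes are annihilated (periodic seam excluded by using
  # constants along each axis)
  expect_true(all(hessianOp(array(3, c(4, 4, 4)), va) == 0))

  # x^2 sampled on the grid: xx-component is 2 at interior points
  n <- 8
  q <- array(rep((0:(n - 1))^2, 5 * 3), c(n, 5, 3))
  hxx <- hessianOp(q, va)[, , , 1]
  expect_true(all(abs(hxx[2:(n - 1), , ] - 2) < 1e-12))

  # adjoint identity under the symmetric-matrix (Frobenius) inner product:
  # cross fields count twice
  set.seed(22)
  wt <- c(1, 1, 1, 2, 2, 2)
  for (rep in 1:5) {
    f <- array(runif(4 * 4 * 3), c(4, 4, 3))
    w <- array(runif(4 * 4 * 3 * 6), c(4, 4, 3, 6))
    H <- hessianOp(f, va)
    lhs <- sum(vapply(1:6, function(k) wt[k] * sum(H[, , , k] * w[, , , k]), 0))
    rhs <- sum(f * hessianAdjoint(w, va))
    expect_lt(abs(lhs - rhs) / abs(rhs), 1e-12)
  }
})

test_that("penalty values follow the mixed-norm definitions", {
  va <- 20 / 107
  tv <- regularizerSpec("tv", mu = 2, voxel_aspect = va)
  hs <- regularizerSpec("hessian_schatten1", mu = 2, voxel_aspect = va)

  expect_equal(regValue(tv, array(4, c(4, 4, 3))), 0)
  expect_equal(regValue(hs, array(4, c(4, 4, 3))), 0)

  # single-voxel impulse: TV value by direct accumulation of voxel norms
  f <- array(0, c(4, 4, 3)); f[2, 2, 2] <- 1.5
  g <- gradientOp(f, va)
  brute <- 0
  for (x in 1:4) for (y in 1:4) for (z in 1:3)
    brute <- brute + sqrt(sum(g[x, y, z, ]^2))
  expect_equal(regValue(tv, f), 2 * brute, tolerance = 1e-12)

  # Hessian-Schatten value against per-voxel sum of |eigenvalues|
  set.seed(23)
  fr <- array(runif(4 * 4 * 3), c(4, 4, 3))
  H <- hessianOp(fr, va)
  acc <- 0
  for (x in 1:4) for (y in 1:4) for (z in 1:3)
    acc <- acc + nuclear3(sym3(H[x, y, z, ]))
  expect_equal(regValue(hs, fr), 2 * acc, tolerance = 1e-10)

  expect_error(regularizerSpec("ridge", mu = 1, voxel_aspect = 1))
  expect_error(regularizerSpec("tv", voxel_aspect = 1), "mu")
})

test_that("group soft-thresholding is the exact l2,1 prox", {
  set.seed(24)
  # shrinkage to zero when the norm is under the threshold
  w <- array(0, c(1, 1, 1, 3)); w[1, 1, 1, ] <- c(0.1, 0.2, -0.1)
  expect_true(all(proxTvVector(w, 1) == 0))
  # tau = 0 is the identity
  wr <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  expect_identical(proxTvVector(wr, 0), wr)
  # random voxels against the 1D radial oracle
  for (rep in 1:20) {
    v <- rnorm(3, sd = 2)
    tau <- runif(1, 0, 3)
    w1 <- array(v, c(1, 1, 1, 3))
    expect_equal(as.vector(proxTvVector(w1, tau)), oracleGroupProx(v, tau),
                 tolerance = 1e-6)
  }
})

test_that("eigenvalue soft-thresholding is the exact nuclear-norm prox", {
  # diagonal case: diag(3, -1, 0) at tau = 1 -> diag(2, 0, 0)
  r <- c(3, -1, 0, 0, 0, 0)
  w <- array(r, c(1, 1, 1, 6))
  expect_equal(as.vector(proxSchatten1(w, 1)), c(2, 0, 0, 0, 0, 0),
               tolerance = 1e-12)
  # tau = 0 identity
  set.seed(25)
  wr <- array(rnorm(2 * 2 * 1 * 6), c(2, 2, 1, 6))
  expect_identical(proxSchatten1(wr, 0), wr)
  # random symmetric matrices against the derivative-free oracle
  for (rep in 1:8) {
    r <- rnorm(6)
    got <- as.vector(proxSchatten1(array(r, c(1, 1, 1, 6)), 0.5))
    ora <- oracleNuclearProx(r, 0.5)
    expect_equal(got, ora, tolerance = 5e-3)
    # and optimality: the returned point has no lower objective nearby
    obj <- function(q) {
      D <- sym3(q) - sym3(r)
      0.5 * nuclear3(sym3(q)) +
        0.5 * (sum(diag(D)^2) + 2 * (D[1, 2]^2 + D[1, 3]^2 + D[2, 3]^2))
    }
    for (k in 1:6) {
      e <- rep(0, 6); e[k] <- 1e-4
      expect_lte(obj(got), obj(got + e) + 1e-12)
      expect_lte(obj(got), obj(got - e) + 1e-12)
    }
  }
})

test_that("prox operators are firmly nonexpansive and vanish as tau grows", {
  set.seed(26)
  wt <- c(1, 1, 1, 2, 2, 2)
  for (rep in 1:10) {
    a3 <- array(rnorm(8 * 3), c(2, 2, 2, 3))
    b3 <- array(rnorm(8 * 3), c(2, 2, 2, 3))
    tau <- runif(1, 0, 2)
    expect_lte(sum((proxTvVector(a3, tau) - proxTvVector(b3, tau))^2),
               sum((a3 - b3)^2) + 1e-12)
    a6 <- array(rnorm(8 * 6), c(2, 2, 2, 6))
    b6 <- array(rnorm(8 * 6), c(2, 2, 2, 6))
    wnorm2 <- function(x) sum(sweep(x, 4, wt, `*`) * x)
    expect_lte(wnorm2(proxSchatten1(a6, tau) - proxSchatten1(b6, tau)),
               wnorm2(a6 - b6) + 1e-12)
  }
  a3 <- array(rnorm(8 * 3), c(2, 2, 2, 3))
  a6 <- array(rnorm(8 * 6), c(2, 2, 2, 6))
  expect_true(all(proxTvVector(a3, 1e9) == 0))
  expect_true(all(abs(proxSchatten1(a6, 1e9)) < 1e-12))
})

test_that("the TV prox satisfies the Moreau identity", {
  # prox_{tau f}(v) + tau * proj_{||.||2 <= 1}(v / tau) = v per voxel
  set.seed(27)
  for (rep in 1:10) {
    v <- rnorm(3, sd = 2)
    tau <- runif(1, 0.1, 2)
    pv <- as.vector(proxTvVector(array(v, c(1, 1, 1, 3)), tau))
    u <- v / tau
    proj <- if (sqrt(sum(u^2)) > 1) u / sqrt(sum(u^2)) else u
    expect_equal(pv + tau * proj, v, tolerance = 1e-12)
  }
})

test_that("zero penalty characterizes the regularizer null space", {
  va <- 1
  tv <- regularizerSpec("tv", mu = 1, voxel_aspect = va)
  hs <- regularizerSpec("hessian_schatten1", mu = 1, voxel_aspect = va)
  # constants: TV and Hessian both zero
  expect_equal(regValue(tv, array(2, c(3, 3, 3))), 0)
  expect_equal(regValue(hs, array(2, c(3, 3, 3))), 0)
  # non-constant volume: strictly positive for both
  set.seed(28)
  f <- array(runif(27), c(3, 3, 3))
  expect_gt(regValue(tv, f), 0)
  expect_gt(regValue(hs, f), 0)
})
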