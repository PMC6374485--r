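test_that("the Fourier denominator inverts the f-update operator exactly", {
  set.seed(31)
  dims <- c(6, 6, 3)
  k <- matrix(runif(9), 3, 3); k <- k / sum(k)
  psf <- makePsf(NULL, "user_supplied", kernel = k)
  reg <- regularizerSpec("tv", mu = 1, voxel_aspect = 0.4)
  rho <- c(1.3, 0.7, 0.5)
  den <- fourierDenominator(psf, reg, dims, rho[1], rho[2], rho[3])
  expect_true(all(den > 0))

  # solving then re-applying (rho1 H'H + rho2 L'L + rho3 I) recovers rhs
  rhs <- array(rnorm(prod(dims)), dims)
  f <- Re(fft(fft(rhs) / den, inverse = TRUE)) / prod(dims)
  back <- rho[1] * applyPsfAdjoint(applyPsf(f, psf, pad = 0L), psf, pad = 0L) +
    rho[2] * gradientAdjoint(gradientOp(f, 0.4), 0.4) + rho[3] * f
  expect_equal(back, rhs, tolerance = 1e-10)

  # delta PSF without operator terms: constant rho1 + rho3
  dden <- fourierDenominator(makePsf(NULL, "delta"), NULL, dims, 2, 1, 0.25)
  expect_equal(as.vector(dden), rep(2.25, prod(dims)), tolerance = 1e-12)

  # DC component: |h^(0)|^2 = 1 for a normalized kernel and gradient
  # kills DC, so the value at frequency zero is rho1 + rho3
  expect_equal(den[1, 1, 1], rho[1] + rho[3], tolerance = 1e-12)
})

test_that("objective evaluation matches term-by-term accumulation", {
  set.seed(32)
  ex <- smallExcitation(3)
  grid <- gridSpec(5, 5, nz = 4)
  Tz <- buildTirfMatrix(ex, grid)
  psf <- makePsf(NULL, "delta")
  reg <- regularizerSpec("tv", mu = 0.3, voxel_aspect = 0.2)

  expect_equal(objectiveValue(array(0, c(5, 5, 4)), array(0, c(5, 5, 3)),
                              Tz, psf, 0, reg), 0)
  fneg <- array(0, c(5, 5, 4)); fneg[1, 1, 1] <- -1
  expect_identical(objectiveValue(fneg, array(0, c(5, 5, 3)), Tz, psf, 0,
                                  reg), Inf)

  f <- array(runif(5 * 5 * 4), c(5, 5, 4))
  g <- array(runif(5 * 5 * 3), c(5, 5, 3))
  b <- c(0.1, 0.2, 0.3)
  got <- objectiveValue(f, g, Tz, psf, b, reg)
  # brute force: data term by loops, TV term by per-voxel accumulation
  data_term <- 0
  gT <- bruteApplyT(Tz, f)
  for (m in 1:3) data_term <- data_term + 0.5 * sum((gT[, , m] -
                                                       (g[, , m] - b[m]))^2)
  gr <- gradientOp(f, 0.2)
  tv_term <- 0
  for (x in 1:5) for (y in 1:5) for (z in 1:4)
    tv_term <- tv_term + sqrt(sum(gr[x, y, z, ]^2))
  expect_equal(got, data_term + 0.3 * tv_term, tolerance = 1e-11)
})

test_that("zero data yields the zero reconstruction", {
  ex <- smallExcitation(4)
  grid <- gridSpec(6, 6, nz = 5)
  Tz <- buildTirfMatrix(ex, grid)
  reg <- regularizerSpec("tv", mu = 1e-2, voxel_aspect = 0.2)
  res <- admmReconstruct(array(0, c(6, 6, 4)), Tz, makePsf(NULL, "delta"),
                         0, reg, solverOptions(n_iter = 20))
  expect_true(all(res@volume@values == 0))
})

test_that("single-pixel axial profile matches a constrained least-squares oracle", {
  # noiseless bright slab at slice 3, tiny mu, delta PSF: compare against
  # projected L-BFGS-B on the pure data term
  ex <- smallExcitation(8)
  grid <- gridSpec(1, 1, nz = 6)
  Tz <- buildTirfMatrix(ex, grid)
  f_true <- array(0, c(1, 1, 6)); f_true[1, 1, 3] <- 2
  g <- applyTirf(Tz, f_true)
  reg <- regularizerSpec("tv", mu = 1e-9, voxel_aspect = 0.2)
  res <- admmReconstruct(g, Tz, makePsf(NULL, "delta"), 0, reg,
                         solverOptions(n_iter = 3000, normalize = FALSE),
                         grid = grid)
  ls <- function(x) 0.5 * sum((as.vector(Tz %*% x) - as.vector(g))^2)
  gr <- function(x) as.vector(crossprod(Tz, Tz %*% x - as.vector(g)))
  fit <- optim(rep(0, 6), ls, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = 5000, factr = 10))
  cen <- function(v) sum(seq_along(v) * v) / sum(v)
  expect_lt(abs(cen(res@volume@values[1, 1, ]) - cen(fit$par)), 1)
  expect_lt(abs(cen(res@volume@values[1, 1, ]) - 3), 1)   # within dz of truth
})

test_that("ADMM reaches the variational minimum found by an independent solver", {
  set.seed(33)
  ex <- smallExcitation(4)
  grid <- gridSpec(6, 6, nz = 4)
  Tz <- buildTirfMatrix(ex, grid)
  k <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 16
  psf <- makePsf(NULL, "user_supplied", kernel = k)
  va <- 0.25
  mu <- 5e-3
  f_true <- array(0, c(6, 6, 4))
  f_true[2:4, 2:4, 2] <- 1; f_true[4:5, 4:5, 3] <- 0.5
  g <- tirfForward(f_true, Tz, psf)
  g <- g / max(g)
  reg <- regularizerSpec("tv", mu = mu, voxel_aspect = va)
  res <- admmReconstruct(g, Tz, psf, 0, reg,
                         solverOptions(n_iter = 8000, normalize = FALSE,
                                       tol_primal = 5e-5))

  # the solver works on the grid padded by the PSF half-width with
  # periodic operators; evaluate both candidates on that same problem
  pad <- c(1L, 1L)
  gp <- array(0, c(8, 8, 4)); gp[2:7, 2:7, ] <- g
  f_admm <- pmax(res@state@u3, 0)
  f_oracle <- oracleSolveTV(gp, Tz, psf, mu, va)
  obj <- function(f) objectiveValue(f, gp, Tz, psf, 0, reg)
  expect_lt(abs(obj(f_admm) - obj(f_oracle)) / obj(f_oracle), 1e-3)

  # primal feasibility at convergence
  expect_lt(res@state@primal_residual, 1e-4)
})

test_that("joint mode with a delta PSF equals the no-deconvolution mode bitwise", {
  set.seed(34)
  ex <- smallExcitation(4)
  grid <- gridSpec(6, 6, nz = 4)
  Tz <- buildTirfMatrix(ex, grid)
  g <- array(runif(6 * 6 * 4), c(6, 6, 4))
  reg <- regularizerSpec("tv", mu = 1e-2, voxel_aspect = 0.2)
  r1 <- admmReconstruct(g, Tz, makePsf(NULL, "delta"), 0, reg,
                        solverOptions(n_iter = 40, deconvolve = TRUE))
  r2 <- admmReconstruct(g, Tz, makePsf(smallOptics(), "gaussian"), 0, reg,
                        solverOptions(n_iter = 40, deconvolve = FALSE))
  expect_identical(r1@volume@values, r2@volume@values)
  expect_identical(r1@state@f, r2@state@f)
})

test_that("the solver is deterministic", {
  set.seed(35)
  ex <- smallExcitation(3)
  Tz <- buildTirfMatrix(ex, gridSpec(5, 5, nz = 4))
  g <- array(runif(5 * 5 * 3), c(5, 5, 3))
  reg <- regularizerSpec("hessian_schatten1", mu = 1e-2, voxel_aspect = 0.2)
  r1 <- admmReconstruct(g, Tz, makePsf(NULL, "delta"), 0, reg,
                        solverOptions(n_iter = 25))
  r2 <- admmReconstruct(g, Tz, makePsf(NULL, "delta"), 0, reg,
                        solverOptions(n_iter = 25))
  expect_identical(r1@volume@values, r2@volume@values)
})

test_that("two buried sheets are localized within one axial step", {
  # laterally separated sheets at 60 and 260 nm, 10 angles, mild noise
  cfg <- smallOptics()
  aset <- angleDesign(cfg, 10)
  ex <- excitationModel(cfg, aset)
  grid <- gridSpec(16, 16, nz = 20, dz_nm = 20, pixel_size_nm = 107)
  vol <- sheetPhantom(c(60, 260), masses = c(1, 1), grid,
                      layout = "disjoint")
  stk <- simulateAcquisition(vol, ex, makePsf(NULL, "delta"), 0,
                             noiseSpec("gaussian", gaussian_sigma = 0.3,
                                       seed = 5))
  Tz <- buildTirfMatrix(ex, grid)
  reg <- regularizerSpec("tv", mu = 3e-3, voxel_aspect = 20 / 107)
  res <- admmReconstruct(stk, Tz, makePsf(NULL, "delta"), 0, reg,
                         solverOptions(n_iter = 400), grid = grid)
  v <- res@volume@values
  zc <- zCenters(grid)
  cen <- function(block) {
    prof <- apply(block, 3, sum)
    sum(zc * prof) / sum(prof)
  }
  expect_lt(abs(cen(v[1:8, , ]) - 60), 20)
  expect_lt(abs(cen(v[9:16, , ]) - 260), 20)
})

test_that("the recorded objective decreases toward convergence", {
  set.seed(36)
  ex <- smallExcitation(4)
  grid <- gridSpec(6, 6, nz = 4)
  Tz <- buildTirfMatrix(ex, grid)
  f_true <- array(0, c(6, 6, 4)); f_true[3:4, 3:4, 2] <- 1
  g <- tirfForward(f_true, Tz, makePsf(NULL, "delta"))
  reg <- regularizerSpec("tv", mu = 1e-3, voxel_aspect = 0.2)
  res <- admmReconstruct(g, Tz, makePsf(NULL, "delta"), 0, reg,
                         solverOptions(n_iter = 150, record_objective = TRUE))
  tr <- res@state@objective_trace
  expect_length(tr, 150)
  expect_lt(tr[150], tr[5])
  expect_true(all(is.finite(tr)))
})
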