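# Independent brute-force oracles and small shared fixtures.

relerr <- function(a, b) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) sqrt(sum(a^2)) else sqrt(sum((a - b)^2)) / nb
}

smallOptics <- function(pixel_size_nm = 107) {
  opticalConfig(wavelength_nm = 491, n_incident = 1.515, n_sample = 1.33,
                numerical_aperture = 1.49, pixel_size_nm = pixel_size_nm)
}

smallExcitation <- function(M = 4, cfg = smallOptics()) {
  excitationModel(cfg, angleSet(seq(63, 75, length.out = M), cfg))
}

# direct element-wise evaluation of the depth-weighting matrix
bruteTirfMatrix <- function(i0, p, zc, dz) {
  M <- length(p); Nz <- length(zc)
  Tz <- matrix(0, M, Nz)
  for (m in seq_len(M))
    for (j in seq_len(Nz))
      Tz[m, j] <- i0[m] * exp(-zc[j] * p[m]) * dz
  Tz
}

# triple-loop application of T
bruteApplyT <- function(Tz, f) {
  d <- dim(f)
  out <- array(0, c(d[1], d[2], nrow(Tz)))
  for (m in seq_len(nrow(Tz)))
    for (x in seq_len(d[1]))
      for (y in seq_len(d[2]))
        out[x, y, m] <- sum(Tz[m, ] * f[x, y, ])
  out
}

# sliding-window periodic 2D convolution (kernel centered)
bruteConv2Periodic <- function(img, kernel) {
  n1 <- nrow(img); n2 <- ncol(img)
  k1 <- nrow(kernel); k2 <- ncol(kernel)
  c1 <- (k1 + 1) / 2; c2 <- (k2 + 1) / 2
  out <- matrix(0, n1, n2)
  for (x in seq_len(n1)) for (y in seq_len(n2)) {
    s <- 0
    for (a in seq_len(k1)) for (b in seq_len(k2)) {
      xx <- ((x - (a - c1) - 1) %% n1) + 1
      yy <- ((y - (b - c2) - 1) %% n2) + 1
      s <- s + kernel[a, b] * img[xx, yy]
    }
    out[x, y] <- s
  }
  out
}

# 1D oracle for the group soft-threshold: shrink the radius numerically
oracleGroupProx <- function(v, tau) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(v * 0)
  obj <- function(s) tau * s + 0.5 * (s - nv)^2
  s_opt <- stats::optimize(obj, c(0, nv + 2 * tau))$minimum
  if (obj(0) <= obj(s_opt)) s_opt <- 0
  v * s_opt / nv
}

sym3 <- function(r) matrix(c(r[1], r[4], r[5],
                             r[4], r[2], r[6],
                             r[5], r[6], r[3]), 3, 3)

nuclear3 <- function(A) sum(abs(eigen(A, symmetric = TRUE,
                                      only.values = TRUE)$values))

# derivative-free oracle for the nuclear-norm prox of a symmetric matrix
oracleNuclearProx <- function(r, tau) {
  obj <- function(q) {
    U <- sym3(q)
    D <- U - sym3(r)
    tau * nuclear3(U) + 0.5 * (sum(diag(D)^2) + 2 * (D[1, 2]^2 + D[1, 3]^2 +
                                                     D[2, 3]^2))
  }
  fit <- stats::optim(r, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
  fit2$par
}

# independent first-order reference solver for the variational problem:
# projected L-BFGS-B on the epsilon-smoothed isotropic TV objective.
# Operators are applied with plain periodic boundary (pad 0), matching
# objectiveValue()'s convention.
oracleSolveTV <- function(g, Tz, psf, mu, voxel_aspect, eps = 1e-8,
                          maxit = 20000) {
  d <- c(dim(g)[1:2], ncol(Tz))
  delta <- all(dim(psf@kernel) == c(1L, 1L))
  Hx <- function(v) if (delta) v else applyPsf(v, psf, pad = 0L)
  Ht <- function(v) if (delta) v else applyPsfAdjoint(v, psf, pad = 0L)
  fn <- function(x) {
    f <- array(x, d)
    r <- applyTirf(Tz, Hx(f)) - g
    gr <- gradientOp(f, voxel_aspect)
    0.5 * sum(r^2) + mu * sum(sqrt(apply(gr^2, 1:3, sum) + eps^2))
  }
  gr <- function(x) {
    f <- array(x, d)
    r <- applyTirf(Tz, Hx(f)) - g
    gf <- gradientOp(f, voxel_aspect)
    nrm <- sqrt(apply(gf^2, 1:3, sum) + eps^2)
    w <- gf / as.vector(nrm)
    as.vector(Ht(applyTirfAdjoint(Tz, r)) + mu * gradientAdjoint(w, voxel_aspect))
  }
  fit <- stats::optim(rep(0, prod(d)), fn, gr, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = maxit, factr = 10))
  array(fit$par, d)
}
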