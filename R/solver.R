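## ADMM for the variational MA-TIRF reconstruction
##
##   min_f  1/2 ||T H f - g||^2 + mu R(L f) + i_{>=0}(f)
##
## split with auxiliary variables u1 = Hf, u2 = Lf, u3 = f. Every
## subproblem has a direct solve (no inner iterations): the u1-update is a
## per-pixel Nz x Nz linear solve with one Cholesky factorization shared by
## all pixels and iterations; the u2-update is the exact prox of the mixed
## norm; the u3-update is a projection onto the nonnegative orthant; the
## f-update is diagonal in the Fourier domain because H and L are periodic
## convolutions on the (padded) grid.

## Frobenius-consistent inner-product weights of the regularizer field
.regWeights <- function(spec) {
  if (spec@kind == "tv") rep(1, 3L) else c(1, 1, 1, 2, 2, 2)
}

## squared W-norm of a regularizer field
.regNorm2 <- function(spec, w) {
  wt <- .regWeights(spec)
  d <- dim(w)
  s <- 0
  for (k in seq_len(d[4])) s <- s + wt[k] * sum(w[, , , k]^2)
  s
}

#' Frequency-domain denominator of the ADMM f-update
#'
#' The f-update solves \code{(rho1 H'H + rho2 L'L + rho3 I) f = rhs}.
#' Because H and L are periodic convolutions, the left-hand operator is
#' diagonal in the 3D Fourier domain; this returns its (strictly positive)
#' eigenvalue array, obtained by transforming the impulse response of
#' \code{rho1 H'H + rho2 L'L + rho3 I}. \code{rho3 > 0} guarantees
#' invertibility.
#'
#' @param psf a [PSFModel-class] (periodic convolution on the grid of
#'   \code{dims}).
#' @param reg a [RegularizerSpec-class] selecting L, or NULL for no
#'   regularization operator term.
#' @param dims grid dimensions \code{c(nx, ny, nz)} the solve runs on.
#' @param rho1,rho2,rho3 ADMM penalties.
#' @return Real array of dimension \code{dims} with the frequency-domain
#'   multiplier.
#' @export
fourierDenominator <- function(psf, reg, dims, rho1 = 1, rho2 = 1, rho3 = 1) {
  delta <- array(0, dims)
  delta[1, 1, 1] <- 1
  acc <- rho3 * delta
  acc <- acc + rho1 * .convSlices(.convSlices(delta, psf@kernel, c(0L, 0L)),
                                  psf@kernel, c(0L, 0L), adjoint = TRUE)
  if (!is.null(reg))
    acc <- acc + rho2 * .regAdjoint(reg, .regOp(reg, delta))
  den <- Re(stats::fft(acc))
  if (any(den <= 0))
    stop("non-positive Fourier denominator; increase rho3")
  den
}

## zero-pad a 3D array laterally by pad pixels on each side
.padLateral <- function(v, pad) {
  if (all(pad == 0L)) return(v)
  d <- dim(v)
  out <- array(0, c(d[1] + 2L * pad[1], d[2] + 2L * pad[2], d[3]))
  out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), ] <- v
  out
}

.cropLateral <- function(v, pad, d) {
  if (all(pad == 0L)) return(v)
  v[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), , drop = FALSE]
}

#' Value of the reconstruction objective
#'
#' Evaluates \code{1/2 ||T H f - (g - b)||^2 + mu R(L f)} plus the
#' nonnegativity indicator (\code{+Inf} if any voxel is negative beyond a
#' tiny tolerance). H is applied as a periodic convolution on the grid of
#' \code{f} (no extra padding), matching the solver's internal model.
#'
#' @param f 3D array or [FluorophoreVolume-class].
#' @param stack data stack (array or [AcquisitionStack-class]).
#' @param Tz M x Nz TIRF matrix.
#' @param psf a [PSFModel-class].
#' @param background per-angle background (numeric, [BackgroundModel-class]
#'   or 0).
#' @param reg a [RegularizerSpec-class].
#' @param tol negativity tolerance for the indicator term.
#' @return Scalar objective value (possibly \code{Inf}).
#' @export
objectiveValue <- function(f, stack, Tz, psf, background = 0, reg,
                           tol = 1e-12) {
  v <- if (is(f, "FluorophoreVolume")) f@values else f
  g <- if (is(stack, "AcquisitionStack")) stack@images else stack
  if (any(v < -tol)) return(Inf)
  b <- if (is(background, "BackgroundModel")) background@level_per_angle
       else rep_len(as.numeric(background), nrow(Tz))
  for (m in seq_len(nrow(Tz))) g[, , m] <- g[, , m] - b[m]
  hv <- if (all(dim(psf@kernel) == c(1L, 1L))) v
        else .convSlices(v, psf@kernel, c(0L, 0L))
  resid <- applyTirf(Tz, hv) - g
  0.5 * sum(resid^2) + regValue(reg, v)
}

#' Joint deconvolution and axial reconstruction by ADMM
#'
#' Estimates the nonnegative fluorophore volume from a multi-angle TIRF
#' stack by solving the variational problem
#' \code{min 1/2 ||THf - g||^2 + mu R(Lf) + i_{>=0}(f)} with the method of
#' multipliers on the splitting u1 = Hf, u2 = Lf, u3 = f. Each iteration
#' performs, in order: the u1 data solve (shared Cholesky of
#' \code{T'T + rho1 I}), the u2 regularizer prox, the u3 nonnegative
#' projection, the exact Fourier-domain f solve, and the dual ascent. All
#' updates are direct; the solver is fully deterministic.
#'
#' The background is subtracted from the data before solving (negative
#' residual pixels are kept to avoid bias) and, with \code{normalize} on,
#' the subtracted data are scaled to peak 1 (so \code{mu} refers to
#' peak-normalized data); the returned volume is scaled back. When
#' \code{deconvolve} is off the PSF is replaced by the identity. The
#' lateral grid is internally extended by the PSF half-width so the
#' periodic convolution cannot wrap structure across the field of view;
#' the returned volume is cropped back.
#'
#' @param stack an [AcquisitionStack-class] or \code{nx x ny x M} array.
#' @param Tz M x Nz matrix from [buildTirfMatrix()].
#' @param psf a [PSFModel-class].
#' @param background per-angle background levels
#'   ([BackgroundModel-class], numeric or 0).
#' @param reg a [RegularizerSpec-class].
#' @param opts a [SolverOptions-class].
#' @param grid optional [GridSpec-class] describing the reconstruction
#'   grid (defaults to the stack's lateral geometry with
#'   \code{ncol(Tz)} slices of 20 nm).
#' @return A [ReconstructionResult-class]; the volume is the nonnegative
#'   u3 iterate.
#' @examples
#' cfg <- opticalConfig()
#' aset <- angleSet(seq(63, 74, length.out = 6), cfg)
#' ex <- excitationModel(cfg, aset)
#' grid <- gridSpec(8, 8, nz = 10)
#' Tz <- buildTirfMatrix(ex, grid)
#' f <- array(0, c(8, 8, 10)); f[3:6, 3:6, 4] <- 1
#' g <- tirfForward(f, Tz, makePsf(cfg, "delta"))
#' reg <- regularizerSpec("tv", mu = 1e-3, voxel_aspect = 20 / 107)
#' res <- admmReconstruct(g, Tz, makePsf(cfg, "delta"), 0, reg,
#'                        solverOptions(n_iter = 30), grid = grid)
#' @export
admmReconstruct <- function(stack, Tz, psf, background = 0, reg, opts,
                            grid = NULL) {
  stopifnot(is(reg, "RegularizerSpec"), is(opts, "SolverOptions"))
  g <- if (is(stack, "AcquisitionStack")) stack@images else stack
  d <- dim(g)
  M <- nrow(Tz); Nz <- ncol(Tz)
  if (d[3] != M) stop("stack has ", d[3], " pages but Tz has ", M, " rows")
  px <- if (is(stack, "AcquisitionStack")) stack@pixel_size_nm else 107
  if (is.null(grid)) grid <- gridSpec(d[1], d[2], nz = Nz, pixel_size_nm = px)
  if (grid@nx != d[1] || grid@ny != d[2] || grid@nz != Nz)
    stop("grid incompatible with stack/Tz dimensions")

  ## background subtraction, optional peak normalization
  b <- if (is(background, "BackgroundModel")) background@level_per_angle
       else rep_len(as.numeric(background), M)
  for (m in seq_len(M)) g[, , m] <- g[, , m] - b[m]
  scale <- 1
  if (opts@normalize) {
    scale <- max(abs(g))
    if (scale == 0) scale <- 1
    g <- g / scale
  }

  if (!opts@deconvolve) psf <- makePsf(NULL, "delta")
  pad <- (dim(psf@kernel) - 1L) %/% 2L
  dv <- c(d[1] + 2L * pad[1], d[2] + 2L * pad[2], Nz)  # padded volume dims
  gp <- .padLateral(g, pad)                            # padded data (zeros outside)
  npix <- dv[1] * dv[2]

  ## precomputations shared by all iterations
  A <- crossprod(Tz) + opts@rho1 * diag(Nz)            # Nz x Nz
  R <- chol(A)
  TtG <- matrix(gp, npix, M) %*% Tz                    # npix x Nz, = (T' g)'
  den <- fourierDenominator(psf, reg, dv, opts@rho1, opts@rho2, opts@rho3)
  delta_psf <- all(dim(psf@kernel) == c(1L, 1L))
  Hf <- function(v) if (delta_psf) v else .convSlices(v, psf@kernel, c(0L, 0L))
  Ht <- function(v) if (delta_psf) v
        else .convSlices(v, psf@kernel, c(0L, 0L), adjoint = TRUE)
  nf <- .regFields(reg)

  f  <- array(0, dv)
  u1 <- array(0, dv); d1 <- array(0, dv)
  u2 <- array(0, c(dv, nf)); d2 <- array(0, c(dv, nf))
  u3 <- array(0, dv); d3 <- array(0, dv)
  trace <- if (opts@record_objective) numeric(opts@n_iter) else numeric(0)
  rp <- NA_real_
  it_done <- 0L

  for (it in seq_len(opts@n_iter)) {
    hf <- Hf(f)
    lf <- .regOp(reg, f)

    ## u1: (T'T + rho1 I) u1_i = T' g_i + rho1 (Hf + d1)_i, per pixel
    V <- TtG + opts@rho1 * matrix(hf + d1, npix, Nz)
    u1 <- array(t(backsolve(R, backsolve(R, t(V), transpose = TRUE))), dv)

    ## u2: prox of (mu / rho2) * mixed norm at Lf + d2
    u2 <- .regProx(reg, lf + d2, reg@mu / opts@rho2)

    ## u3: projection onto the nonnegative orthant
    u3 <- pmax(f + d3, 0)

    ## f: exact Fourier solve of
    ## (rho1 H'H + rho2 L'L + rho3 I) f = rho1 H'(u1-d1) + rho2 L'(u2-d2)
    ##                                    + rho3 (u3-d3)
    rhs <- opts@rho1 * Ht(u1 - d1) + opts@rho2 * .regAdjoint(reg, u2 - d2) +
      opts@rho3 * (u3 - d3)
    f <- Re(stats::fft(stats::fft(rhs) / den, inverse = TRUE)) / prod(dv)

    ## dual ascent
    hf <- Hf(f)
    lf <- .regOp(reg, f)
    d1 <- d1 + hf - u1
    d2 <- d2 + lf - u2
    d3 <- d3 + f - u3

    if (!all(is.finite(f)))
      stop("solver diverged (non-finite values) at iteration ", it)
    it_done <- it

    if (opts@record_objective)
      trace[it] <- 0.5 * sum((applyTirf(Tz, Hf(pmax(f, 0))) - gp)^2) +
        regValue(reg, pmax(f, 0))

    nr <- function(a, b) {
      nb <- sqrt(sum(b^2))
      if (nb == 0) sqrt(sum(a^2)) else sqrt(sum((a - b)^2)) / nb
    }
    rp <- max(nr(u1, hf), nr(u2, lf), nr(u3, f))
    if (is.finite(opts@tol_primal) && rp < opts@tol_primal) break
  }

  fout <- .cropLateral(pmax(u3, 0), pad, d) * scale
  vol <- fluorophoreVolume(fout, grid)
  state <- new("SolverState", f = f, u1 = u1, u2 = u2, u3 = u3,
               d1 = d1, d2 = d2, d3 = d3, it = it_done,
               objective_trace = if (opts@record_objective)
                 trace[seq_len(it_done)] else numeric(0),
               primal_residual = rp)
  new("ReconstructionResult", volume = vol, state = state,
      settings = list(reg_kind = reg@kind, mu = reg@mu,
                      voxel_aspect = reg@voxel_aspect,
                      n_iter = opts@n_iter, rho = c(opts@rho1, opts@rho2,
                                                    opts@rho3),
                      deconvolve = opts@deconvolve,
                      normalize = opts@normalize, scale = scale,
                      background = b, pad = pad))
}
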