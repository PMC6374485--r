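## Sparsity-promoting regularizers: the 3D gradient and Hessian operators
## (periodic forward differences, axially rescaled to physical isotropy),
## their adjoints, penalty values and exact proximal operators.
##
## Axial differences are divided by voxel_aspect = dz / lateral pixel so a
## given physical slope costs the same along z as laterally (dz is much
## smaller than the lateral pixel on the default grid).
##
## Hessian convention: the six unique second differences (xx, yy, zz, xy,
## xz, yz) define the symmetric 3x3 matrix per voxel. Norms and adjoints
## use the full matrix Frobenius inner product (off-diagonals counted
## twice), so the nuclear-norm prox by eigenvalue soft-thresholding is
## exact.

## circular shift by s along one axis of a 3D array
.shift3 <- function(v, s, axis) {
  d <- dim(v)
  idx <- ((seq_len(d[axis]) - 1 + s) %% d[axis]) + 1
  switch(axis, v[idx, , , drop = FALSE], v[, idx, , drop = FALSE],
         v[, , idx, drop = FALSE])
}

.dfwd  <- function(v, axis) .shift3(v, 1L, axis) - v        # f[x+1] - f[x]
.dfwdT <- function(v, axis) .shift3(v, -1L, axis) - v       # adjoint: f[x-1] - f[x]
.d2    <- function(v, axis) .shift3(v, 1L, axis) - 2 * v + .shift3(v, -1L, axis)

#' 3D gradient operator and its adjoint
#'
#' Forward finite differences along x, y and z with periodic boundary; the
#' axial difference is divided by \code{voxel_aspect} so the penalty is
#' isotropic in physical units. The adjoint is the negative divergence
#' built from the exact transposes of the difference stencils.
#'
#' @param v 3D array (or [FluorophoreVolume-class]).
#' @param w 4D array \code{c(dim(v), 3)} of gradient fields.
#' @param voxel_aspect dz / lateral pixel size.
#' @return \code{gradientOp}: 4D array \code{c(nx, ny, nz, 3)};
#'   \code{gradientAdjoint}: 3D array.
#' @export
gradientOp <- function(v, voxel_aspect = 1) {
  if (is(v, "FluorophoreVolume")) v <- v@values
  d <- dim(v)
  out <- array(0, c(d, 3L))
  out[, , , 1L] <- .dfwd(v, 1L)
  out[, , , 2L] <- .dfwd(v, 2L)
  out[, , , 3L] <- .dfwd(v, 3L) / voxel_aspect
  out
}

#' @rdname gradientOp
#' @export
gradientAdjoint <- function(w, voxel_aspect = 1) {
  d <- dim(w)[1:3]
  .dfwdT(array(w[, , , 1L], d), 1L) +
    .dfwdT(array(w[, , , 2L], d), 2L) +
    .dfwdT(array(w[, , , 3L], d), 3L) / voxel_aspect
}

#' 3D Hessian operator and its adjoint
#'
#' The six unique second-order periodic finite differences per voxel, in
#' the order xx, yy, zz, xy, xz, yz. Pure second differences are centered
#' (self-adjoint); cross terms are forward-forward. Differences are scaled
#' by \code{1 / voxel_aspect} per axial derivative order. The adjoint is
#' taken with respect to the symmetric-matrix Frobenius inner product, so
#' cross fields carry a factor 2.
#'
#' @param v 3D array (or [FluorophoreVolume-class]).
#' @param w 4D array \code{c(dim(v), 6)} of Hessian fields.
#' @param voxel_aspect dz / lateral pixel size.
#' @return \code{hessianOp}: 4D array \code{c(nx, ny, nz, 6)};
#'   \code{hessianAdjoint}: 3D array.
#' @export
hessianOp <- function(v, voxel_aspect = 1) {
  if (is(v, "FluorophoreVolume")) v <- v@values
  d <- dim(v)
  va <- voxel_aspect
  out <- array(0, c(d, 6L))
  out[, , , 1L] <- .d2(v, 1L)
  out[, , , 2L] <- .d2(v, 2L)
  out[, , , 3L] <- .d2(v, 3L) / va^2
  out[, , , 4L] <- .dfwd(.dfwd(v, 1L), 2L)
  out[, , , 5L] <- .dfwd(.dfwd(v, 1L), 3L) / va
  out[, , , 6L] <- .dfwd(.dfwd(v, 2L), 3L) / va
  out
}

#' @rdname hessianOp
#' @export
hessianAdjoint <- function(w, voxel_aspect = 1) {
  d <- dim(w)[1:3]
  va <- voxel_aspect
  g <- function(k) array(w[, , , k], d)
  .d2(g(1L), 1L) + .d2(g(2L), 2L) + .d2(g(3L), 3L) / va^2 +
    2 * .dfwdT(.dfwdT(g(4L), 1L), 2L) +
    2 * .dfwdT(.dfwdT(g(5L), 1L), 3L) / va +
    2 * .dfwdT(.dfwdT(g(6L), 2L), 3L) / va
}

## per-voxel symmetric 3x3 matrices from the 6 Hessian fields, as an
## n x 6 matrix of rows (xx, yy, zz, xy, xz, yz)
.hessRows <- function(w) {
  d <- dim(w)
  matrix(w, prod(d[1:3]), 6L)
}

#' Regularization penalty value
#'
#' \code{"tv"}: \code{mu * sum_voxels ||grad f||_2} (isotropic 3D total
#' variation). \code{"hessian_schatten1"}: \code{mu * sum_voxels} nuclear
#' norm (sum of absolute eigenvalues) of the symmetric 3x3 Hessian.
#'
#' @param spec a [RegularizerSpec-class].
#' @param v 3D array or [FluorophoreVolume-class].
#' @return Scalar penalty value.
#' @export
regValue <- function(spec, v) {
  stopifnot(is(spec, "RegularizerSpec"))
  if (is(v, "FluorophoreVolume")) v <- v@values
  if (spec@kind == "tv") {
    g <- gradientOp(v, spec@voxel_aspect)
    spec@mu * sum(sqrt(apply(g^2, 1:3, sum)))
  } else {
    rows <- .hessRows(hessianOp(v, spec@voxel_aspect))
    tot <- 0
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      A <- matrix(c(r[1], r[4], r[5],
                    r[4], r[2], r[6],
                    r[5], r[6], r[3]), 3L, 3L)
      tot <- tot + sum(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
    }
    spec@mu * tot
  }
}

#' Proximal operator of the isotropic group l2,1 norm
#'
#' Per-voxel group soft-thresholding of the 3-vector field:
#' \code{v * max(0, 1 - tau / ||v||_2)}, with 0 where the norm vanishes.
#' This is the exact prox of \code{tau * sum ||.||_2}.
#'
#' @param w 4D array \code{c(nx, ny, nz, 3)}.
#' @param tau threshold, >= 0.
#' @return Shrunk field of the same shape.
#' @export
proxTvVector <- function(w, tau) {
  if (tau < 0) stop("tau must be >= 0")
  if (tau == 0) return(w)
  nrm <- sqrt(apply(w^2, 1:3, sum))
  fac <- ifelse(nrm > 0, pmax(0, 1 - tau / nrm), 0)
  w * as.vector(fac)
}

#' Proximal operator of the Schatten-1 (nuclear) norm on a field of
#' symmetric matrices
#'
#' Per voxel, the symmetric 3x3 Hessian matrix is eigendecomposed, each
#' eigenvalue soft-thresholded by \code{tau} toward zero, and the matrix
#' reconstructed. Under the matrix Frobenius inner product this is the
#' exact prox of \code{tau * ||.||_*}.
#'
#' @param w 4D array \code{c(nx, ny, nz, 6)} of fields (xx, yy, zz, xy,
#'   xz, yz).
#' @param tau threshold, >= 0.
#' @return Shrunk field of the same shape.
#' @export
proxSchatten1 <- function(w, tau) {
  if (tau < 0) stop("tau must be >= 0")
  if (tau == 0) return(w)
  d <- dim(w)
  rows <- .hessRows(w)
  out <- rows
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    A <- matrix(c(r[1], r[4], r[5],
                  r[4], r[2], r[6],
                  r[5], r[6], r[3]), 3L, 3L)
    e <- eigen(A, symmetric = TRUE)
    lam <- sign(e$values) * pmax(0, abs(e$values) - tau)
    B <- e$vectors %*% (lam * t(e$vectors))
    out[i, ] <- c(B[1, 1], B[2, 2], B[3, 3], B[1, 2], B[1, 3], B[2, 3])
  }
  array(out, d)
}

## dispatch helpers used by the solver -------------------------------------

.regOp <- function(spec, v) {
  if (spec@kind == "tv") gradientOp(v, spec@voxel_aspect)
  else hessianOp(v, spec@voxel_aspect)
}

.regAdjoint <- function(spec, w) {
  if (spec@kind == "tv") gradientAdjoint(w, spec@voxel_aspect)
  else hessianAdjoint(w, spec@voxel_aspect)
}

.regProx <- function(spec, w, tau) {
  if (spec@kind == "tv") proxTvVector(w, tau) else proxSchatten1(w, tau)
}

.regFields <- function(spec) if (spec@kind == "tv") 3L else 6L
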