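## Discrete MA-TIRF image formation: g_m = T H f + b.
## T is a dense M x Nz depth-weighting matrix shared by all pixels
## (excitation depends only on depth and angle); H blurs every z-slice with
## the same in-focus 2D PSF, implemented as a periodic convolution on a
## zero-padded lateral grid.

#' Build the discrete TIRF depth-weighting matrix
#'
#' Entry (m, j) is the contribution of a unit density at slice center
#' \code{z_j} to the image at angle m:
#' \code{I0(alpha_m) * exp(-z_j * p(alpha_m)) * dz} (midpoint quadrature of
#' the within-slice integral) or the exact per-slab integral of the
#' exponential in \code{"exact"} mode. \code{p = 0} is accepted in the
#' list form and yields the widefield limit (constant row: plain axial sum
#' projection).
#'
#' @param excitation an [ExcitationModel-class], or a
#'   \code{list(i0 =, p =)} with per-angle interface intensities and
#'   inverse penetration depths (1/nm; \code{p >= 0} allowed).
#' @param grid a [GridSpec-class] supplying the slice centers and dz.
#' @param quadrature \code{"midpoint"} (value at slice center times dz) or
#'   \code{"exact"} (analytic integral over each slab).
#' @return A dense M x Nz matrix with strictly positive entries.
#' @examples
#' cfg <- opticalConfig()
#' ex <- excitationModel(cfg, angleSet(seq(63, 75, length.out = 6), cfg))
#' Tz <- buildTirfMatrix(ex, gridSpec(8, 8))
#' dim(Tz)
#' @export
buildTirfMatrix <- function(excitation, grid, quadrature = c("midpoint", "exact")) {
  quadrature <- match.arg(quadrature)
  if (is(excitation, "ExcitationModel")) {
    i0 <- excitation@i0; p <- excitation@p
  } else if (is.list(excitation) && all(c("i0", "p") %in% names(excitation))) {
    i0 <- as.numeric(excitation$i0); p <- as.numeric(excitation$p)
    if (length(i0) != length(p)) stop("i0 and p must have equal length")
    if (any(p < 0) || any(i0 <= 0)) stop("need p >= 0 and i0 > 0")
  } else stop("excitation must be an ExcitationModel or list(i0 =, p =)")
  zc <- zCenters(grid)
  dz <- grid@dz_nm
  Tz <- i0 * exp(-outer(p, zc))          # M x Nz
  if (quadrature == "midpoint") {
    Tz <- Tz * dz
  } else {
    w <- ifelse(p > 0, 2 * sinh(p * dz / 2) / p, dz)
    Tz <- Tz * w
  }
  Tz
}

#' Apply the TIRF depth-weighting operator
#'
#' Computes, for every lateral pixel, the M per-angle intensities
#' \code{sum_j Tz[m, j] * f[i, j]} (no blur, no background).
#'
#' @param Tz M x Nz matrix from [buildTirfMatrix()].
#' @param f a [FluorophoreVolume-class] or an \code{nx x ny x nz} array.
#' @param angle_set optional [AngleSet-class]; when supplied the result is
#'   wrapped into an [AcquisitionStack-class], otherwise a plain
#'   \code{nx x ny x M} array is returned.
#' @param pixel_size_nm pixel size used when wrapping into a stack.
#' @return \code{nx x ny x M} array or [AcquisitionStack-class].
#' @export
applyTirf <- function(Tz, f, angle_set = NULL, pixel_size_nm = 107) {
  v <- if (is(f, "FluorophoreVolume")) f@values else f
  d <- dim(v)
  if (length(d) != 3L || d[3] != ncol(Tz))
    stop("volume has ", d[3], " slices but Tz has ", ncol(Tz), " columns")
  G <- matrix(v, d[1] * d[2], d[3]) %*% t(Tz)
  out <- array(G, c(d[1], d[2], nrow(Tz)))
  if (!is.null(angle_set))
    out <- acquisitionStack(out, angle_set, pixel_size_nm)
  out
}

#' Adjoint of the TIRF depth-weighting operator
#'
#' Maps a stack back to volume shape: \code{out[i, j] = sum_m Tz[m, j] *
#' stack[i, m]}; satisfies \code{<T f, g> = <f, T' g>}.
#'
#' @param Tz M x Nz matrix.
#' @param stack an [AcquisitionStack-class] or \code{nx x ny x M} array.
#' @return \code{nx x ny x Nz} array.
#' @export
applyTirfAdjoint <- function(Tz, stack) {
  g <- if (is(stack, "AcquisitionStack")) stack@images else stack
  d <- dim(g)
  if (length(d) != 3L || d[3] != nrow(Tz))
    stop("stack has ", d[3], " pages but Tz has ", nrow(Tz), " rows")
  V <- matrix(g, d[1] * d[2], d[3]) %*% Tz
  array(V, c(d[1], d[2], ncol(Tz)))
}

## kernel embedded on an nxp x nyp grid with its center wrapped to (1, 1)
.kernelFFT <- function(kernel, nxp, nyp) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr > nxp || kc > nyp)
    stop("PSF kernel (", kr, "x", kc, ") larger than the padded grid (",
         nxp, "x", nyp, ")")
  cx <- (kr + 1L) / 2L; cy <- (kc + 1L) / 2L
  K <- matrix(0, nxp, nyp)
  ii <- ((seq_len(kr) - cx) %% nxp) + 1L
  jj <- ((seq_len(kc) - cy) %% nyp) + 1L
  K[ii, jj] <- kernel
  stats::fft(K)
}

## periodic convolution (or correlation, for the adjoint) of every z-slice
## on a laterally zero-padded grid, cropped back afterwards
.convSlices <- function(v, kernel, pad, adjoint = FALSE) {
  if (all(dim(kernel) == c(1L, 1L))) return(v * kernel[1, 1])
  d <- dim(v)
  nxp <- d[1] + 2L * pad[1]; nyp <- d[2] + 2L * pad[2]
  kf <- .kernelFFT(kernel, nxp, nyp)
  if (adjoint) kf <- Conj(kf)
  ix <- pad[1] + seq_len(d[1]); iy <- pad[2] + seq_len(d[2])
  out <- array(0, d)
  buf <- matrix(0, nxp, nyp)
  for (j in seq_len(d[3])) {
    buf[] <- 0
    buf[ix, iy] <- v[, , j]
    cj <- Re(stats::fft(stats::fft(buf) * kf, inverse = TRUE)) / (nxp * nyp)
    out[, , j] <- cj[ix, iy]
  }
  out
}

#' Slice-wise 2D PSF convolution and its adjoint
#'
#' Convolves each z-slice of a volume with the same in-focus 2D kernel.
#' The convolution is periodic on a grid zero-padded laterally by the
#' kernel half-width (then cropped), which keeps the operator exactly
#' diagonalizable in the Fourier domain while suppressing wrap-around
#' artifacts; \code{pad = c(0, 0)} gives plain periodic convolution. The
#' adjoint is correlation with the same kernel under the same
#' pad-and-crop scheme.
#'
#' @param f a [FluorophoreVolume-class] or 3D array.
#' @param psf a [PSFModel-class].
#' @param pad integer lateral padding (pixels); defaults to the kernel
#'   half-width.
#' @return Array with the dimensions of the input volume.
#' @export
applyPsf <- function(f, psf, pad = NULL) {
  v <- if (is(f, "FluorophoreVolume")) f@values else f
  if (is.null(pad)) pad <- (dim(psf@kernel) - 1L) %/% 2L
  .convSlices(v, psf@kernel, as.integer(rep_len(pad, 2L)))
}

#' @rdname applyPsf
#' @export
applyPsfAdjoint <- function(f, psf, pad = NULL) {
  v <- if (is(f, "FluorophoreVolume")) f@values else f
  if (is.null(pad)) pad <- (dim(psf@kernel) - 1L) %/% 2L
  .convSlices(v, psf@kernel, as.integer(rep_len(pad, 2L)), adjoint = TRUE)
}

#' Full MA-TIRF forward model
#'
#' Simulates noiseless acquisitions \code{g_m = T H f + b_m}: slice-wise
#' PSF blur, per-angle exponential depth weighting, then a spatially
#' constant per-angle background.
#'
#' @param f a [FluorophoreVolume-class] or 3D array.
#' @param Tz M x Nz matrix from [buildTirfMatrix()].
#' @param psf a [PSFModel-class]; a 1x1 delta kernel skips the blur.
#' @param background a [BackgroundModel-class], a numeric vector (one level
#'   per angle, recycled) or 0.
#' @param angle_set optional [AngleSet-class] to wrap the result into an
#'   [AcquisitionStack-class].
#' @param pixel_size_nm pixel size for the wrapped stack.
#' @return \code{nx x ny x M} array or [AcquisitionStack-class].
#' @export
tirfForward <- function(f, Tz, psf, background = 0, angle_set = NULL,
                        pixel_size_nm = 107) {
  v <- if (is(f, "FluorophoreVolume")) f@values else f
  hv <- if (all(dim(psf@kernel) == c(1L, 1L))) v else applyPsf(v, psf)
  g <- applyTirf(Tz, hv)
  b <- if (is(background, "BackgroundModel")) background@level_per_angle
       else rep_len(as.numeric(background), nrow(Tz))
  for (m in seq_len(nrow(Tz))) g[, , m] <- g[, , m] + b[m]
  if (!is.null(angle_set))
    g <- acquisitionStack(g, angle_set, pixel_size_nm)
  g
}

#' Estimate the per-angle constant background from a structure-free region
#'
#' The background of each angle image is the mean intensity over a region
#' of interest known to contain no fluorescent structures.
#'
#' @param stack an [AcquisitionStack-class] or \code{nx x ny x M} array.
#' @param roi_mask logical nx x ny matrix; TRUE marks background pixels.
#' @return A [BackgroundModel-class] with one level per angle.
#' @export
estimateBackground <- function(stack, roi_mask) {
  g <- if (is(stack, "AcquisitionStack")) stack@images else stack
  d <- dim(g)
  if (!is.logical(roi_mask) || !all(dim(roi_mask) == d[1:2]))
    stop("roi_mask must be a logical nx x ny matrix")
  if (!any(roi_mask)) stop("roi_mask is empty")
  lev <- vapply(seq_len(d[3]), function(m) mean(g[, , m][roi_mask]), 0)
  backgroundModel(lev)
}

#' Construct a 2D point spread function model
#'
#' \code{"gaussian"} builds an isotropic Gaussian with
#' \code{sigma = 0.21 * lambda / NA} (converted to pixels), the standard
#' in-focus widefield approximation. \code{"airy"} builds the normalized
#' in-focus Airy pattern \code{(2 J1(v)/v)^2} with
#' \code{v = 2 pi NA r / lambda}. \code{"user_supplied"} validates and
#' sum-normalizes a provided kernel, and \code{"delta"} is the 1x1 identity
#' kernel (no blur).
#'
#' @param config an [OpticalConfig-class] (used by gaussian/airy).
#' @param provenance kernel family.
#' @param size odd kernel side length in pixels; chosen automatically when
#'   NULL.
#' @param kernel user-supplied nonnegative matrix (for
#'   \code{"user_supplied"}).
#' @param focal_plane_z_nm focal-plane depth metadata (nm).
#' @return A [PSFModel-class].
#' @examples
#' psf <- makePsf(opticalConfig(), "gaussian")
#' sum(psf@kernel)
#' @export
makePsf <- function(config, provenance = c("gaussian", "airy",
                                           "user_supplied", "delta"),
                    size = NULL, kernel = NULL, focal_plane_z_nm = 0) {
  provenance <- match.arg(provenance)
  if (provenance == "delta") {
    k <- matrix(1, 1, 1)
  } else if (provenance == "user_supplied") {
    if (is.null(kernel)) stop("user_supplied requires a kernel")
    if (nrow(kernel) %% 2L == 0L || ncol(kernel) %% 2L == 0L)
      stop("kernel sizes must be odd")
    if (any(kernel < 0)) stop("kernel must be nonnegative")
    s <- sum(kernel)
    if (s <= 0) stop("kernel is not normalizable (sums to zero)")
    k <- kernel / s
  } else {
    stopifnot(is(config, "OpticalConfig"))
    if (!is.null(size) && size %% 2L == 0L) stop("size must be odd")
    px <- config@pixel_size_nm
    if (provenance == "gaussian") {
      sigma_px <- 0.21 * config@wavelength_nm / config@numerical_aperture / px
      if (is.null(size)) size <- 2L * as.integer(ceiling(4 * sigma_px)) + 1L
      h <- (size - 1L) %/% 2L
      x <- (-h):h
      g1 <- exp(-x^2 / (2 * sigma_px^2))
      k <- outer(g1, g1)
    } else {                                   # airy
      if (is.null(size)) {
        r1_px <- 0.61 * config@wavelength_nm / config@numerical_aperture / px
        size <- 2L * as.integer(ceiling(3 * r1_px)) + 1L
      }
      h <- (size - 1L) %/% 2L
      x <- (-h):h
      r <- sqrt(outer(x^2, x^2, `+`)) * px
      v <- 2 * pi * config@numerical_aperture * r / config@wavelength_nm
      k <- ifelse(v == 0, 1, (2 * besselJ(v, 1) / v)^2)
    }
    k <- k / sum(k)
  }
  new("PSFModel", kernel = k, provenance = provenance,
      focal_plane_z_nm = as.numeric(focal_plane_z_nm))
}
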