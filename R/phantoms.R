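## Synthetic ground-truth volumes (lens gap, sheets, filaments) and
## simulated MA-TIRF acquisitions with sensor noise. These generate every
## fixture the rest of the package is tested on; no experimental data are
## required anywhere.

## run expr with a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Fluorescent-gap volume under a spherical lens
#'
#' Voxelizes the lens calibration phantom: uniform fluorophore density
#' where \code{z < t(r)} (gap profile from [lensGapProfile()]), zero
#' elsewhere, with partial-volume weighting of the slab's top slice (and
#' of any slice part lying below the coverslip). Slice j covers depths
#' \code{[z_j - dz/2, z_j + dz/2]}.
#'
#' The default field of view is a narrow strip along x starting at the
#' contact point; the gap thickness varies slowly, so a coarse lateral
#' sampling covering the 0-600 nm gap range is sufficient (the full lens
#' is never simulated).
#'
#' @param spec a [LensPhantomSpec-class].
#' @param grid a [GridSpec-class]; the pixel size times the lateral size
#'   sets the physical strip length.
#' @param origin_mm lateral (x, y) coordinates of pixel (1, 1) in mm,
#'   relative to the same frame as \code{spec@contact}.
#' @return A [FluorophoreVolume-class].
#' @export
lensPhantomVolume <- function(spec, grid, origin_mm = c(0, 0)) {
  stopifnot(is(spec, "LensPhantomSpec"), is(grid, "GridSpec"))
  px_mm <- grid@pixel_size_nm * 1e-6
  x <- origin_mm[1] + (seq_len(grid@nx) - 1) * px_mm - spec@contact[1]
  y <- origin_mm[2] + (seq_len(grid@ny) - 1) * px_mm - spec@contact[2]
  r <- sqrt(outer(x^2, y^2, `+`))
  t_nm <- matrix(lensGapProfile(spec, r), grid@nx, grid@ny)
  zc <- zCenters(grid)
  dz <- grid@dz_nm
  vol <- array(0, c(grid@nx, grid@ny, grid@nz))
  for (j in seq_len(grid@nz)) {
    lo <- pmax(zc[j] - dz / 2, 0)
    hi <- zc[j] + dz / 2
    frac <- pmin(pmax((pmin(t_nm, hi) - lo) / dz, 0), 1)
    vol[, , j] <- spec@fluor_density * frac
  }
  fluorophoreVolume(vol, grid)
}

#' Laterally uniform (or disjoint) fluorescent sheets at given depths
#'
#' Places thin sheets at the requested depths; a depth falling between two
#' slice centers is split linearly between the bracketing slices so the
#' axial centroid equals the requested depth exactly. \code{masses} are
#' the per-pixel axial sums contributed by each sheet.
#'
#' @param depths_nm sheet depths (nm), within the grid's axial range.
#' @param masses per-sheet per-pixel mass (recycled).
#' @param grid a [GridSpec-class].
#' @param layout \code{"uniform"} (sheets span the whole field, stacked)
#'   or \code{"disjoint"} (the x-range is split into one block per sheet).
#' @return A [FluorophoreVolume-class].
#' @export
sheetPhantom <- function(depths_nm, masses = 1, grid,
                         layout = c("uniform", "disjoint")) {
  layout <- match.arg(layout)
  stopifnot(is(grid, "GridSpec"))
  masses <- rep_len(masses, length(depths_nm))
  zc <- zCenters(grid)
  if (any(depths_nm < zc[1] - 1e-9 | depths_nm > zc[grid@nz] + 1e-9))
    stop("sheet depth outside the axial grid range [", zc[1], ", ",
         zc[grid@nz], "] nm")
  vol <- array(0, c(grid@nx, grid@ny, grid@nz))
  xblocks <- if (layout == "disjoint") {
    cuts <- round(seq(0, grid@nx, length.out = length(depths_nm) + 1))
    lapply(seq_along(depths_nm), function(k) (cuts[k] + 1):cuts[k + 1])
  } else rep(list(seq_len(grid@nx)), length(depths_nm))
  for (k in seq_along(depths_nm)) {
    pos <- (depths_nm[k] - grid@z0_nm) / grid@dz_nm + 1   # fractional slice
    j0 <- min(max(floor(pos), 1), grid@nz)
    w1 <- pos - j0
    vol[xblocks[[k]], , j0] <- vol[xblocks[[k]], , j0] + masses[k] * (1 - w1)
    if (w1 > 0 && j0 < grid@nz)
      vol[xblocks[[k]], , j0 + 1] <- vol[xblocks[[k]], , j0 + 1] +
        masses[k] * w1
  }
  fluorophoreVolume(vol, grid)
}

#' Filament-like tube phantom
#'
#' Rasterizes a piecewise-linear 3D curve (actin-fiber-like test scene):
#' the curve is sampled densely, each sample deposits a Gaussian lateral
#' footprint of width \code{lateral_width_px} and is linearly interpolated
#' between the two bracketing z-slices. Fully deterministic.
#'
#' @param control_points_3d matrix with columns (x_px, y_px, z_nm);
#'   lateral coordinates in (fractional) pixels, depth in nm.
#' @param intensity peak deposit per curve sample.
#' @param grid a [GridSpec-class].
#' @param lateral_width_px Gaussian lateral sigma in pixels.
#' @return A [FluorophoreVolume-class].
#' @export
filamentPhantom <- function(control_points_3d, intensity = 1, grid,
                            lateral_width_px = 1) {
  stopifnot(is(grid, "GridSpec"))
  cp <- as.matrix(control_points_3d)
  if (ncol(cp) != 3L || nrow(cp) < 2L)
    stop("need a matrix of >= 2 control points with columns (x, y, z)")
  vol <- array(0, c(grid@nx, grid@ny, grid@nz))
  if (intensity == 0) return(fluorophoreVolume(vol, grid))
  zc <- zCenters(grid)
  hw <- max(1L, ceiling(3 * lateral_width_px))
  for (s in seq_len(nrow(cp) - 1L)) {
    a <- cp[s, ]; b <- cp[s + 1L, ]
    len <- sqrt(sum((b[1:2] - a[1:2])^2))
    nsamp <- max(2L, ceiling(len * 4))
    tt <- seq(0, 1, length.out = nsamp)
    for (u in tt) {
      q <- a + u * (b - a)
      pos <- (q[3] - grid@z0_nm) / grid@dz_nm + 1
      j0 <- min(max(floor(pos), 1), grid@nz)
      wz <- pos - j0
      ix <- max(1, round(q[1]) - hw):min(grid@nx, round(q[1]) + hw)
      iy <- max(1, round(q[2]) - hw):min(grid@ny, round(q[2]) + hw)
      w <- outer(exp(-(ix - q[1])^2 / (2 * lateral_width_px^2)),
                 exp(-(iy - q[2])^2 / (2 * lateral_width_px^2)))
      vol[ix, iy, j0] <- vol[ix, iy, j0] + intensity * (1 - wz) * w / nsamp
      if (wz > 0 && j0 < grid@nz)
        vol[ix, iy, j0 + 1] <- vol[ix, iy, j0 + 1] + intensity * wz * w / nsamp
    }
  }
  fluorophoreVolume(vol, grid)
}

#' Simulate the spherical-lens calibration experiment
#'
#' Bundles the standard calibration study: a lateral patch touching the
#' lens contact point is voxelized on a fine axial grid (4 nm steps, deep
#' enough to contain the thickest gap in the field of view), imaged at
#' \code{n_angles} supercritical angles spaced uniformly in inverse
#' penetration depth ([angleDesign()]), with unit interface intensity and
#' the exact per-slab excitation integral. Optionally Poisson-Gaussian
#' camera noise is added at a prescribed peak signal-to-noise ratio: the
#' photon budget is set so the brightest stack pixel has shot-noise SNR
#' \code{peak_snr}, plus Gaussian read noise ten times smaller.
#'
#' The gap thickness varies slowly, so coarse "virtual pixels" (5 um by
#' default) are appropriate and no lateral PSF is applied -- the fit uses
#' the pure depth-weighting model.
#'
#' @param spec a [LensPhantomSpec-class].
#' @param config an [OpticalConfig-class]; the pixel size is overridden by
#'   \code{pixel_size_nm}.
#' @param nx,ny lateral patch size in virtual pixels (pixel (1, 1) at the
#'   contact point).
#' @param pixel_size_nm virtual pixel size (nm).
#' @param n_angles number of incident angles.
#' @param dz_nm axial voxelization step of the generator grid (nm).
#' @param peak_snr peak signal-to-noise ratio; NULL for a noiseless stack.
#' @param seed RNG seed for the noise draw.
#' @return List with \code{stack} ([AcquisitionStack-class]),
#'   \code{excitation} ([ExcitationModel-class]), \code{true_thickness_nm}
#'   (nx x ny matrix from [lensGapProfile()]), \code{volume}, and
#'   \code{noise} (the [NoiseSpec-class] used, or NULL).
#' @examples
#' sim <- simulateLensCalibration(nx = 40, ny = 2)
#' fit <- fitSlabPerPixel(sim$stack, sim$excitation)
#' fitLensRadius(fit@thickness_map, 5000)$radius_mm
#' @export
simulateLensCalibration <- function(spec = lensPhantomSpec(),
                                    config = opticalConfig(),
                                    nx = 110L, ny = 4L,
                                    pixel_size_nm = 5000,
                                    n_angles = 10L, dz_nm = 4,
                                    peak_snr = NULL, seed = 1L) {
  config@pixel_size_nm <- as.numeric(pixel_size_nm)
  aset <- angleDesign(config, n_angles)
  ex <- excitationModel(config, aset)
  x <- (seq_len(nx) - 1) * pixel_size_nm * 1e-6
  y <- (seq_len(ny) - 1) * pixel_size_nm * 1e-6
  r <- sqrt(outer(x^2, y^2, `+`))
  ttrue <- matrix(lensGapProfile(spec, r), nx, ny)
  nz <- as.integer(ceiling((max(ttrue) + 3 * dz_nm) / dz_nm))
  grid <- gridSpec(nx, ny, nz, dz_nm, pixel_size_nm)
  vol <- lensPhantomVolume(spec, grid)
  psf <- makePsf(config, "delta")
  ns <- NULL
  if (!is.null(peak_snr)) {
    peak <- max(tirfForward(vol@values, buildTirfMatrix(ex, grid, "exact"),
                            psf))
    ns <- noiseSpec("poisson_gaussian",
                    gaussian_sigma = peak / (10 * peak_snr),
                    photon_scale = peak_snr^2 / peak, seed = seed)
  }
  stk <- simulateAcquisition(vol, ex, psf, 0,
                             if (is.null(ns)) noiseSpec("none") else ns,
                             quadrature = "exact")
  list(stack = stk, excitation = ex, true_thickness_nm = ttrue,
       volume = vol, noise = ns)
}

#' Simulate a multi-angle TIRF acquisition
#'
#' Runs the forward model (depth weighting, slice-wise blur, constant
#' background) and applies the sensor-noise model: \code{"gaussian"} adds
#' N(0, sigma^2); \code{"poisson_gaussian"} draws
#' \code{Poisson(photon_scale * clean) / photon_scale} and then adds
#' Gaussian read noise. Noisy stacks are clamped at 0; with
#' \code{model = "none"} the noiseless forward output is returned
#' unchanged. The generator is seeded from \code{noise@seed}, so a fixed
#' seed reproduces the stack bit for bit (the caller's RNG state is left
#' untouched).
#'
#' @param volume a [FluorophoreVolume-class].
#' @param excitation an [ExcitationModel-class].
#' @param psf a [PSFModel-class].
#' @param background per-angle background ([BackgroundModel-class],
#'   numeric or 0).
#' @param noise a [NoiseSpec-class].
#' @param quadrature passed to [buildTirfMatrix()]; the generator defaults
#'   to the exact per-slab integral (the physically faithful choice; the
#'   midpoint rule is the reconstruction-side approximation).
#' @return An [AcquisitionStack-class].
#' @export
simulateAcquisition <- function(volume, excitation, psf, background = 0,
                                noise = noiseSpec("none"),
                                quadrature = "exact") {
  stopifnot(is(volume, "FluorophoreVolume"), is(excitation, "ExcitationModel"),
            is(noise, "NoiseSpec"))
  Tz <- buildTirfMatrix(excitation, volume@grid, quadrature)
  clean <- tirfForward(volume@values, Tz, psf, background)
  g <- if (noise@model == "none") clean else .withSeed(noise@seed, {
    n <- length(clean)
    noisy <- if (noise@model == "gaussian") {
      clean + stats::rnorm(n, 0, noise@gaussian_sigma)
    } else {
      stats::rpois(n, noise@photon_scale * pmax(clean, 0)) /
        noise@photon_scale + stats::rnorm(n, 0, noise@gaussian_sigma)
    }
    array(pmax(noisy, 0), dim(clean))
  })
  acquisitionStack(g, excitation@angle_set, volume@grid@pixel_size_nm)
}
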