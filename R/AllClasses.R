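#' @import methods
NULL

## ---------------------------------------------------------------------------
## Optics
## ---------------------------------------------------------------------------

#' Optical configuration of a TIRF microscope
#'
#' Holds the physical constants of the excitation path: vacuum wavelength,
#' refractive indices on both sides of the coverslip, objective numerical
#' aperture and the lateral sample-plane pixel size. Total internal
#' reflection requires the incident (glass/immersion) medium to be denser
#' than the sample medium.
#'
#' @slot wavelength_nm excitation wavelength in vacuum (nm).
#' @slot n_incident refractive index of the glass/immersion side.
#' @slot n_sample refractive index of the sample medium.
#' @slot numerical_aperture objective NA; bounded by \code{n_incident}.
#' @slot pixel_size_nm lateral sample-plane pixel size (nm).
#'
#' @seealso [opticalConfig()], [criticalAngle()], [penetrationInverse()]
#' @export
setClass("OpticalConfig",
  representation(
    wavelength_nm = "numeric",
    n_incident = "numeric",
    n_sample = "numeric",
    numerical_aperture = "numeric",
    pixel_size_nm = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  sc <- function(x) length(x) == 1L && is.finite(x)
  if (!sc(object@wavelength_nm) || object@wavelength_nm <= 0)
    msg <- c(msg, "wavelength_nm must be a positive scalar")
  if (!sc(object@pixel_size_nm) || object@pixel_size_nm <= 0)
    msg <- c(msg, "pixel_size_nm must be a positive scalar")
  if (!sc(object@n_incident) || !sc(object@n_sample) ||
      object@n_sample <= 0 || object@n_incident <= object@n_sample)
    msg <- c(msg, "need n_incident > n_sample > 0 (TIR requires a denser incident medium)")
  if (!sc(object@numerical_aperture) || object@numerical_aperture <= 0 ||
      object@numerical_aperture > object@n_incident)
    msg <- c(msg, "numerical_aperture must lie in (0, n_incident]")
  if (length(msg)) msg else TRUE
})

#' Create an optical configuration
#'
#' Defaults describe a conventional oil-immersion TIRF setup: 491 nm
#' excitation, glass/oil index 1.515, aqueous sample index 1.33, a 1.49 NA
#' objective and 107 nm pixels.
#'
#' @param wavelength_nm excitation wavelength in vacuum (nm).
#' @param n_incident refractive index of the glass/immersion medium.
#' @param n_sample refractive index of the sample medium.
#' @param numerical_aperture objective numerical aperture.
#' @param pixel_size_nm lateral pixel size in the sample plane (nm).
#' @return An [OpticalConfig-class] object.
#' @examples
#' cfg <- opticalConfig()
#' criticalAngle(cfg)
#' @export
opticalConfig <- function(wavelength_nm = 491, n_incident = 1.515,
                          n_sample = 1.33, numerical_aperture = 1.49,
                          pixel_size_nm = 107) {
  new("OpticalConfig",
      wavelength_nm = as.numeric(wavelength_nm),
      n_incident = as.numeric(n_incident),
      n_sample = as.numeric(n_sample),
      numerical_aperture = as.numeric(numerical_aperture),
      pixel_size_nm = as.numeric(pixel_size_nm))
}

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig: lambda =", object@wavelength_nm, "nm, n1 =",
      object@n_incident, ", n2 =", object@n_sample, ", NA =",
      object@numerical_aperture, ", pixel =", object@pixel_size_nm, "nm\n")
  invisible(NULL)
})

#' Ordered set of supercritical incident angles
#'
#' @slot angles_deg strictly increasing incident angles in degrees,
#'   measured from the optical axis (normal to the coverslip).
#' @seealso [angleSet()]
#' @export
setClass("AngleSet", representation(angles_deg = "numeric"))

setValidity("AngleSet", function(object) {
  a <- object@angles_deg
  msg <- character()
  if (length(a) < 2L) msg <- c(msg, "need at least two incident angles")
  if (anyNA(a) || any(!is.finite(a))) msg <- c(msg, "angles must be finite")
  else if (any(diff(a) <= 0)) msg <- c(msg, "angles must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Create an angle set, optionally validated against an optical configuration
#'
#' When \code{config} is supplied, all angles must be strictly above the
#' critical angle and within the aperture of the objective
#' (\code{asin(NA / n_incident)}).
#'
#' @param angles_deg strictly increasing incident angles (degrees).
#' @param config optional [OpticalConfig-class] used to check that the angles
#'   are supercritical and objective-accessible.
#' @return An [AngleSet-class].
#' @examples
#' angleSet(seq(63, 75, length.out = 10), opticalConfig())
#' @export
angleSet <- function(angles_deg, config = NULL) {
  obj <- new("AngleSet", angles_deg = as.numeric(angles_deg))
  if (!is.null(config)) {
    ac <- criticalAngle(config)
    amax <- asin(config@numerical_aperture / config@n_incident) * 180 / pi
    if (any(obj@angles_deg <= ac))
      stop("all angles must exceed the critical angle (", signif(ac, 5), " deg)")
    if (any(obj@angles_deg > amax + 1e-9))
      stop("angles beyond the objective aperture limit (", signif(amax, 5), " deg)")
  }
  obj
}

#' Number of angles in an object
#' @param x an [AngleSet-class], [ExcitationModel-class] or
#'   [AcquisitionStack-class].
#' @return integer count of incident angles.
#' @export
setGeneric("nAngles", function(x) standardGeneric("nAngles"))

#' Incident angles of an object (degrees)
#' @param x an object carrying an angle set.
#' @return numeric vector of angles in degrees.
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' @rdname nAngles
setMethod("nAngles", "AngleSet", function(x) length(x@angles_deg))
#' @rdname angles
setMethod("angles", "AngleSet", function(x) x@angles_deg)

#' Per-angle evanescent excitation model
#'
#' For each incident angle the evanescent excitation decays as
#' \eqn{I(z, \alpha) = I_0(\alpha) e^{-z p(\alpha)}} with depth z; the model
#' stores the interface intensity \eqn{I_0} and the inverse penetration
#' depth \eqn{p} (1/nm) per angle.
#'
#' @slot angle_set the [AngleSet-class].
#' @slot i0 per-angle interface intensity (arbitrary units), positive.
#' @slot p per-angle inverse penetration depth (1/nm), positive and
#'   strictly increasing with angle.
#' @seealso [excitationModel()]
#' @export
setClass("ExcitationModel",
  representation(angle_set = "AngleSet", i0 = "numeric", p = "numeric"))

setValidity("ExcitationModel", function(object) {
  m <- nAngles(object@angle_set)
  msg <- character()
  if (length(object@i0) != m || length(object@p) != m)
    msg <- c(msg, "i0 and p must have one entry per angle")
  if (any(object@i0 <= 0)) msg <- c(msg, "i0 must be strictly positive")
  if (any(object@p <= 0)) msg <- c(msg, "p must be strictly positive")
  if (length(object@p) > 1 && any(diff(object@p) <= 0))
    msg <- c(msg, "p must increase strictly with angle")
  if (length(msg)) msg else TRUE
})

#' @rdname nAngles
setMethod("nAngles", "ExcitationModel", function(x) nAngles(x@angle_set))
#' @rdname angles
setMethod("angles", "ExcitationModel", function(x) angles(x@angle_set))

setMethod("show", "ExcitationModel", function(object) {
  a <- angles(object)
  cat("ExcitationModel with", length(a), "angles:",
      signif(min(a), 4), "-", signif(max(a), 4), "deg; penetration depth",
      signif(1 / max(object@p), 4), "-", signif(1 / min(object@p), 4), "nm\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## Grids, volumes, stacks
## ---------------------------------------------------------------------------

#' Reconstruction grid specification
#'
#' Slice centers sit at \code{z_j = z0_nm + (j - 1) * dz_nm}, j = 1..nz,
#' with z = 0 at the glass/sample interface and z growing away from the
#' coverslip. The default grid spans 0-400 nm in 20 nm steps.
#'
#' @slot nx,ny lateral grid sizes (pixels).
#' @slot nz number of axial slices.
#' @slot dz_nm axial step (nm).
#' @slot pixel_size_nm lateral step (nm).
#' @slot z0_nm depth of the first slice center (nm, >= 0).
#' @seealso [gridSpec()], [zCenters()]
#' @export
setClass("GridSpec",
  representation(nx = "integer", ny = "integer", nz = "integer",
                 dz_nm = "numeric", pixel_size_nm = "numeric",
                 z0_nm = "numeric"))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (object@nx < 1L || object@ny < 1L || object@nz < 1L)
    msg <- c(msg, "grid sizes must be >= 1")
  if (object@dz_nm <= 0) msg <- c(msg, "dz_nm must be positive")
  if (object@pixel_size_nm <= 0) msg <- c(msg, "pixel_size_nm must be positive")
  if (object@z0_nm < 0) msg <- c(msg, "z0_nm must be >= 0 (coverslip at z = 0)")
  if (length(msg)) msg else TRUE
})

#' Create a grid specification
#' @param nx,ny lateral sizes in pixels.
#' @param nz number of axial slices.
#' @param dz_nm axial step (nm).
#' @param pixel_size_nm lateral pixel size (nm).
#' @param z0_nm depth of the first slice center (nm).
#' @return A [GridSpec-class].
#' @examples
#' g <- gridSpec(64, 64)           # 0-380 nm in 20 nm steps
#' zCenters(g)
#' @export
gridSpec <- function(nx, ny, nz = 20L, dz_nm = 20, pixel_size_nm = 107,
                     z0_nm = 0) {
  new("GridSpec", nx = as.integer(nx), ny = as.integer(ny),
      nz = as.integer(nz), dz_nm = as.numeric(dz_nm),
      pixel_size_nm = as.numeric(pixel_size_nm), z0_nm = as.numeric(z0_nm))
}

#' Axial slice-center coordinates of a grid (nm)
#' @param grid a [GridSpec-class].
#' @return numeric vector of length \code{nz}.
#' @export
zCenters <- function(grid) grid@z0_nm + (seq_len(grid@nz) - 1) * grid@dz_nm

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d x %d, pixel %g nm, dz %g nm, z in [%g, %g] nm\n",
              object@nx, object@ny, object@nz, object@pixel_size_nm,
              object@dz_nm, object@z0_nm,
              object@z0_nm + (object@nz - 1) * object@dz_nm))
  invisible(NULL)
})

#' Nonnegative fluorophore density on a 3D grid
#'
#' @slot grid the [GridSpec-class].
#' @slot values nonnegative array of dimension \code{c(nx, ny, nz)}
#'   (arbitrary units).
#' @seealso [fluorophoreVolume()]
#' @export
setClass("FluorophoreVolume",
  representation(grid = "GridSpec", values = "array"))

setValidity("FluorophoreVolume", function(object) {
  d <- dim(object@values)
  g <- object@grid
  msg <- character()
  if (length(d) != 3L || !all(d == c(g@nx, g@ny, g@nz)))
    msg <- c(msg, "values must be an nx x ny x nz array matching the grid")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  else if (any(object@values < 0))
    msg <- c(msg, "fluorophore density must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Create a fluorophore volume
#' @param values nonnegative \code{nx x ny x nz} array.
#' @param grid matching [GridSpec-class].
#' @return A [FluorophoreVolume-class].
#' @export
fluorophoreVolume <- function(values, grid) {
  new("FluorophoreVolume", grid = grid, values = values)
}

#' @describeIn fluorophoreVolume extract the raw density array.
#' @param x a \code{FluorophoreVolume}.
#' @param ... ignored.
#' @export
setMethod("as.array", "FluorophoreVolume", function(x, ...) x@values)

setMethod("show", "FluorophoreVolume", function(object) {
  g <- object@grid
  cat(sprintf("FluorophoreVolume %d x %d x %d (dz %g nm), total mass %.4g\n",
              g@nx, g@ny, g@nz, g@dz_nm, sum(object@values)))
  invisible(NULL)
})

#' Multi-angle TIRF acquisition stack
#'
#' The measured data g: one co-registered 2D image per incident angle,
#' stored as an \code{nx x ny x M} array with ascending angles along the
#' third dimension.
#'
#' @slot images \code{nx x ny x M} array of nonnegative-going intensities
#'   (arbitrary units; background-subtracted stacks may dip below zero).
#' @slot angle_set the [AngleSet-class], length M.
#' @slot pixel_size_nm lateral pixel size (nm).
#' @slot channel_label free-text channel tag.
#' @seealso [acquisitionStack()]
#' @export
setClass("AcquisitionStack",
  representation(images = "array", angle_set = "AngleSet",
                 pixel_size_nm = "numeric", channel_label = "character"))

setValidity("AcquisitionStack", function(object) {
  d <- dim(object@images)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "images must be an nx x ny x M array")
  else if (d[3] != nAngles(object@angle_set))
    msg <- c(msg, sprintf("stack has %d pages but %d angles", d[3],
                          nAngles(object@angle_set)))
  if (anyNA(object@images) || any(!is.finite(object@images)))
    msg <- c(msg, "intensities must be finite")
  if (object@pixel_size_nm <= 0) msg <- c(msg, "pixel_size_nm must be positive")
  if (length(msg)) msg else TRUE
})

#' Create an acquisition stack
#' @param images \code{nx x ny x M} array, pages in ascending-angle order.
#' @param angle_set matching [AngleSet-class].
#' @param pixel_size_nm lateral pixel size (nm).
#' @param channel_label optional channel tag.
#' @return An [AcquisitionStack-class].
#' @export
acquisitionStack <- function(images, angle_set, pixel_size_nm = 107,
                             channel_label = "") {
  new("AcquisitionStack", images = images, angle_set = angle_set,
      pixel_size_nm = as.numeric(pixel_size_nm),
      channel_label = as.character(channel_label))
}

#' @describeIn acquisitionStack extract the raw image array.
#' @param x an \code{AcquisitionStack}.
#' @param ... ignored.
#' @export
setMethod("as.array", "AcquisitionStack", function(x, ...) x@images)

#' @rdname nAngles
setMethod("nAngles", "AcquisitionStack", function(x) nAngles(x@angle_set))
#' @rdname angles
setMethod("angles", "AcquisitionStack", function(x) angles(x@angle_set))

setMethod("show", "AcquisitionStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("AcquisitionStack %d x %d, %d angles (%g-%g deg)%s\n",
              d[1], d[2], d[3], min(angles(object)), max(angles(object)),
              if (nzchar(object@channel_label))
                paste0(", channel '", object@channel_label, "'") else ""))
  invisible(NULL)
})

#' In-focus 2D point spread function
#'
#' The blur applied identically to every z-slice. Within the thin excited
#' layer the 3D PSF is close to constant axially, so a single in-focus 2D
#' kernel is used; \code{focal_plane_z_nm} is retained as metadata only.
#'
#' @slot kernel odd-sized, sum-normalized, centered nonnegative matrix.
#' @slot provenance one of \code{"gaussian"}, \code{"airy"},
#'   \code{"user_supplied"}, \code{"delta"}.
#' @slot focal_plane_z_nm focal-plane depth (nm), metadata.
#' @seealso [makePsf()]
#' @export
setClass("PSFModel",
  representation(kernel = "matrix", provenance = "character",
                 focal_plane_z_nm = "numeric"))

setValidity("PSFModel", function(object) {
  k <- object@kernel
  msg <- character()
  if (nrow(k) %% 2L == 0L || ncol(k) %% 2L == 0L)
    msg <- c(msg, "kernel sizes must be odd")
  if (any(k < 0)) msg <- c(msg, "kernel must be nonnegative")
  if (abs(sum(k) - 1) > 1e-12) msg <- c(msg, "kernel must sum to 1")
  cx <- sum(row(k) * k); cy <- sum(col(k) * k)
  if (abs(cx - (nrow(k) + 1) / 2) > 0.5 || abs(cy - (ncol(k) + 1) / 2) > 0.5)
    msg <- c(msg, "kernel centroid must lie within half a pixel of the center")
  if (length(msg)) msg else TRUE
})

#' Per-angle constant background level
#'
#' @slot level_per_angle M nonnegative scalars (arbitrary units).
#' @export
setClass("BackgroundModel", representation(level_per_angle = "numeric"))

setValidity("BackgroundModel", function(object) {
  if (any(!is.finite(object@level_per_angle)) ||
      any(object@level_per_angle < 0))
    "background levels must be finite and nonnegative" else TRUE
})

#' Create a background model
#' @param level_per_angle nonnegative scalar (recycled) or one level per angle.
#' @param M number of angles, used to recycle a scalar.
#' @return A [BackgroundModel-class].
#' @export
backgroundModel <- function(level_per_angle, M = length(level_per_angle)) {
  new("BackgroundModel", level_per_angle = rep_len(as.numeric(level_per_angle), M))
}

## ---------------------------------------------------------------------------
## Regularization / solver
## ---------------------------------------------------------------------------

#' Regularizer choice for the variational reconstruction
#'
#' Either isotropic 3D total variation (\code{"tv"}: the l2,1 mixed norm of
#' the gradient) or the order-1 Hessian-Schatten norm
#' (\code{"hessian_schatten1"}: per-voxel nuclear norm of the symmetric 3x3
#' Hessian). Axial finite differences are divided by \code{voxel_aspect}
#' (dz / lateral pixel) so the penalty is isotropic in physical units.
#'
#' @slot kind \code{"tv"} or \code{"hessian_schatten1"}.
#' @slot mu regularization weight, > 0.
#' @slot voxel_aspect dz_nm / pixel_size_nm, > 0.
#' @seealso [regularizerSpec()]
#' @export
setClass("RegularizerSpec",
  representation(kind = "character", mu = "numeric", voxel_aspect = "numeric"))

setValidity("RegularizerSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("tv", "hessian_schatten1"))
    msg <- c(msg, "kind must be 'tv' or 'hessian_schatten1'")
  if (!is.finite(object@mu) || object@mu <= 0)
    msg <- c(msg, "mu must be > 0")
  if (!is.finite(object@voxel_aspect) || object@voxel_aspect <= 0)
    msg <- c(msg, "voxel_aspect must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a regularizer specification
#'
#' \code{mu} has no default: it balances data fidelity against regularity
#' and must be chosen by the user (for data normalized to peak 1, values
#' around 1e-3 to 1e-1 are a reasonable starting range).
#'
#' @param kind \code{"tv"} or \code{"hessian_schatten1"}.
#' @param mu regularization weight (> 0), applied to peak-normalized data
#'   when the solver's \code{normalize} option is on.
#' @param voxel_aspect axial-to-lateral step ratio; pass
#'   \code{dz_nm / pixel_size_nm} of your grid.
#' @return A [RegularizerSpec-class].
#' @export
regularizerSpec <- function(kind = c("tv", "hessian_schatten1"), mu,
                            voxel_aspect) {
  kind <- match.arg(kind)
  if (missing(mu)) stop("mu is required (no default)")
  new("RegularizerSpec", kind = kind, mu = as.numeric(mu),
      voxel_aspect = as.numeric(voxel_aspect))
}

#' ADMM solver options
#'
#' @slot n_iter number of outer iterations (default 50).
#' @slot rho1,rho2,rho3 positive penalty parameters for the three split
#'   constraints (u1 = Hf, u2 = Lf, u3 = f).
#' @slot tol_primal optional relative primal-residual stopping tolerance
#'   (NA = run all iterations).
#' @slot deconvolve include the PSF in the model (joint mode) or replace it
#'   by the identity.
#' @slot normalize scale the background-subtracted data to peak 1 before
#'   solving (the result is scaled back).
#' @slot record_objective record the objective value each iteration.
#' @slot seed unused; kept for interface symmetry (the solver is
#'   deterministic).
#' @seealso [solverOptions()], [admmReconstruct()]
#' @export
setClass("SolverOptions",
  representation(n_iter = "integer", rho1 = "numeric", rho2 = "numeric",
                 rho3 = "numeric", tol_primal = "numeric",
                 deconvolve = "logical", normalize = "logical",
                 record_objective = "logical", seed = "integer"))

setValidity("SolverOptions", function(object) {
  msg <- character()
  if (object@n_iter < 1L) msg <- c(msg, "n_iter must be >= 1")
  if (object@rho1 <= 0 || object@rho2 <= 0 || object@rho3 <= 0)
    msg <- c(msg, "penalty parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' Create solver options
#' @param n_iter iteration count.
#' @param rho1,rho2,rho3 ADMM penalties (> 0).
#' @param tol_primal optional early-stop tolerance on the maximum relative
#'   primal residual; \code{NA} disables early stopping.
#' @param deconvolve logical; joint deconvolution on/off.
#' @param normalize logical; peak-normalize data internally.
#' @param record_objective logical; keep a per-iteration objective trace.
#' @param seed unused placeholder (solver is deterministic).
#' @return A [SolverOptions-class].
#' @export
solverOptions <- function(n_iter = 50L, rho1 = 1, rho2 = 1, rho3 = 1,
                          tol_primal = NA_real_, deconvolve = TRUE,
                          normalize = TRUE, record_objective = FALSE,
                          seed = 0L) {
  new("SolverOptions", n_iter = as.integer(n_iter), rho1 = as.numeric(rho1),
      rho2 = as.numeric(rho2), rho3 = as.numeric(rho3),
      tol_primal = as.numeric(tol_primal), deconvolve = isTRUE(deconvolve),
      normalize = isTRUE(normalize),
      record_objective = isTRUE(record_objective), seed = as.integer(seed))
}

#' Final state of the ADMM solver
#'
#' @slot f primal volume iterate (array).
#' @slot u1,u2,u3 auxiliary variables (u1 = Hf target, u2 = Lf target,
#'   u3 = nonnegative copy of f).
#' @slot d1,d2,d3 scaled dual variables matching u1-u3.
#' @slot it iterations actually run.
#' @slot objective_trace per-iteration objective values (possibly empty).
#' @slot primal_residual final maximum relative primal residual.
#' @export
setClass("SolverState",
  representation(f = "array", u1 = "array", u2 = "array", u3 = "array",
                 d1 = "array", d2 = "array", d3 = "array", it = "integer",
                 objective_trace = "numeric", primal_residual = "numeric"))

#' Result of an ADMM reconstruction
#'
#' The returned volume is the nonnegative auxiliary iterate u3 (exactly
#' feasible by construction), scaled back to the data units.
#'
#' @slot volume the estimated [FluorophoreVolume-class].
#' @slot state final [SolverState-class].
#' @slot settings list echoing the solver/regularizer configuration.
#' @export
setClass("ReconstructionResult",
  representation(volume = "FluorophoreVolume", state = "SolverState",
                 settings = "list"))

setMethod("show", "ReconstructionResult", function(object) {
  g <- object@volume@grid
  cat(sprintf("ReconstructionResult: %d x %d x %d volume after %d ADMM iterations\n",
              g@nx, g@ny, g@nz, object@state@it))
  if (length(object@state@objective_trace))
    cat(sprintf("  final objective %.6g, primal residual %.3g\n",
                utils::tail(object@state@objective_trace, 1),
                object@state@primal_residual))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## Phantoms / fitting / postprocessing
## ---------------------------------------------------------------------------

#' Sensor noise specification for simulated acquisitions
#'
#' \code{"poisson_gaussian"} emulates an EMCCD-like camera: photon shot
#' noise at \code{photon_scale} counts per intensity unit followed by
#' additive Gaussian read noise.
#'
#' @slot model \code{"none"}, \code{"gaussian"} or \code{"poisson_gaussian"}.
#' @slot gaussian_sigma read-noise standard deviation (a.u.).
#' @slot photon_scale counts per intensity unit for the Poisson branch.
#' @slot seed integer seed; a fixed seed gives bit-reproducible stacks.
#' @seealso [noiseSpec()], [simulateAcquisition()]
#' @export
setClass("NoiseSpec",
  representation(model = "character", gaussian_sigma = "numeric",
                 photon_scale = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (!object@model %in% c("none", "gaussian", "poisson_gaussian"))
    msg <- c(msg, "model must be none, gaussian or poisson_gaussian")
  if (object@gaussian_sigma < 0) msg <- c(msg, "gaussian_sigma must be >= 0")
  if (object@photon_scale <= 0) msg <- c(msg, "photon_scale must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a noise specification
#' @param model noise model name.
#' @param gaussian_sigma Gaussian standard deviation (a.u.).
#' @param photon_scale counts per intensity unit (Poisson branch).
#' @param seed integer RNG seed.
#' @return A [NoiseSpec-class].
#' @export
noiseSpec <- function(model = c("poisson_gaussian", "gaussian", "none"),
                      gaussian_sigma = 0.01, photon_scale = 1000,
                      seed = 1L) {
  new("NoiseSpec", model = match.arg(model),
      gaussian_sigma = as.numeric(gaussian_sigma),
      photon_scale = as.numeric(photon_scale), seed = as.integer(seed))
}

#' Spherical-lens calibration phantom geometry
#'
#' A divergent spherical lens resting on the coverslip with fluorescent
#' liquid filling the gap; the gap thickness grows as
#' \eqn{t(r) = R - \sqrt{R^2 - r^2}} with lateral distance r from the
#' contact point.
#'
#' @slot radius_mm lens radius of curvature R (mm).
#' @slot diameter_mm lens diameter (mm).
#' @slot contact lateral (x, y) coordinates of the contact point (mm).
#' @slot fluor_density uniform fluorophore density of the liquid (a.u.).
#' @seealso [lensPhantomSpec()], [lensGapProfile()], [lensPhantomVolume()]
#' @export
setClass("LensPhantomSpec",
  representation(radius_mm = "numeric", diameter_mm = "numeric",
                 contact = "numeric", fluor_density = "numeric"))

setValidity("LensPhantomSpec", function(object) {
  msg <- character()
  if (object@radius_mm <= 0) msg <- c(msg, "radius_mm must be positive")
  if (object@diameter_mm <= 0) msg <- c(msg, "diameter_mm must be positive")
  if (length(object@contact) != 2L) msg <- c(msg, "contact must be (x, y) in mm")
  if (object@fluor_density < 0) msg <- c(msg, "fluor_density must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a lens-phantom specification
#'
#' Defaults are the calibration lens used throughout: R = 288 mm radius of
#' curvature, 25.1 mm diameter.
#'
#' @param radius_mm radius of curvature (mm).
#' @param diameter_mm lens diameter (mm).
#' @param contact lateral coordinates of the contact point (mm).
#' @param fluor_density density of the fluorescent liquid (a.u.).
#' @return A [LensPhantomSpec-class].
#' @export
lensPhantomSpec <- function(radius_mm = 288, diameter_mm = 25.1,
                            contact = c(0, 0), fluor_density = 1) {
  new("LensPhantomSpec", radius_mm = as.numeric(radius_mm),
      diameter_mm = as.numeric(diameter_mm), contact = as.numeric(contact),
      fluor_density = as.numeric(fluor_density))
}

#' Per-pixel top-hat slab fit result
#'
#' @slot thickness_map fitted slab thickness per pixel (nm).
#' @slot amplitude_map fitted density amplitude per pixel (a.u.).
#' @slot start_depth_map fitted (or fixed) slab start depth per pixel (nm).
#' @slot residual_map per-pixel fit RMS residual.
#' @slot flag_map integer codes: 0 ok, 1 empty pixel, 2 parameter at
#'   bound, 3 lack of fit (residual above 10% of the curve RMS).
#' @seealso [fitSlabPerPixel()]
#' @export
setClass("SlabFitResult",
  representation(thickness_map = "matrix", amplitude_map = "matrix",
                 start_depth_map = "matrix", residual_map = "matrix",
                 flag_map = "matrix"))

setValidity("SlabFitResult", function(object) {
  msg <- character()
  if (any(object@thickness_map < 0, na.rm = TRUE))
    msg <- c(msg, "thickness must be >= 0")
  if (any(object@amplitude_map < 0, na.rm = TRUE))
    msg <- c(msg, "amplitude must be >= 0")
  if (any(!is.finite(object@residual_map)))
    msg <- c(msg, "residuals must be finite")
  if (length(msg)) msg else TRUE
})

#' Per-pixel mean depth map
#'
#' Mean depth is the rounded intensity-weighted mean slice index times the
#' axial step, so values are integer multiples of dz in
#' [dz, nz * dz] (slice indices are 1-based). Pixels without axial mass are
#' invalid (NA).
#'
#' @slot values per-pixel depth (nm); NA on invalid pixels.
#' @slot valid_mask logical matrix of pixels with nonzero axial mass.
#' @slot dz_nm axial step (nm).
#' @slot nz number of slices of the source volume.
#' @seealso [meanDepthMap()]
#' @export
setClass("DepthMap",
  representation(values = "matrix", valid_mask = "matrix", dz_nm = "numeric",
                 nz = "integer"))

setValidity("DepthMap", function(object) {
  v <- object@values[object@valid_mask]
  msg <- character()
  if (anyNA(v)) msg <- c(msg, "valid pixels must have a depth value")
  else {
    if (any(v < object@dz_nm - 1e-9 | v > object@nz * object@dz_nm + 1e-9))
      msg <- c(msg, "depths must lie in [dz, nz * dz]")
    if (any(abs(v / object@dz_nm - round(v / object@dz_nm)) > 1e-9))
      msg <- c(msg, "depths must be integer multiples of dz")
  }
  if (length(msg)) msg else TRUE
})

#' Relative-depth 2D histogram between two channels
#'
#' @slot bins depth bin centers shared by both axes (nm), dz-spaced.
#' @slot counts nonnegative weight matrix; rows index channel-1 depth.
#' @slot normalized logical; when TRUE the maximum equals 1 exactly.
#' @seealso [relativeDepthHistogram()]
#' @export
setClass("RelativeDepthHistogram",
  representation(bins = "numeric", counts = "matrix", normalized = "logical"))

setValidity("RelativeDepthHistogram", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (nrow(object@counts) != length(object@bins) ||
      ncol(object@counts) != length(object@bins))
    msg <- c(msg, "counts must be square on the bin grid")
  if (isTRUE(object@normalized) && max(object@counts) != 1)
    msg <- c(msg, "normalized histogram must have maximum exactly 1")
  if (length(msg)) msg else TRUE
})

#' Options for color-coded depth rendering
#'
#' @slot colormap nz x 3 matrix of RGB triplets in [0, 1], one per slice
#'   (isoluminant by default).
#' @slot intensity_scaling \code{"linear"} or \code{"percentile_clip"}.
#' @seealso [renderOptions()], [depthRender()]
#' @export
setClass("RenderOptions",
  representation(colormap = "matrix", intensity_scaling = "character"))

setValidity("RenderOptions", function(object) {
  msg <- character()
  if (ncol(object@colormap) != 3L)
    msg <- c(msg, "colormap must have three columns (R, G, B)")
  if (any(object@colormap < 0 | object@colormap > 1))
    msg <- c(msg, "colormap entries must lie in [0, 1]")
  if (!object@intensity_scaling %in% c("linear", "percentile_clip"))
    msg <- c(msg, "intensity_scaling must be linear or percentile_clip")
  if (length(msg)) msg else TRUE
})

#' Create render options
#' @param colormap nz x 3 RGB matrix; defaults to [isolumColormap()] of the
#'   requested length.
#' @param nz number of slices (used when \code{colormap} is missing).
#' @param intensity_scaling \code{"linear"} or \code{"percentile_clip"}.
#' @return A [RenderOptions-class].
#' @export
renderOptions <- function(colormap = NULL, nz = 20L,
                          intensity_scaling = c("linear", "percentile_clip")) {
  if (is.null(colormap)) colormap <- isolumColormap(nz)
  new("RenderOptions", colormap = colormap,
      intensity_scaling = match.arg(intensity_scaling))
}
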