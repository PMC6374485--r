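## File formats and configuration: multi-page TIFF stacks/volumes with
## plain-text sidecars (YAML metadata, CSV angle lists) and the validated
## run configuration. Axial orientation convention: page 1 is the
## coverslip-nearest slice, z grows away from the coverslip.

.pagesToArray <- function(pages) {
  if (is.matrix(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], length(pages)))
  for (m in seq_along(pages)) {
    p <- pages[[m]]
    if (length(dim(p)) == 3L) p <- p[, , 1]   # collapse grayscale channels
    arr[, , m] <- p
  }
  arr
}

## normalized 32-bit TIFF storage: pages carry (x - offset) / scale in
## [0, 1] at 32-bit depth; offset/scale live in the YAML sidecar, so the
## round trip is accurate to ~1e-9 of the data range
.writePages32 <- function(arr, path) {
  offset <- min(arr, 0)
  scale <- max(arr - offset)
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(m) (arr[, , m] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  list(offset = offset, scale = scale)
}

.readPages <- function(path, meta = NULL) {
  if (is.null(meta)) {
    ## raw integer samples (e.g. 16-bit camera counts), taken as-is
    .pagesToArray(tiff::readTIFF(path, all = TRUE, as.is = TRUE))
  } else {
    arr <- .pagesToArray(tiff::readTIFF(path, all = TRUE))
    sc <- if (is.null(meta$scale)) 1 else meta$scale
    off <- if (is.null(meta$offset)) 0 else meta$offset
    arr * sc + off
  }
}

#' Read / write a multi-angle stack as multi-page TIFF
#'
#' One 32-bit page per angle, ascending-angle page order. Written stacks
#' are normalized to the data range at 32-bit depth with the range (and
#' angles, pixel size) recorded in a YAML sidecar, so values round-trip
#' to ~1e-9 relative accuracy. Plain TIFFs without a sidecar (e.g. 16-bit
#' unsigned camera output) are read as-is, converted to float with no
#' scaling.
#'
#' @param path TIFF file path.
#' @param angles_source an [AngleSet-class], a numeric vector of degrees,
#'   or the path of a one-column CSV of angles; may be omitted when the
#'   sidecar stores the angles.
#' @param meta_path YAML sidecar path (default: \code{path} + ".yml").
#' @param pixel_size_nm lateral pixel size (nm); sidecar value wins.
#' @param channel_label channel tag for the returned stack.
#' @return \code{readStack}: an [AcquisitionStack-class].
#' @export
readStack <- function(path, angles_source = NULL,
                      meta_path = paste0(path, ".yml"),
                      pixel_size_nm = 107, channel_label = "") {
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  arr <- .readPages(path, meta)
  if (is.null(angles_source)) {
    if (is.null(meta$angles_deg))
      stop("no angle source: supply angles_source or a sidecar with angles")
    angles_source <- unlist(meta$angles_deg)
  }
  aset <- if (is(angles_source, "AngleSet")) angles_source
          else if (is.numeric(angles_source)) angleSet(angles_source)
          else angleSet(readAnglesCsv(angles_source))
  if (!is.null(meta$pixel_size_nm)) pixel_size_nm <- meta$pixel_size_nm
  if (dim(arr)[3] != nAngles(aset))
    stop("TIFF has ", dim(arr)[3], " pages but the angle set has ",
         nAngles(aset), " angles")
  acquisitionStack(arr, aset, pixel_size_nm, channel_label)
}

#' @rdname readStack
#' @param stack an [AcquisitionStack-class] (or \code{nx x ny x M} array).
#' @return \code{writeStack}: the path, invisibly.
#' @export
writeStack <- function(stack, path, meta_path = paste0(path, ".yml")) {
  g <- if (is(stack, "AcquisitionStack")) stack@images else stack
  norm <- .writePages32(g, path)
  meta <- c(norm, list(
    angles_deg = if (is(stack, "AcquisitionStack")) angles(stack) else NULL,
    pixel_size_nm = if (is(stack, "AcquisitionStack")) stack@pixel_size_nm
                    else NULL))
  yaml::write_yaml(meta[!vapply(meta, is.null, TRUE)], meta_path)
  invisible(path)
}

#' Read / write an angle list as a one-column CSV (degrees)
#' @param path CSV file path.
#' @return \code{readAnglesCsv}: numeric vector of angles in degrees.
#' @export
readAnglesCsv <- function(path) {
  df <- utils::read.csv(path)
  as.numeric(df[[1]])
}

#' @rdname readAnglesCsv
#' @param angles numeric vector or [AngleSet-class].
#' @export
writeAnglesCsv <- function(angles, path) {
  if (is(angles, "AngleSet")) angles <- angles(angles)
  utils::write.csv(data.frame(angle_deg = angles), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a fluorophore volume as multi-page TIFF plus YAML metadata
#'
#' One 32-bit page per z-slice, ascending depth (page 1 nearest the
#' coverslip), normalized to the data range like [writeStack()]. The grid
#' geometry (nx, ny, nz, dz_nm, pixel_size_nm, z0_nm) is carried by the
#' YAML sidecar so the round trip preserves it; without a sidecar a
#' [GridSpec-class] must be supplied (the axial step cannot be guessed).
#'
#' @param path TIFF file path.
#' @param meta_path YAML sidecar path (default: \code{path} + ".yml").
#' @param grid a [GridSpec-class], used instead of the sidecar geometry.
#' @return \code{readVolume}: a [FluorophoreVolume-class].
#' @export
readVolume <- function(path, meta_path = paste0(path, ".yml"), grid = NULL) {
  m <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  arr <- .readPages(path, m)
  if (is.null(grid)) {
    if (is.null(m))
      stop("no grid metadata: missing sidecar ", meta_path,
           " and no grid supplied (dz unknown)")
    grid <- gridSpec(m$nx, m$ny, m$nz, m$dz_nm, m$pixel_size_nm, m$z0_nm)
  }
  d <- dim(arr)
  if (!all(d == c(grid@nx, grid@ny, grid@nz)))
    stop("TIFF dimensions ", paste(d, collapse = "x"),
         " do not match the grid ", grid@nx, "x", grid@ny, "x", grid@nz)
  fluorophoreVolume(pmax(arr, 0), grid)
}

#' @rdname readVolume
#' @param volume a [FluorophoreVolume-class].
#' @export
writeVolume <- function(volume, path, meta_path = paste0(path, ".yml")) {
  g <- volume@grid
  norm <- .writePages32(volume@values, path)
  yaml::write_yaml(c(norm, list(nx = g@nx, ny = g@ny, nz = g@nz,
                                dz_nm = g@dz_nm,
                                pixel_size_nm = g@pixel_size_nm,
                                z0_nm = g@z0_nm)), meta_path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Run configuration
## ---------------------------------------------------------------------------

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key(s) under '", where, "': ",
         paste(bad, collapse = ", "))
}

.getOr <- function(x, key, default) if (is.null(x[[key]])) default else x[[key]]

#' Parse and validate a YAML run configuration
#'
#' Top-level sections: \code{optical}, \code{grid}, \code{angles},
#' \code{regularizer}, \code{solver}, \code{noise}, \code{paths}. Unknown
#' keys are rejected with the offending key path; component invariants are
#' enforced by the respective constructors. \code{angles} is either
#' \code{values:} (list of degrees) or \code{csv:} (one-column file).
#' \code{regularizer.mu} has no default and is required whenever the
#' section is present.
#'
#' @param path YAML file path.
#' @return A list with elements \code{optical} ([OpticalConfig-class]),
#'   \code{grid} ([GridSpec-class]), \code{angles} ([AngleSet-class] or
#'   NULL), \code{regularizer} ([RegularizerSpec-class] or NULL),
#'   \code{solver} ([SolverOptions-class]), \code{noise}
#'   ([NoiseSpec-class]), \code{paths} (list).
#' @export
parseConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .checkKeys(cfg, c("optical", "grid", "angles", "regularizer", "solver",
                    "noise", "paths"), "(top level)")

  o <- .getOr(cfg, "optical", list())
  .checkKeys(o, c("wavelength_nm", "n_incident", "n_sample",
                  "numerical_aperture", "pixel_size_nm"), "optical")
  optical <- opticalConfig(
    wavelength_nm = .getOr(o, "wavelength_nm", 491),
    n_incident = .getOr(o, "n_incident", 1.515),
    n_sample = .getOr(o, "n_sample", 1.33),
    numerical_aperture = .getOr(o, "numerical_aperture", 1.49),
    pixel_size_nm = .getOr(o, "pixel_size_nm", 107))

  gr <- .getOr(cfg, "grid", list())
  .checkKeys(gr, c("nx", "ny", "nz", "dz_nm", "pixel_size_nm", "z0_nm"),
             "grid")
  grid <- gridSpec(nx = .getOr(gr, "nx", 64), ny = .getOr(gr, "ny", 64),
                   nz = .getOr(gr, "nz", 20), dz_nm = .getOr(gr, "dz_nm", 20),
                   pixel_size_nm = .getOr(gr, "pixel_size_nm",
                                          optical@pixel_size_nm),
                   z0_nm = .getOr(gr, "z0_nm", 0))

  angles <- NULL
  if (!is.null(cfg$angles)) {
    .checkKeys(cfg$angles, c("values", "csv"), "angles")
    av <- if (!is.null(cfg$angles$values)) unlist(cfg$angles$values)
          else readAnglesCsv(cfg$angles$csv)
    angles <- angleSet(av, optical)
  }

  regularizer <- NULL
  if (!is.null(cfg$regularizer)) {
    rg <- cfg$regularizer
    .checkKeys(rg, c("kind", "mu", "voxel_aspect"), "regularizer")
    if (is.null(rg$mu))
      stop("required key missing: regularizer.mu (no default)")
    regularizer <- regularizerSpec(
      kind = .getOr(rg, "kind", "tv"), mu = rg$mu,
      voxel_aspect = .getOr(rg, "voxel_aspect",
                            grid@dz_nm / grid@pixel_size_nm))
  }

  so <- .getOr(cfg, "solver", list())
  .checkKeys(so, c("n_iter", "rho1", "rho2", "rho3", "tol_primal",
                   "deconvolve", "normalize", "record_objective", "seed"),
             "solver")
  solver <- solverOptions(
    n_iter = .getOr(so, "n_iter", 50), rho1 = .getOr(so, "rho1", 1),
    rho2 = .getOr(so, "rho2", 1), rho3 = .getOr(so, "rho3", 1),
    tol_primal = .getOr(so, "tol_primal", NA_real_),
    deconvolve = .getOr(so, "deconvolve", TRUE),
    normalize = .getOr(so, "normalize", TRUE),
    record_objective = .getOr(so, "record_objective", FALSE),
    seed = .getOr(so, "seed", 0))

  no <- .getOr(cfg, "noise", list())
  .checkKeys(no, c("model", "gaussian_sigma", "photon_scale", "seed"),
             "noise")
  noise <- noiseSpec(model = .getOr(no, "model", "poisson_gaussian"),
                     gaussian_sigma = .getOr(no, "gaussian_sigma", 0.01),
                     photon_scale = .getOr(no, "photon_scale", 1000),
                     seed = .getOr(no, "seed", 1))

  list(optical = optical, grid = grid, angles = angles,
       regularizer = regularizer, solver = solver, noise = noise,
       paths = .getOr(cfg, "paths", list()))
}
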