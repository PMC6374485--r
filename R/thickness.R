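## Calibration-phantom workflow: the multi-angle intensity of a uniform
## fluorescent slab (top-hat axial profile) has a closed form, so per-pixel
## nonlinear least squares recovers the local layer thickness; on the
## spherical-lens phantom the thickness profile then yields the radius of
## curvature.

.excitIP <- function(excitation) {
  if (is(excitation, "ExcitationModel"))
    list(i0 = excitation@i0, p = excitation@p)
  else if (is.list(excitation) && all(c("i0", "p") %in% names(excitation)))
    list(i0 = as.numeric(excitation$i0), p = as.numeric(excitation$p))
  else stop("excitation must be an ExcitationModel or list(i0 =, p =)")
}

#' Multi-angle intensity of a uniform fluorescent slab
#'
#' Closed-form axial integral of the evanescent excitation over a slab of
#' density A occupying depths [z0, z0 + t]:
#' \deqn{g_m = A\, I_0(\alpha_m) e^{-z_0 p_m} (1 - e^{-t p_m}) / p_m,}
#' with the widefield limit \code{A * I0 * t} at \code{p = 0}. The
#' intensity grows strictly with both t and A at every angle.
#'
#' @param thickness_nm slab thickness t (nm), >= 0.
#' @param amplitude density A (a.u.), >= 0.
#' @param z0_nm slab start depth (nm), >= 0.
#' @param excitation an [ExcitationModel-class] or \code{list(i0 =, p =)}
#'   (\code{p >= 0} allowed in list form).
#' @return Numeric vector of M per-angle intensities.
#' @export
slabIntensity <- function(thickness_nm, amplitude, z0_nm, excitation) {
  if (thickness_nm < 0) stop("thickness must be >= 0")
  ex <- .excitIP(excitation)
  out <- numeric(length(ex$p))
  zero <- ex$p == 0
  if (any(zero))
    out[zero] <- amplitude * ex$i0[zero] * thickness_nm
  if (any(!zero)) {
    p <- ex$p[!zero]
    ## -expm1(-t p) = 1 - e^{-t p}, stable for small t p
    out[!zero] <- amplitude * ex$i0[!zero] * exp(-z0_nm * p) *
      (-expm1(-thickness_nm * p)) / p
  }
  out
}

## fit one pixel's M-point angle curve; returns c(t, A, z0, rms, flag)
.fitSlabPixel <- function(y, i0, p, fix_z0, t_starts, t_max, z0_max,
                          noise = NULL) {
  if (max(abs(y)) == 0)
    return(c(0, 0, 0, 0, 1))
  ex <- list(i0 = i0, p = p)
  model <- function(par) {
    z0 <- if (fix_z0) 0 else par[3]
    slabIntensity(par[1], par[2], z0, ex)
  }
  lower <- if (fix_z0) c(0, 0) else c(0, 0, 0)
  upper <- if (fix_z0) c(t_max, Inf) else c(t_max, Inf, z0_max)
  lmfit <- function(par0, sw) tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = function(par) (model(par) - y) / sw,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  best <- NULL
  for (t0 in t_starts) {
    s <- slabIntensity(t0, 1, 0, ex)
    a0 <- max(sum(y * s) / sum(s * s), 1e-12)
    par0 <- if (fix_z0) c(t0, a0) else c(t0, a0, 0)
    fit <- lmfit(par0, 1)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) return(c(NA, NA, NA, Inf, 2))
  if (!is.null(noise)) {
    ## IRLS refinement: weight residuals by the model-predicted camera
    ## variance (shot noise / photon_scale + read noise)
    par <- best$par
    for (k in 1:3) {
      v <- pmax(model(par), 0) / noise$photon_scale + noise$gaussian_sigma^2
      fit <- lmfit(par, sqrt(pmax(v, 1e-300)))
      if (is.null(fit)) break
      par <- fit$par
    }
    best$par <- par
    best$rss <- sum((model(par) - y)^2)
  }
  t_hat <- best$par[1]; a_hat <- best$par[2]
  z0_hat <- if (fix_z0) 0 else best$par[3]
  rms <- sqrt(best$rss / length(y))
  flag <- 0
  if (t_hat > t_max - 1e-6 || (!fix_z0 && z0_hat > z0_max - 1e-6)) flag <- 2
  ## lack of fit: the slab model cannot reproduce the curve shape
  else if (rms > 0.1 * sqrt(mean(y^2))) flag <- 3
  c(t_hat, a_hat, z0_hat, rms, flag)
}

#' Per-pixel top-hat slab fit of a multi-angle stack
#'
#' For every lateral pixel, fits the closed-form slab curve
#' [slabIntensity()] to the M-point per-angle intensity by bounded
#' Levenberg-Marquardt least squares. Free parameters are the thickness t
#' and amplitude A (plus the start depth z0 unless \code{fix_z0}). To
#' avoid local minima the fit is restarted from a deterministic grid of
#' thickness initializations (50, 150, 300 nm by default) with the
#' amplitude initialized at its least-squares projection; the best
#' residual wins.
#'
#' When the camera noise model is calibrated, passing \code{noise} (a
#' [NoiseSpec-class] or \code{list(photon_scale =, gaussian_sigma =)})
#' switches on iteratively reweighted least squares: residuals are scaled
#' by the model-predicted standard deviation
#' \code{sqrt(signal / photon_scale + sigma^2)}, the approximate maximum
#' likelihood estimator for shot-noise-limited data.
#'
#' The stack must be background-subtracted. All-zero pixels are returned
#' as thickness 0 / amplitude 0 with flag 1; fits ending on a parameter
#' bound carry flag 2.
#'
#' @param stack an [AcquisitionStack-class] or \code{nx x ny x M} array,
#'   background-subtracted.
#' @param excitation an [ExcitationModel-class] (or \code{list(i0 =, p =)})
#'   matching the stack's angles.
#' @param fix_z0 logical; fix the slab start at the coverslip (z0 = 0,
#'   appropriate for the lens phantom).
#' @param t_starts deterministic thickness initializations (nm).
#' @param t_max,z0_max parameter bounds (nm).
#' @param noise optional calibrated camera noise model for variance
#'   weighting (NULL = unweighted fit).
#' @return A [SlabFitResult-class].
#' @export
fitSlabPerPixel <- function(stack, excitation, fix_z0 = TRUE,
                            t_starts = c(50, 150, 300), t_max = 1000,
                            z0_max = 500, noise = NULL) {
  g <- if (is(stack, "AcquisitionStack")) stack@images else stack
  d <- dim(g)
  ex <- .excitIP(excitation)
  if (length(ex$p) != d[3])
    stop("stack has ", d[3], " pages but excitation has ", length(ex$p),
         " angles")
  n_par <- if (fix_z0) 2L else 3L
  if (d[3] < n_par)
    stop("need at least ", n_par, " angles for ", n_par, " free parameters")
  if (is(noise, "NoiseSpec"))
    noise <- if (noise@model == "poisson_gaussian")
      list(photon_scale = noise@photon_scale,
           gaussian_sigma = noise@gaussian_sigma)
    else if (noise@model == "gaussian") NULL   # homoscedastic: plain LS
    else NULL
  G <- matrix(g, d[1] * d[2], d[3])
  res <- matrix(0, d[1] * d[2], 5L)
  for (i in seq_len(nrow(G)))
    res[i, ] <- .fitSlabPixel(G[i, ], ex$i0, ex$p, fix_z0, t_starts,
                              t_max, z0_max, noise)
  shape <- function(k) matrix(res[, k], d[1], d[2])
  new("SlabFitResult", thickness_map = shape(1), amplitude_map = shape(2),
      start_depth_map = shape(3), residual_map = shape(4),
      flag_map = shape(5))
}

#' Gap thickness under a spherical lens
#'
#' Thickness of the liquid layer between a flat coverslip and a spherical
#' lens of curvature radius R touching it at r = 0:
#' \eqn{t(r) = R - \sqrt{R^2 - r^2}} (about \eqn{r^2 / 2R} near contact),
#' returned in nm.
#'
#' @param spec a [LensPhantomSpec-class].
#' @param lateral_positions_mm radial distances from the contact point (mm).
#' @return Gap thicknesses in nm.
#' @examples
#' lensGapProfile(lensPhantomSpec(), 0.48)  # ~400 nm
#' @export
lensGapProfile <- function(spec, lateral_positions_mm) {
  stopifnot(is(spec, "LensPhantomSpec"))
  r <- abs(lateral_positions_mm)
  if (any(r > spec@diameter_mm / 2))
    stop("lateral position beyond the lens radius (", spec@diameter_mm / 2,
         " mm)")
  R <- spec@radius_mm
  (R - sqrt(R^2 - r^2)) * 1e6
}

#' Recover the lens radius of curvature from a fitted thickness map
#'
#' Restricts pixels to a thickness window where the slab fit is reliable
#' (100-400 nm by default), and least-squares fits the parabolic gap
#' approximation \eqn{t(r) = r^2 / (2 R) + c} against radial distance from
#' the contact point.
#'
#' @param thickness_map matrix of fitted thicknesses (nm), e.g.
#'   \code{fit@thickness_map}.
#' @param pixel_size_nm lateral pixel size (nm).
#' @param depth_window_nm inclusive thickness window (nm) of pixels used.
#' @param contact_px lateral (row, col) pixel coordinates of the contact
#'   point; defaults to the pixel of minimum thickness.
#' @return List with \code{radius_mm} (the estimate; \code{Inf} when the
#'   profile has no usable curvature, i.e. a nonpositive or implausibly
#'   small fitted slope corresponding to R > 1 m), \code{intercept_nm},
#'   \code{n_pixels}, and \code{unbounded} flag.
#' @export
fitLensRadius <- function(thickness_map, pixel_size_nm,
                          depth_window_nm = c(100, 400), contact_px = NULL) {
  t_nm <- thickness_map
  if (is.null(contact_px)) {
    w <- which(t_nm == min(t_nm, na.rm = TRUE), arr.ind = TRUE)
    contact_px <- w[1, ]
  }
  rr <- sqrt(outer((seq_len(nrow(t_nm)) - contact_px[1])^2,
                   (seq_len(ncol(t_nm)) - contact_px[2])^2, `+`)) *
    pixel_size_nm * 1e-6                       # mm
  use <- is.finite(t_nm) & t_nm >= depth_window_nm[1] &
    t_nm <= depth_window_nm[2]
  if (sum(use) < 10)
    stop("fewer than 10 usable pixels in the thickness window")
  fit <- stats::lm(t ~ r2, data = data.frame(t = t_nm[use], r2 = rr[use]^2))
  slope <- stats::coef(fit)[["r2"]]            # nm per mm^2
  unbounded <- !is.finite(slope) || slope <= 0 || 1e6 / (2 * slope) > 1e6
  radius_mm <- if (unbounded) Inf else 1e6 / (2 * slope)
  list(radius_mm = radius_mm, intercept_nm = stats::coef(fit)[["(Intercept)"]],
       n_pixels = sum(use), unbounded = unbounded)
}
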