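## Evanescent-excitation physics: critical angle, penetration depth,
## interface intensity and the back-focal-plane geometry.

#' Critical angle of total internal reflection
#'
#' The incidence angle above which the excitation beam is totally reflected
#' at the glass/sample interface and only an evanescent wave enters the
#' sample: \code{asin(n_sample / n_incident)}.
#'
#' @param config an [OpticalConfig-class].
#' @return Critical angle in degrees.
#' @examples
#' criticalAngle(opticalConfig())  # ~61.4 deg for glass/water
#' @export
criticalAngle <- function(config) {
  stopifnot(is(config, "OpticalConfig"))
  validObject(config)
  asin(config@n_sample / config@n_incident) * 180 / pi
}

#' Inverse penetration depth of the evanescent wave
#'
#' For a supercritical incidence angle the evanescent excitation decays as
#' \eqn{e^{-z p(\alpha)}} with
#' \deqn{p(\alpha) = \frac{4\pi}{\lambda}\sqrt{n_1^2 \sin^2\alpha - n_2^2},}
#' so \code{1/p} is the depth at which excitation falls to 1/e. \code{p}
#' grows strictly with the angle: steeper illumination probes a thinner
#' layer.
#'
#' @param config an [OpticalConfig-class].
#' @param angle_deg incidence angle(s) in degrees, strictly above the
#'   critical angle.
#' @return Inverse penetration depth(s) in 1/nm.
#' @examples
#' cfg <- opticalConfig()
#' 1 / penetrationInverse(cfg, 70)  # penetration depth ~77 nm
#' @export
penetrationInverse <- function(config, angle_deg) {
  stopifnot(is(config, "OpticalConfig"))
  ac <- criticalAngle(config)
  if (any(angle_deg <= ac))
    stop("angle(s) at or below the critical angle (", signif(ac, 6),
         " deg): evanescent regime undefined")
  s <- config@n_incident * sin(angle_deg * pi / 180)
  (4 * pi / config@wavelength_nm) * sqrt(s^2 - config@n_sample^2)
}

#' Evanescent intensity at the interface
#'
#' Intensity transmission factor I0 at z = 0. In \code{"unit"} mode it is 1
#' for every angle (angle-dependent excitation strength is absorbed into
#' the arbitrary units of the fluorophore density). In \code{"fresnel_s"}
#' mode it is the s-polarized evanescent-field intensity enhancement
#' \eqn{4\cos^2\alpha / (1 - n^2)} with \eqn{n = n_2/n_1}, which decreases
#' from 4 at the critical angle as the angle grows.
#'
#' @param config an [OpticalConfig-class].
#' @param angle_deg supercritical incidence angle(s), degrees.
#' @param mode \code{"unit"} or \code{"fresnel_s"}.
#' @return Interface intensity factor(s) (arbitrary units).
#' @export
interfaceIntensity <- function(config, angle_deg, mode = c("unit", "fresnel_s")) {
  stopifnot(is(config, "OpticalConfig"))
  mode <- match.arg(mode)
  ac <- criticalAngle(config)
  if (any(angle_deg <= ac))
    stop("angle(s) at or below the critical angle (", signif(ac, 6), " deg)")
  if (mode == "unit") return(rep(1, length(angle_deg)))
  n <- config@n_sample / config@n_incident
  4 * cos(angle_deg * pi / 180)^2 / (1 - n^2)
}

#' Build a per-angle excitation model
#'
#' Evaluates \code{p} and \code{I0} at every angle of the set and bundles
#' them into an [ExcitationModel-class].
#'
#' @param config an [OpticalConfig-class].
#' @param angle_set an [AngleSet-class] (all angles supercritical).
#' @param i0_mode interface-intensity mode, see [interfaceIntensity()].
#' @return An [ExcitationModel-class].
#' @examples
#' cfg <- opticalConfig()
#' excitationModel(cfg, angleSet(seq(63, 75, length.out = 10), cfg))
#' @export
excitationModel <- function(config, angle_set, i0_mode = "unit") {
  stopifnot(is(angle_set, "AngleSet"))
  a <- angles(angle_set)
  new("ExcitationModel", angle_set = angle_set,
      i0 = interfaceIntensity(config, a, i0_mode),
      p = penetrationInverse(config, a))
}

#' Map a back-focal-plane ring radius to an incidence angle
#'
#' In the objective's back focal plane the illumination spot traces a ring
#' whose radius encodes the incidence angle through the Abbe sine
#' condition \eqn{r = f_{obj}\, n_1 \sin\alpha}.
#'
#' @param radius_um ring radius in the back focal plane (micrometres).
#' @param objective_focal_mm objective focal length (mm).
#' @param config an [OpticalConfig-class] supplying \code{n_incident}.
#' @return Incidence angle in degrees.
#' @seealso [angleToBfpRadius()]
#' @export
bfpRadiusToAngle <- function(radius_um, objective_focal_mm, config) {
  stopifnot(is(config, "OpticalConfig"))
  if (any(radius_um < 0) || objective_focal_mm <= 0)
    stop("radius and focal length must be nonnegative/positive")
  s <- radius_um / (objective_focal_mm * 1000 * config@n_incident)
  if (any(s > 1 + 1e-12))
    stop("ring radius exceeds the aperture (r > f_obj * n_incident)")
  asin(pmin(s, 1)) * 180 / pi
}

#' Incidence angle giving a prescribed penetration depth
#'
#' Inverts the closed form of [penetrationInverse()]: returns the
#' supercritical angle at which the evanescent penetration depth \code{1/p}
#' equals \code{depth_nm}.
#'
#' @param config an [OpticalConfig-class].
#' @param depth_nm target penetration depth (nm), > 0.
#' @return Incidence angle in degrees.
#' @export
angleForPenetration <- function(config, depth_nm) {
  stopifnot(is(config, "OpticalConfig"))
  if (any(depth_nm <= 0)) stop("penetration depth must be positive")
  p <- 1 / depth_nm
  s <- sqrt((p * config@wavelength_nm / (4 * pi))^2 + config@n_sample^2) /
    config@n_incident
  if (any(s > 1))
    stop("penetration depth unreachable within the aperture")
  asin(s) * 180 / pi
}

#' Design a multi-angle acquisition sequence
#'
#' Chooses n supercritical angles between a near-critical lower bound and
#' the objective aperture limit. With \code{spacing = "p_uniform"} (the
#' default) the angles are equally spaced in the inverse penetration depth
#' p, so the exponential depth weights sample the axial range evenly --
#' the natural design when the goal is depth reconstruction over the full
#' accessible range; \code{"angle_uniform"} spaces the angles themselves
#' evenly.
#'
#' @param config an [OpticalConfig-class].
#' @param n number of angles (default 10).
#' @param min_angle_deg lower bound; default critical angle + 0.2 degrees
#'   (penetration depths of several hundred nm while staying safely in the
#'   evanescent regime).
#' @param max_angle_deg upper bound; default 0.5 degrees inside the
#'   objective aperture limit \code{asin(NA / n_incident)}.
#' @param spacing \code{"p_uniform"} or \code{"angle_uniform"}.
#' @return An [AngleSet-class].
#' @examples
#' cfg <- opticalConfig()
#' round(1 / excitationModel(cfg, angleDesign(cfg))@p)  # depths ~59-475 nm
#' @export
angleDesign <- function(config, n = 10L, min_angle_deg = NULL,
                        max_angle_deg = NULL,
                        spacing = c("p_uniform", "angle_uniform")) {
  spacing <- match.arg(spacing)
  stopifnot(is(config, "OpticalConfig"))
  if (is.null(min_angle_deg)) min_angle_deg <- criticalAngle(config) + 0.2
  if (is.null(max_angle_deg))
    max_angle_deg <- asin(config@numerical_aperture / config@n_incident) *
      180 / pi - 0.5
  if (max_angle_deg <= min_angle_deg)
    stop("empty angle range")
  a <- if (spacing == "angle_uniform") {
    seq(min_angle_deg, max_angle_deg, length.out = n)
  } else {
    pr <- penetrationInverse(config, c(min_angle_deg, max_angle_deg))
    angleForPenetration(config, 1 / seq(pr[1], pr[2], length.out = n))
  }
  angleSet(a, config)
}

#' Map an incidence angle to its back-focal-plane ring radius
#'
#' Inverse of [bfpRadiusToAngle()]: \eqn{r = f_{obj}\, n_1 \sin\alpha}.
#'
#' @param angle_deg incidence angle in degrees, in [0, 90].
#' @param objective_focal_mm objective focal length (mm).
#' @param config an [OpticalConfig-class].
#' @return Ring radius in micrometres.
#' @export
angleToBfpRadius <- function(angle_deg, objective_focal_mm, config) {
  stopifnot(is(config, "OpticalConfig"))
  if (any(angle_deg < 0 | angle_deg > 90))
    stop("angle must lie in [0, 90] degrees")
  objective_focal_mm * 1000 * config@n_incident * sin(angle_deg * pi / 180)
}
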