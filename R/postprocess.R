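## Depth statistics and visualization: per-pixel mean depth maps,
## relative-depth 2D histograms between channels, color-coded depth
## rendering and lateral drift estimation.

## round half away from zero (base round() is banker's); depths are
## nonnegative here but the rule is kept general
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-pixel mean depth of a reconstructed volume
#'
#' For each lateral pixel i the mean depth is
#' \deqn{D_i = \mathrm{round}\Big(\sum_j j R_{ij} / \sum_j R_{ij}\Big)
#'   \times \delta_z}
#' with 1-based slice index j, so values are integer multiples of the
#' axial step in \code{[dz, nz * dz]}. Rounding is half away from zero.
#' Pixels with no axial mass are masked invalid (NA).
#'
#' @param volume a [FluorophoreVolume-class] (nonnegative).
#' @return A [DepthMap-class].
#' @examples
#' g <- gridSpec(4, 4, nz = 5)
#' v <- array(0, c(4, 4, 5)); v[, , 3] <- 1
#' meanDepthMap(fluorophoreVolume(v, g))@values[1, 1]   # 60 nm
#' @export
meanDepthMap <- function(volume) {
  stopifnot(is(volume, "FluorophoreVolume"))
  v <- volume@values
  g <- volume@grid
  mass <- apply(v, 1:2, sum)
  jmean <- apply(v, 1:2, function(col) sum(seq_along(col) * col)) / mass
  valid <- mass > 0
  vals <- matrix(NA_real_, g@nx, g@ny)
  vals[valid] <- .roundHalfAway(jmean[valid]) * g@dz_nm
  new("DepthMap", values = vals, valid_mask = valid, dz_nm = g@dz_nm,
      nz = g@nz)
}

#' Relative-depth 2D histogram between two channels
#'
#' Loops over pixels valid in both channels and accumulates, at bin
#' \code{(D_i^1, D_i^2)} of the mean-depth pair, the geometric mean of the
#' two axial masses:
#' \code{H(D1, D2) += sqrt(sum_j R1_ij * sum_j R2_ij)}. The histogram is
#' then normalized so its maximal value is exactly 1 (unless
#' \code{normalize = FALSE}). Identical channels put all weight on the
#' diagonal.
#'
#' @param vol1,vol2 [FluorophoreVolume-class] objects on the same grid.
#' @param normalize divide by the maximum.
#' @return A [RelativeDepthHistogram-class]; bins are the possible depth
#'   values \code{(1:nz) * dz} (nm).
#' @export
relativeDepthHistogram <- function(vol1, vol2, normalize = TRUE) {
  stopifnot(is(vol1, "FluorophoreVolume"), is(vol2, "FluorophoreVolume"))
  g1 <- vol1@grid; g2 <- vol2@grid
  if (g1@nx != g2@nx || g1@ny != g2@ny || g1@nz != g2@nz ||
      g1@dz_nm != g2@dz_nm)
    stop("the two volumes must share the same grid")
  m1 <- apply(vol1@values, 1:2, sum)
  m2 <- apply(vol2@values, 1:2, sum)
  d1 <- meanDepthMap(vol1); d2 <- meanDepthMap(vol2)
  both <- d1@valid_mask & d2@valid_mask
  if (!any(both))
    stop("no pixel has axial mass in both channels (empty histogram)")
  k1 <- as.integer(round(d1@values[both] / g1@dz_nm))
  k2 <- as.integer(round(d2@values[both] / g1@dz_nm))
  w <- sqrt(m1[both] * m2[both])
  counts <- matrix(0, g1@nz, g1@nz)
  for (i in seq_along(w))
    counts[k1[i], k2[i]] <- counts[k1[i], k2[i]] + w[i]
  if (normalize) counts <- counts / max(counts)
  new("RelativeDepthHistogram", bins = seq_len(g1@nz) * g1@dz_nm,
      counts = counts, normalized = isTRUE(normalize))
}

#' Isoluminant depth colormap
#'
#' A blue-to-orange ramp of roughly constant luminance, one RGB triplet
#' per z-slice, suitable for color-coding depth without confounding hue
#' and brightness.
#'
#' @param n number of entries (one per slice).
#' @return \code{n x 3} matrix of RGB values in [0, 1].
#' @export
isolumColormap <- function(n = 20L) {
  anchors <- c("#3C6FDCFF", "#00909E", "#4E9A51", "#C2883A", "#E06D3C")
  ramp <- grDevices::colorRamp(anchors, space = "Lab")
  m <- ramp(seq(0, 1, length.out = n)) / 255
  m[m < 0] <- 0; m[m > 1] <- 1
  dimnames(m) <- NULL
  m[, 1:3, drop = FALSE]
}

#' Color-coded depth rendering of a volume
#'
#' Multiplies each z-slice by its colormap entry and averages along z:
#' \code{RGB_i = (1/nz) * sum_j R_ij * colormap[j, ]}. With
#' \code{rescale = TRUE} the image is scaled into [0, 1] afterwards
#' (linearly, or after clipping at the 99.5th luminance percentile for
#' \code{"percentile_clip"}); scaling is a global scalar, so hues are
#' unchanged.
#'
#' @param volume a [FluorophoreVolume-class].
#' @param options a [RenderOptions-class] with \code{nz} colormap rows.
#' @param rescale logical; apply display scaling.
#' @return \code{nx x ny x 3} RGB array.
#' @export
depthRender <- function(volume, options = renderOptions(nz = volume@grid@nz),
                        rescale = TRUE) {
  stopifnot(is(volume, "FluorophoreVolume"), is(options, "RenderOptions"))
  g <- volume@grid
  if (nrow(options@colormap) != g@nz)
    stop("colormap has ", nrow(options@colormap), " entries but the volume has ",
         g@nz, " slices")
  rgb <- array(0, c(g@nx, g@ny, 3L))
  for (j in seq_len(g@nz))
    for (c in 1:3)
      rgb[, , c] <- rgb[, , c] + volume@values[, , j] * options@colormap[j, c]
  rgb <- rgb / g@nz
  if (rescale) {
    lum <- apply(rgb, 1:2, max)
    top <- if (options@intensity_scaling == "percentile_clip")
      stats::quantile(lum[lum > 0], 0.995, names = FALSE) else max(lum)
    if (is.na(top) || top == 0) top <- 1
    rgb <- pmin(rgb / top, 1)
  }
  rgb
}

#' Lateral drift between two channels
#'
#' Estimates the global lateral shift of \code{img2} relative to
#' \code{img1} by the peak of their circular cross-correlation, refined to
#' subpixel precision by separable quadratic (log-parabolic where
#' possible) interpolation around the peak, and converted to nm.
#'
#' @param img1,img2 matrices on the same lateral grid (e.g. summed
#'   intensity or mean-depth images).
#' @param pixel_size_nm lateral pixel size (nm).
#' @return Named numeric \code{c(dx, dy)} shift in nm: the displacement to
#'   apply to \code{img1} to align it with \code{img2}.
#' @export
channelDrift <- function(img1, img2, pixel_size_nm = 107) {
  if (!all(dim(img1) == dim(img2))) stop("images must share the same grid")
  if (stats::sd(img1) == 0 || stats::sd(img2) == 0)
    stop("flat image: cross-correlation peak undefined")
  a <- img1 - mean(img1); b <- img2 - mean(img2)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    length(a)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  d <- dim(cc)
  sub <- function(axis) {
    i <- pk[axis]; n <- d[axis]
    ip <- (i %% n) + 1L; im <- ((i - 2L) %% n) + 1L
    tri <- if (axis == 1L) cc[c(im, i, ip), pk[2]] else cc[pk[1], c(im, i, ip)]
    if (all(tri > 0)) tri <- log(tri)
    den <- tri[1] - 2 * tri[2] + tri[3]
    if (den == 0) 0 else 0.5 * (tri[1] - tri[3]) / den
  }
  shift <- (pk - 1) + c(sub(1L), sub(2L))
  ## wrap to the centered range (-n/2, n/2]
  shift <- ((shift + d / 2) %% d) - d / 2
  stats::setNames(shift * pixel_size_nm, c("dx", "dy"))
}
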