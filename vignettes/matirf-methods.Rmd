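---
title: "MA-TIRF depth reconstruction: models, algorithms and design choices"
author: "matirf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MA-TIRF depth reconstruction: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matirf)
```

# The physical model

Beyond the critical angle $\alpha_c = \arcsin(n_2/n_1)$ (about
$61.4^\circ$ for glass/water), the excitation beam is totally reflected
and only an evanescent field enters the sample, decaying with depth $z$
as
$$I(z, \alpha) = I_0(\alpha)\, e^{-z\,p(\alpha)}, \qquad
  p(\alpha) = \frac{4\pi}{\lambda}\sqrt{n_1^2 \sin^2\alpha - n_2^2}.$$
The penetration depth $1/p$ shrinks from several hundred nm just above
$\alpha_c$ to $\sim 60$ nm at the aperture limit of a 1.49 NA objective.
A multi-angle acquisition therefore probes the same field with a family
of exponential depth weights, and the per-angle intensity curve of each
pixel carries axial information.

Discretizing the fluorophore density $f$ on an $N_{xy} \times N_z$ grid
(slice centers $z_j = z_0 + (j-1)\,\delta_z$, coverslip at $z = 0$, $z$
growing into the sample), image formation becomes
$$\mathbf{g}_m = \mathbf{T}\,\mathbf{H}\,\mathbf{f} + \mathbf{b},$$
with $\mathbf{T}[m, j] = I_0(\alpha_m)\,e^{-z_j p(\alpha_m)}\,\delta_z$
a dense $M \times N_z$ matrix shared by all pixels (excitation depends
only on depth and angle), $\mathbf{H}$ a slice-wise 2D convolution with a
single in-focus PSF, and $\mathbf{b}$ a spatially constant per-angle
background. The 2D PSF reduction is justified by the thinness of the
excited layer: within a few hundred nm of the focal plane the 3D PSF is
nearly constant axially. The background is taken per angle (interface
intensity and laser throughput vary with the galvanometer position) and
estimated as the mean over a user-outlined structure-free region.

Assumptions worth stating: fluorophores are isotropic emitters in a
medium of uniform index $n_2$ (no correction for index mismatch inside
thick samples); the excitation is s-polarized or angle-flat
(`interfaceIntensity` offers a unit mode, the default, and an s-pol
Fresnel mode — reconstructed densities are in arbitrary units either
way); the within-slice integral of the exponential uses the midpoint rule
by default ($\delta_z\,p \ll 1$ on the default grid), with the exact
per-slab integral available (`quadrature = "exact"`).

# The variational reconstruction

The estimate solves
$$\hat{\mathbf f} = \arg\min_{\mathbf f}
  \tfrac12\|\mathbf{T}\mathbf{H}\mathbf{f} - \mathbf{g}\|_2^2
  + \mu\, R(\mathbf{L}\mathbf{f}) + i_{\ge 0}(\mathbf f),$$
with $R(\mathbf L \cdot)$ one of

* **TV**: $\mathbf L = \nabla$ (periodic forward differences) with the
  $\ell_{2,1}$ mixed norm — piecewise-constant prior;
* **Hessian–Schatten (order 1)**: $\mathbf L$ the 3D Hessian with the
  per-voxel nuclear norm — piecewise-smooth prior that avoids the
  staircasing of TV.

Both operators are applied in 3D. Axial finite differences are divided
by the voxel aspect $\delta_z / \text{pixel}$ so a given physical slope
costs the same in every direction; without this, the 20 nm axial step
versus $\sim$107 nm pixels would make the penalty strongly anisotropic.
Off-diagonal Hessian entries are stored once but weighted by 2 in all
inner products, i.e. the penalty and the prox act on the true symmetric
matrix — eigenvalue soft-thresholding is then the exact nuclear-norm
prox.

## ADMM with direct subproblem solves

With auxiliary variables $u_1 = \mathbf{Hf}$, $u_2 = \mathbf{Lf}$,
$u_3 = \mathbf{f}$ and scaled duals, each iteration performs

1. **$u_1$**: per-pixel solve of
   $(\mathbf{T}^\top\mathbf{T} + \rho_1 I)\,u_1 =
   \mathbf{T}^\top g + \rho_1(\mathbf{Hf} + d_1)$ — one $N_z \times N_z$
   Cholesky factorization computed once and reused for every pixel and
   iteration;
2. **$u_2$**: the exact prox of $(\mu/\rho_2)$ times the mixed norm
   (group soft-threshold for TV, eigenvalue soft-threshold for
   Hessian–Schatten);
3. **$u_3$**: projection onto the nonnegative orthant;
4. **$f$**: exact solve of $(\rho_1 \mathbf{H}^\top\mathbf{H} +
   \rho_2 \mathbf{L}^\top\mathbf{L} + \rho_3 I)f = \text{rhs}$, diagonal
   in the 3D Fourier domain because $\mathbf H$ and $\mathbf L$ are
   periodic convolutions ($\rho_3 > 0$ guarantees invertibility; the
   eigenvalues are obtained by transforming the impulse response of the
   assembled operator, so they match the implemented stencils exactly);
5. dual ascent.

No step contains an inner iterative solver. The update order
(`u`-updates from the previous $f$, then $f$, then duals) is one of the
standard ADMM orderings; a long-run independent first-order solver is
used in the test suite to confirm the converged objective matches the
variational minimum to 0.1%.

Numerical choices: the background is subtracted from the data up front
(negative residuals kept, to avoid bias); with `normalize = TRUE`
(default) the subtracted data are scaled to peak 1, so unit penalties
$\rho_1 = \rho_2 = \rho_3 = 1$ are a serviceable default and $\mu$ is
quoted relative to peak-normalized data ($10^{-3}$–$10^{-1}$ is a
reasonable starting range; $\mu$ itself has deliberately no default).
The returned volume is the $u_3$ iterate — exactly nonnegative by
construction, whereas $f$ is only nonnegative in the limit. The lateral
grid is extended internally by the PSF half-width so the periodic
convolution cannot wrap structure across the boundary; the result is
cropped back. Stopping is a fixed iteration count (default 50) with an
optional early stop on the relative primal residual. The solver contains
no randomness: identical inputs give bit-identical outputs.

# Calibration with the spherical-lens phantom

A divergent lens of curvature radius $R$ resting on the coverslip over a
fluorescent liquid forms a gap
$t(r) = R - \sqrt{R^2 - r^2} \approx r^2/2R$; with $R = 288$ mm the gap
sweeps 0–500 nm over a fraction of a millimetre. Each pixel's
multi-angle curve is fit with the analytic top-hat (uniform slab) model
$$g_m = A\,\frac{I_0(\alpha_m)}{p_m}\,e^{-z_0 p_m}\,(1 - e^{-t\,p_m}),$$
(`slabIntensity`, computed with `expm1` for stability; the $p \to 0$
widefield limit is $A\,I_0\,t$). The fit is bounded Levenberg–Marquardt
least squares over $(t, A)$ — $z_0$ is fixed at 0 for the lens phantom,
where the liquid touches the coverslip — restarted from the
deterministic thickness grid $\{50, 150, 300\}$ nm with the amplitude
initialized at its least-squares projection, best residual kept:
reproducible without randomness. For calibrated cameras an optional IRLS
mode weights residuals by the model-predicted Poisson–Gaussian standard
deviation, the approximate maximum-likelihood estimator for
shot-noise-limited data; the lens-calibration pipeline uses it whenever
the noise model is known. Finally `fitLensRadius` restricts pixels to a
thickness window (default 100–400 nm, where the slab fit is most
reliable) and fits $t = r^2/2\hat R + c$.

## Study conditions of the built-in calibration simulation

`simulateLensCalibration` fixes the in-silico study design:

* **Angles**: 10 supercritical angles spaced uniformly in $p$ between
  $\alpha_c + 0.2^\circ$ and the aperture limit $-0.5^\circ$
  (61.6°–79.1°), giving penetration depths 59–477 nm. Uniform-in-$p$
  spacing samples the exponential depth weights evenly across the
  targeted 0–500 nm range; spacing uniform in angle would crowd the
  short penetration depths and leave almost no sensitivity beyond
  200 nm.
* **Geometry**: a lateral patch at the contact point with 5 µm virtual
  pixels (the gap varies slowly, and the fit uses the pure
  depth-weighting model, so no lateral PSF is applied); the generator
  voxelizes the slab on a fine 4 nm axial grid, deep enough to contain
  the thickest gap in view, and integrates the excitation exactly per
  slab. The fine generator grid keeps voxelization bias in the simulated
  curves below 1 nm — the reconstruction-side 20 nm step plays no role
  in generating the data.
* **Noise**: Poisson–Gaussian camera noise with the photon budget set so
  the brightest stack pixel has shot-noise SNR 30, plus Gaussian read
  noise ten times smaller; one seed drives the whole draw.

Under these conditions the noiseless pipeline recovers the lens radius
to better than 0.1% (inverse-crime regime: same forward physics, finite
sampling only), and noisy per-pixel thickness estimates track the true
gap within one 20 nm axial step typically up to roughly 400 nm. That
limit is not an implementation artifact: the Cramér–Rao bound for the
slab thickness at $t = 400$ nm under these conditions is $\approx 30$ nm
standard deviation, which corresponds to a median absolute error of
$0.674\,\sigma \approx 20$ nm — exactly the one-step criterion. The
measured tracking limit therefore fluctuates with the noise seed around
380–420 nm (occasionally lower), and deeper gaps cannot meet the
criterion at this SNR with any estimator.

# Synthetic data: what it emulates, and what it does not

The phantom generators cover laterally uniform or disjoint sheets
(axial-resolution tests; sub-step depths are split linearly between
bracketing slices so centroids are exact), filament-like tubes with
Gaussian lateral profiles (cytoskeleton-like scenes), and the lens gap
with partial-volume weighting of boundary slices. The noise model
emulates an EMCCD-like camera (shot noise plus read noise, clamped at
zero). Real acquisitions additionally contain angle-calibration errors,
polarization-dependent interface intensities, refractive-index
heterogeneity, spatially varying background, fixed-pattern noise and
drift — none of which are simulated. Passing tests therefore validate
the *numerics* (operators, solver, estimators) and the *identifiability*
of depth under the stated model, not robustness to those experimental
non-idealities.

# Depth statistics and rendering conventions

Mean depth per pixel is
$D_i = \mathrm{round}\!\big(\sum_j j\,R_{ij} / \sum_j R_{ij}\big)\,
\delta_z$ with 1-based slice index $j$ — values are multiples of
$\delta_z$ in $[\delta_z, N_z\delta_z]$. Rounding is half-away-from-zero
(documented because banker's rounding would flip bin assignment at exact
half-step centroids); pixels with zero axial mass are masked and
excluded from histograms (the accumulation loop is otherwise silent
about empty pixels). The relative-depth histogram accumulates
$\sqrt{(\sum_j R^1_{ij})(\sum_j R^2_{ij})}$ at $(D^1_i, D^2_i)$ over
pixels valid in both channels and is normalized so its maximum is
exactly 1. Rendering multiplies each slice by an isoluminant colormap
entry (a built-in blue-to-orange table, user-replaceable) and averages
along $z$; display scaling is a global scalar so hues are preserved.
Channel drift is the cross-correlation peak with separable parabolic
(log-parabolic where positive) interpolation.

# File formats

Stacks and volumes are multi-page TIFF (page order: ascending angle,
respectively ascending $z$ with page 1 at the coverslip). The TIFF
writer stores 32-bit samples normalized to the data range; the range,
angles, pixel size and grid geometry travel in a YAML sidecar, making
round trips accurate to $\sim 10^{-9}$ of the range. Plain TIFFs without
a sidecar (camera output) are read as raw counts. Angle lists are
one-column CSVs; run configuration is a validated YAML file in which
unknown keys are rejected by name and `regularizer.mu` is mandatory.

# Known limitations

* Single 2D PSF for all depths; no depth-varying or measured 3D PSF.
* Per-angle scalar background only.
* The angle-to-hardware mapping (galvanometer voltages, BFP images) is
  out of scope; angles are specified in degrees at the interface, with
  only the ideal sine-condition BFP-radius relation provided.
* No automatic selection of $\mu$ (L-curve/SURE) — the weight must be
  chosen by the user.
* The Hessian–Schatten prox eigendecomposes per voxel in R; on large
  grids TV is markedly faster.

# Problem sizes used in the shipped tests

Operator and prox identities run on random instances up to
$8 \times 8 \times 5$; solver–oracle comparisons on $6 \times 6 \times 4$
(TV, 4 angles); sheet-recovery on $16 \times 16 \times 20$ with 10
angles; the calibration pipeline on strips of a few hundred to a few
tens of thousands of virtual pixels. These sizes were chosen so the full
suite exercises every code path in a couple of minutes while remaining
far above the resolution of the assertions' tolerances.
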