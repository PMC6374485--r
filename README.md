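# matirf

Nanometric axial reconstruction from multi-angle TIRF (MA-TIRF) microscopy.

Total internal reflection fluorescence microscopy excites only a thin layer
above the coverslip: beyond the critical angle, the excitation decays with
depth as an evanescent wave, `I(z, α) = I0(α) e^{−z p(α)}`, where the
inverse penetration depth `p(α) = (4π/λ)·sqrt(n1² sin²α − n2²)` grows with
the incidence angle α. A single TIRF image is therefore depth-blind — but a
*stack* of images of the same field acquired at several supercritical
angles encodes the axial position of every fluorophore in its per-angle
intensity curve. `matirf` turns such stacks into quantitative 3D density
maps with axial detail far below the diffraction limit (tens of nm), for
studies of cell–substrate contacts, focal adhesions and the basal
cytoskeleton.

## What the package computes

**Forward model.** The acquisition at angle `α_m` is modeled as
`g_m = T H f + b`: the unknown nonnegative fluorophore density `f` on an
`Nxy × Nz` grid is blurred slice-by-slice with a single in-focus 2D PSF
(`H`), weighted in depth by the dense `M × Nz` matrix
`T[m, j] = I0(α_m) e^{−z_j p(α_m)} δz`, and offset by a spatially constant
per-angle background `b` (estimated from a structure-free region).

**Inverse problem.** The reconstruction solves

    f̂ = argmin_{f ≥ 0}  ½‖T H f − g‖² + μ R(L f)

where `R(L·)` is either the isotropic 3D total variation (ℓ2,1 norm of the
gradient) or the Hessian–Schatten norm of order 1 (per-voxel nuclear norm
of the 3×3 Hessian). The solver is an ADMM on the splitting `u1 = Hf`,
`u2 = Lf`, `u3 = f`; every subproblem is solved *exactly and directly* (no
inner iterations): a shared `Nz × Nz` Cholesky solve for the data term, a
closed-form prox (group soft-threshold or eigenvalue soft-threshold) for
the regularizer, a clip at zero for the constraint, and an FFT-diagonal
solve for `f`. Joint deconvolution can be toggled off by replacing `H`
with the identity.

**Calibration.** A divergent spherical lens (radius R = 288 mm) resting on
the coverslip over fluorescent liquid creates a gap of known thickness
`t(r) = R − sqrt(R² − r²)` (≈ 400 nm at r = 0.48 mm). Per-pixel top-hat
(uniform slab) fits of the multi-angle curves recover the local layer
thickness analytically (`g_m = A·I0/p_m·e^{−z0 p_m}(1 − e^{−t p_m})`), and
a parabolic fit of thickness versus radial distance returns the lens
radius — an end-to-end check of the whole model. All of this is
reproducible in silico via the built-in phantom generators.

**Post-processing.** Rounded intensity-weighted mean-depth maps,
relative-depth 2D histograms between channels (geometric-mean mass
weights, normalized to maximum 1), isoluminant color-coded depth
renderings, and subpixel channel-drift estimation by cross-correlation.

## Worked example

Two fluorescent sheets buried at 60 nm and 260 nm, imaged at 10 angles
chosen so the penetration depths (59–477 nm) sample the axial range
evenly, with camera noise; reconstructed with TV regularization:

```r
library(matirf)
cfg  <- opticalConfig()             # 491 nm, n1 = 1.515, n2 = 1.33, NA 1.49
aset <- angleDesign(cfg, 10)        # 61.59 ... 79.08 degrees
ex   <- excitationModel(cfg, aset)

grid <- gridSpec(16, 16, nz = 20)   # 0-380 nm in 20 nm steps
vol  <- sheetPhantom(c(60, 260), c(1, 1), grid, layout = "disjoint")
stk  <- simulateAcquisition(vol, ex, makePsf(cfg, "delta"), 0,
                            noiseSpec("gaussian", gaussian_sigma = 0.3,
                                      seed = 5))

Tz  <- buildTirfMatrix(ex, grid)
reg <- regularizerSpec("tv", mu = 3e-3, voxel_aspect = 20 / 107)
res <- admmReconstruct(stk, Tz, makePsf(cfg, "delta"), 0, reg,
                       solverOptions(n_iter = 400), grid = grid)

v  <- as.array(res@volume); zc <- zCenters(grid)
cen <- function(b) { p <- apply(b, 3, sum); sum(zc * p) / sum(p) }
cen(v[1:8, , ])    # 67.4  -- left sheet, truth 60 nm
cen(v[9:16, , ])   # 272.6 -- right sheet, truth 260 nm
```

Both centroids land within one axial step (20 nm) of the truth. The lens
calibration phantom round-trips the same way:

```r
sim <- simulateLensCalibration(nx = 110, ny = 4)        # noiseless strip
fit <- fitSlabPerPixel(sim$stack, sim$excitation)
fitLensRadius(fit@thickness_map, 5000)$radius_mm        # 288.07 (nominal 288)
```

## Command-line tool

`inst/cli/matirf` wraps the same functions for shell use:

```sh
Rscript inst/cli/matirf simulate      --config config.yml --phantom lens --output-dir out
Rscript inst/cli/matirf reconstruct   --config config.yml --input out/stack.tif --output-dir out
Rscript inst/cli/matirf fit-thickness --config config.yml --input out/stack.tif --output-dir out
Rscript inst/cli/matirf depthmap      --config config.yml --input out/reconstruction.tif
```

(see `inst/extdata/example_config.yml`; further commands: `fit-lens`,
`hist2d`, `render`, `drift`). Stacks and volumes are multi-page TIFF with
a YAML sidecar carrying the value range, angles and grid geometry.

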