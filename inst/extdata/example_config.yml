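# Example MA-TIRF run configuration.
# Units: nm for lengths, degrees for angles at the glass/sample interface.
optical:
  wavelength_nm: 491
  n_incident: 1.515
  n_sample: 1.33
  numerical_aperture: 1.49
  pixel_size_nm: 107
grid:
  nx: 32
  ny: 32
  nz: 20          # 0-380 nm in 20 nm steps, z = 0 at the coverslip
  dz_nm: 20
angles:
  values: [61.7, 62.2, 62.8, 63.6, 64.7, 66.1, 68.0, 70.4, 73.5, 78.0]
regularizer:
  kind: tv        # or hessian_schatten1
  mu: 0.01        # weight on peak-normalized data; no default
solver:
  n_iter: 50
  deconvolve: true
noise:              # used by `simulate` only
  model: poisson_gaussian
  gaussian_sigma: 0.01
  photon_scale: 1000
  seed: 1
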