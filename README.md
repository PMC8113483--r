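# mfmt

Simulation and reconstruction for **mesoscopic fluorescence molecular
tomography (MFMT)** — raster-scanned laminar optical tomography that
resolves fluorophore distributions 0.1–3 mm deep in scattering tissue at
~100–250 µm resolution. The package is aimed at people developing or
validating MFMT-style instruments and pipelines: it provides the digital
phantoms, photon-transport models, and the full inverse pipeline needed
to run closed-loop (simulate → reconstruct → quantify) studies entirely
in software, including the longitudinal tumor-burden workflow
(cell-count calibration, growth/regression time series).

## The model

A focused beam raster-scans the surface (default 41 × 41 positions at
0.25 mm pitch); for each position a 7 × 7 superpixel array (0.5 mm pitch)
records the diffuse fluorescence at varying source–detector separations,
which encode depth. Under the Born approximation the data are linear in
the voxelized fluorophore density *x*:

```
b = A x,   A[(s,d),v] = Gx(r_s → r_v) · Gm(r_v → r_d) · ΔV
```

with Green's functions from either a CPU Monte-Carlo random walk
(Henyey–Greenstein phase function, implicit capture, Russian roulette) or
the semi-infinite diffusion approximation with extrapolated boundary.
Reconstruction solves

```
min ‖A x − b‖₂² + λ‖x‖₁   subject to x ≥ 0
```

by FISTA, with λ initialized at the L-curve corner and fine-tuned by
maximizing the mutual information between the thresholded
reconstruction's maximum-intensity projection and the (gated)
center-detector image. The same MI scan provides an unbiased threshold
for volume and integrated-signal quantification, which a linear histology
calibration converts to absolute cell counts.

## Worked example

Two fluorescent beads, 1 mm apart at 750 µm depth, simulated and
reconstructed closed-loop:

```r
library(mfmt)

geom  <- scan_geometry(fov = c(3, 3), scan_step = 0.25)   # 13 x 13 raster
grid  <- voxel_grid(c(3, 3, 1.5), c(0.25, 0.25, 0.1))
A     <- assemble_jacobian(geom, grid, optical_properties())
scene <- make_bead_phantom(depth = 0.75, separation = 1, grid = grid)
scan  <- simulate_scan(scene, A, noise_level = 0.01, seed = 1)
fit   <- mfmt_reconstruct(scan, A)
summary(fit)
```

```
Reconstruction summary
  grid: 12 x 12 x 15 voxels; lambda = 0.001498 via l_curve + mi_fine_tune
  solver: 917 iterations, converged; objective 0.594654 (residual 0.3971, L1 291.7)
  preprocessing: median cut 0.01407, center-detector gate lower bound -0.2978
  thresholded: 22 voxels, integrated signal 291.1 a.u., volume 0.1375 mm^3
```

The summary reads: the regularization weight 0.0015 was chosen by the
L-curve corner and MI fine-tuning; the median raw-data cut and the
center-detector gate bound are the preprocessing constants; 22 voxels
(0.14 mm^3) survive the MI threshold and carry 291 a.u. of integrated
signal -- the quantity a calibration would convert to cells.

The fit is a classed object: `coef(fit)` is the reconstructed 3D density,
`fitted(fit)`/`residuals(fit)` live in measurement space,
`predict(fit, newdata = scene)` forward-projects a phantom,
`simulate(fit)` draws noisy measurement replicates, and `plot(fit)` shows
the thresholded MIP. Here the two beads reconstruct as two distinct
maxima 1 mm apart, with center-of-mass errors of ~0.18 mm laterally and
~0.02 mm axially — within one lateral and three axial voxels of truth
(see `bead_experiment()`, which packages this study).

Higher-level replication studies: `linearity_experiment()` (integrated
signal vs 100:10:1 tube concentrations; prints Pearson R),
`mi_threshold_experiment()` (MI threshold vs fixed-50% baseline), and
`make_tumor_series()` + `longitudinal_summary()` for growth/regression
time courses. A command-line front end (`inst/cli/mfmt.R`) exposes
`simulate`, `reconstruct`, `quantify`, `fixtures`, and `selfcheck`
subcommands over YAML run configs, writing TIFF volumes/scans with JSON
sidecars and checksummed manifests.

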