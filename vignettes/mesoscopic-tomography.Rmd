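---
title: "Mesoscopic fluorescence tomography: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscopic fluorescence tomography: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfmt)
```

# The measurement model

Mesoscopic fluorescence molecular tomography (MFMT) raster-scans a focused
excitation spot across the tissue surface while a camera records, for each
scan position, the multiply scattered fluorescence emerging around the
spot. Binned superpixels of that camera image act as detectors at a set of
lateral source-detector (S-D) separations; because photons collected
farther from the source have, on average, visited deeper tissue, the
detector array encodes depth. The default geometry in `scan_geometry()` is
a 10 x 10 mm field scanned at 0.25 mm pitch (41 x 41 positions) with a
7 x 7 superpixel array at 0.5 mm pitch. The zero-separation center
superpixel is excluded from the inversion data -- with it the array
contributes 48 detectors and the measurement vector has
41 x 41 x 48 = 80,688 entries -- but its image is retained, because the
least-diffused center-detector map is what the thresholding stages compare
against.

Under the Born approximation the expected measurement is linear in the
voxelized fluorophore density $x \ge 0$:

$$ b = A x, \qquad
   A_{(s,d),v} = G_x(r_s \to r_v)\, G_m(r_v \to r_d)\, \Delta V, $$

with $G_x$ the excitation fluence Green's function, $G_m$ the emission
Green's function obtained by reciprocity (launching from the detector
position), and $\Delta V$ the voxel volume. Excitation and emission share
one set of optical properties; at the wavelengths involved their
difference is a few percent, which is below every other error source in
the model. The slab is laterally homogeneous, so one transport solution
per unique relative offset suffices.

## Transport engines

Two engines provide the Green's functions.

The **Monte-Carlo engine** (`run_mc()`) is a voxelized random walk:
exponential step lengths at rate $\mu_t = \mu_s + \mu_a$,
Henyey-Greenstein deflections with anisotropy $g$, implicit capture
(weight multiplied by $\mu_s/\mu_t$ per interaction, the absorbed part
deposited in the current voxel) and Russian roulette below weight
$10^{-4}$ with survival probability 0.1. The top surface applies Fresnel
reflection when a refractive mismatch is configured; the default is
index-matched, reflecting imaging through a contacted coverslip that also
justifies the flat-boundary assumption. Each run records its seed and a
weight ledger (absorbed + reflected + transmitted = launched, up to
roulette noise below 0.5%).

The **diffusion engine** (`diffusion_green()`) is the steady-state
semi-infinite extrapolated-boundary solution
$$ G(r, r') = \frac{1}{4\pi D}\left[
   \frac{e^{-\mu_{\rm eff} r_1}}{r_1} -
   \frac{e^{-\mu_{\rm eff} r_2}}{r_2} \right],
   \qquad D = \frac{1}{3(\mu_a + \mu_s')},\quad
   \mu_{\rm eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}, $$
with the image source mirrored across the extrapolated boundary
$z = -2AD$ ($A = 1$ when index-matched) and surface pencils represented
as isotropic points at depth $z_0 = 1/(\mu_a + \mu_s')$. For the default
tissue values ($\mu_s = 20\,\mathrm{mm^{-1}}$,
$\mu_a = 0.1\,\mathrm{mm^{-1}}$, $g = 0.85$, so
$\mu_s' = 3\,\mathrm{mm^{-1}}$) the two engines agree to within a few
percent beyond one transport mean free path (1/3 mm); the closed form is
both the fast Jacobian engine and the independent oracle that the
Monte-Carlo tests check against. Near the source (< 1 mfp') the diffusion
approximation underestimates the singular ballistic contribution -- the
known breakdown regime -- which is why engine cross-checks exclude the
shallowest voxels.

# The inverse problem

Reconstruction minimizes
$$ \| A x - b \|_2^2 + \lambda \| x \|_1, \qquad x \ge 0 . $$
The L1 penalty matches the sparse, compact sources of interest (beads,
capillaries, early tumors); non-negativity is added because fluorophore
density is physical. Note the objective carries no 1/2 on the data term,
so the solution is exactly zero iff $\lambda \ge \max(2 A^\top b)$ -- the
tests rely on this closed-form switch-off point.

`solve_l1()` is FISTA: proximal gradient with Nesterov momentum, fixed
step $1/L$ where $L = 2\sigma_{\max}(A)^2$ comes from a deterministic
power iteration, and adaptive restart whenever the objective would rise,
so the stored objective trace is non-increasing and every solve is
bit-reproducible. For the over-determined systems the pipeline produces
(tens of thousands of measurements, thousands of voxels) the iteration is
run through the Gram system $A^\top A,\ A^\top b$: one symmetric
matrix-vector product per iteration, with the momentum point's product
formed from cached images of the last two iterates. $A^\top A$ does not
depend on the data, so regularization sweeps -- and repeated scans with
the same Jacobian -- reuse it.

## Choosing the regularization weight

An initial $\lambda$ comes from the L-curve: solve along a warm-started
path of candidates (default nine values log-spaced over
$10^{-4}..1 \times \lambda_{\max}$) and take the point of maximum
discrete curvature of $(\log_{10}\|Ax-b\|_2, \log_{10}\|x\|_1)$
parameterized by $\log_{10}\lambda$, three-point finite differences on
interior points, candidates with empty solutions excluded, collinear
curves falling back to the median candidate with a warning. The span
matters: at percent-level noise the informative bend of the curve is
where the residual hits the noise floor, around $10^{-4}..10^{-3}
\lambda_{\max}$ in our studies; a narrower span finds only the
sparsity-collapse elbow at large $\lambda$ and over-regularizes, which in
the bead study showed up directly as an axial localization bias.

The final choice is made by mutual information: for factors
$\{1/4, 1/2, 1, 2, 4\}$ times the L-curve value, reconstruct, run the
threshold scan below, and keep the $\lambda$ whose thresholded volume
attains the highest MI against the gated center-detector image, ties
breaking toward the initial value. This adapts to dataset-to-dataset
noise differences without user bias. Both stages are config-exposed; the
selection sweeps run at a looser tolerance (`search_tol = 1e-4`, capped
at 1000 iterations) than the warm-started final polish (`tol = 1e-6`,
`max_iter = 5000`).

# Post-processing

The pipeline order is fixed: median filter, center-detector gate,
reconstruction, MI threshold scan.

* **Median filter** (`median_noise_filter()`): every raw value strictly
  below the median over the measurement-vector data points is zeroed.
* **Center-detector gate** (`center_detector_gate()`): scan positions are
  kept where the center-detector image lies within
  $[\mathrm{mean} - 2\,\mathrm{SD}, \max]$ (population SD). This is an
  empirical rule against the diffuse halo; with different reporters or
  intensity ranges the factor would need revisiting.
* **MI threshold scan** (`mi_threshold_scan()`): 50 thresholds linearly
  spaced over the volume's range; at each, the maximum intensity
  projection of the thresholded volume is compared to the reference image
  by mutual information (joint histogram, 64 equal-width bins after
  min-max scaling, zero bins contributing nothing), and the argmax-MI
  threshold defines the final mask. The reference is the gated
  center-detector image resampled bilinearly to the MIP grid -- the most
  natural 2D fluorescence map; a sum over detectors or the full frame are
  defensible alternatives and the reference is therefore an argument, not
  a constant. A fixed fraction-of-maximum mask (`fixed_threshold()`) is
  provided only as the conventional baseline the MI scan is meant to
  replace.

# Quantification

`estimate_slice_cells()` implements the histology extrapolation
$C = C_{\rm sub} A_1 / A_2$ per slice and `tumor_total_cells()` sums
slices; the dominant uncertainty is density heterogeneity between counted
and extrapolated regions, and simulations with a two-fold density split
reproduce the expected ~30% bias. `fit_calibration()` is ordinary least
squares of cell count on thresholded integrated signal, reporting
R-squared and RMSE in the cell-count scale; with it,
`longitudinal_summary()` turns a series of reconstructions into per-day
cell counts and volumes normalized to the first acquisition (the natural
baseline for relative change). Per-voxel cell maps apportion the
intercept over the mask proportionally to signal so the map sums to the
calibrated total.

# The synthetic-data generator

`make_tube_phantom()`, `make_bead_phantom()` and `make_tumor_series()`
generate the study objects: fluorescein capillaries (0.5 mm inner radius,
length set by the ~3 uL volume, clipped to the reconstruction volume when
necessary) at 25/2.5/0.25 uM and 1.3 mm depth; paired 50 um beads at
750 um depth; and blob tumors (sums of Gaussian lobes thresholded at half
maximum, shapes jittered per timepoint under a fixed seed) whose
integrated cell count -- cells per voxel derived from a nominal 12.5 um
cell diameter, the midpoint of mammary tumor cell sizes -- rises
ten-fold over the induction phase and decays back after withdrawal.
Rasterization uses 5x supersampling on boundary voxels and conserves
analytic fluorophore mass to ~2% for bodies spanning three or more voxels
per axis; sub-voxel bodies deposit their full mass in one voxel, exactly.

The scattering phantom uses the same optical coefficients as tissue
unless overridden; the measured coefficients of a 10% Intralipid bath are
not part of the model and this default is a configuration convention, not
a physical claim. Simulated measurements add relative Gaussian noise
(default 1% SD per element, clipped at zero) or Poisson shot noise; the
generator does not emulate detector offsets/dark structure, tissue
heterogeneity, motion, or autofluorescence. Passing closed-loop tests
therefore demonstrates the internal consistency of the
simulate-reconstruct-quantify chain under the stated noise model -- not
performance on real tissue, where model mismatch (unknown optical
properties, heterogeneity) dominates.

# Study sizes and numerical choices

The replication studies are sized for a desk-scale CPU run and state
their grids explicitly:

* `linearity_experiment()`: 21 x 21 scan over 5 x 5 mm, 48 detectors,
  reconstruction volume 5 x 5 x 2 mm at 0.25 x 0.25 x 0.2 mm voxels
  (n = 4000; the axial pitch is twice the full-scale 0.1 mm default),
  1% noise, diffusion-engine Jacobian and Gram matrix shared across the
  three tubes, tightened corner search (the tubes are compared to each
  other, so all three runs must settle on the same L-curve feature; with
  it, the selected lambda scales exactly with tube signal and the
  integrated signals sit on the 100:10:1 line).
* `bead_experiment()`: 13 x 13 scan over 3 x 3 mm, volume
  3 x 3 x 1.5 mm at the full 0.25 x 0.25 x 0.1 mm voxel (n = 2160).
* `mi_threshold_experiment()`: same scan on isotropic 0.25 mm voxels
  (n = 864); its ground-truth voxel count is the majority-occupancy
  rasterization of the blob, i.e. its analytic volume up to quantization
  -- counting every partially-touched boundary voxel would overstate any
  body's volume by construction.
* Monte-Carlo verification uses 2-4 x 10^5 photons per source with
  batch-replicate standard errors; the full-scale Jacobian photon budget
  (10^6 per source by default) is a configuration knob, and any
  MC-engine Jacobian records its photon count and seed.

Other numerical conventions: voxel positions are centers, 0-based
physical coordinates with z into the tissue and x fastest in all
flattened vectors; Green's-function distances are clamped at half the
smallest voxel edge to avoid the singularity when the effective source
depth coincides with a voxel center; degenerate inputs (zero-variance
gate images, collinear L-curves, all-zero reconstructions) warn or error
rather than silently proceeding.

# Known limitations

* Depth localization degrades as lambda grows; the MI criterion compares
  2D projections and cannot see depth, so regularization beyond the
  noise-floor corner biases reconstructions shallow. The wide default
  candidate span exists precisely to anchor the corner correctly.
* The integrated L1 signal is shrunk in proportion to lambda, so
  cross-dataset comparability (calibration, time courses) requires the
  corner search to land on the same L-curve feature for every dataset.
  The discrete-curvature corner is sensitive to how well the small-lambda
  end of the path has converged: longitudinal studies should tighten the
  search (`search_tol = 1e-5`, `search_max_iter = 4000`, affordable at
  their problem sizes), which in our ten-fold growth/regression loop
  keeps per-timepoint signal-per-cell constant to a few percent and
  recovers the growth ratio within ten percent.
* Absolute radiometry is out of scope -- all signals are relative, and
  quantum yield, collection efficiency and camera gain are absorbed into
  the cell-count calibration.
* The Jacobian assumes a homogeneous slab; per-voxel optical properties
  and depth-compensating row weights are not implemented.
* Absolute thresholded volumes depend on the threshold rule; time-course
  ratios are the robust quantity.
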