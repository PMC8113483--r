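#' Fluorescent inclusion inside a slab phantom
#'
#' An inclusion is a geometric body carrying a uniform fluorophore density
#' (arbitrary units per mm^3; cells per mm^3 for tumor blobs). Supported
#' shapes: `sphere` (radius), `cylinder` (radius + length, axis along y),
#' and `blob` (a sum of 3D Gaussian lobes thresholded at half of its
#' maximum, giving an irregular compact body).
#'
#' @param shape One of `"sphere"`, `"cylinder"`, `"blob"`.
#' @param center Center `c(x, y, z)` in mm.
#' @param radius Radius in mm (sphere, cylinder).
#' @param length Cylinder length in mm (axis along y).
#' @param density Fluorophore density (a.u. per mm^3), >= 0.
#' @param lobes For blobs: a matrix with columns `x, y, z, sigma, amp`, one
#'   Gaussian lobe per row.
#' @return An object of class `mfmt_inclusion`.
#' @export
inclusion <- function(shape = c("sphere", "cylinder", "blob"), center,
                      radius = NULL, length = NULL, density = 1,
                      lobes = NULL) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 3L, is.numeric(density), density >= 0)
  if (shape %in% c("sphere", "cylinder")) {
    stopifnot(is.numeric(radius), radius > 0)
    if (shape == "cylinder") stopifnot(is.numeric(length), length > 0)
  }
  if (shape == "blob") {
    stopifnot(is.matrix(lobes), ncol(lobes) == 5L, nrow(lobes) >= 1L)
    colnames(lobes) <- c("x", "y", "z", "sigma", "amp")
  }
  structure(list(shape = shape, center = as.numeric(center), radius = radius,
                 length = length, density = density, lobes = lobes),
            class = "mfmt_inclusion")
}

# Axis-aligned bounding box of an inclusion (mm).
inclusion_bbox <- function(inc) {
  c0 <- inc$center
  switch(inc$shape,
    sphere = rbind(c0 - inc$radius, c0 + inc$radius),
    cylinder = rbind(c0 - c(inc$radius, inc$length / 2, inc$radius),
                     c0 + c(inc$radius, inc$length / 2, inc$radius)),
    blob = {
      # half-maximum thresholding keeps the support well inside 2 sigma
      r <- 2 * inc$lobes[, "sigma"]
      rbind(apply(inc$lobes[, 1:3, drop = FALSE] - r, 2, min),
            apply(inc$lobes[, 1:3, drop = FALSE] + r, 2, max))
    })
}

# Analytic integral of density over the inclusion volume (a.u.).
# Blobs have no closed form; their integral is taken on a fine subgrid.
inclusion_integral <- function(inc) {
  switch(inc$shape,
    sphere = inc$density * 4 / 3 * pi * inc$radius^3,
    cylinder = inc$density * pi * inc$radius^2 * inc$length,
    blob = NA_real_)
}

#' Digital slab phantom
#'
#' A homogeneous optical slab of given thickness carrying a set of
#' fluorescent inclusions, together with the voxel grid on which its
#' ground-truth fluorophore map is rasterized. Every inclusion must be fully
#' contained in the slab and within the grid's lateral extent.
#'
#' @param props [optical_properties()] of the slab.
#' @param thickness Slab thickness (mm), >= grid z extent.
#' @param grid A [voxel_grid()].
#' @param inclusions List of [inclusion()] objects.
#' @param label Free-text description.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(props = optical_properties(), thickness = NULL,
                          grid, inclusions = list(), label = "") {
  stopifnot(inherits(props, "optical_properties"), inherits(grid, "voxel_grid"))
  if (is.null(thickness)) thickness <- grid$extent[3]
  stopifnot(thickness >= grid$extent[3])
  for (inc in inclusions) {
    stopifnot(inherits(inc, "mfmt_inclusion"))
    bb <- inclusion_bbox(inc)
    if (bb[1, 3] < -1e-9 || bb[2, 3] > thickness + 1e-9)
      stop("inclusion extends outside the slab (z range ",
           signif(bb[1, 3], 3), "..", signif(bb[2, 3], 3),
           " mm, slab thickness ", thickness, " mm)")
    if (any(bb[1, 1:2] < -1e-9) || any(bb[2, 1:2] > grid$extent[1:2] + 1e-9))
      stop("inclusion extends laterally outside the reconstruction volume")
  }
  structure(list(props = props, thickness = thickness, grid = grid,
                 inclusions = inclusions, label = label),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("Phantom scene '%s': %d inclusion(s) in a %g mm slab\n",
              x$label, length(x$inclusions), x$thickness))
  print(x$props)
  print(x$grid)
  invisible(x)
}

# Evaluate a blob's density field at points (n x 3 matrix): sum of Gaussian
# lobes, thresholded at half of the blob's peak amplitude (compact support).
blob_density_at <- function(inc, pts) {
  f <- numeric(nrow(pts))
  for (k in seq_len(nrow(inc$lobes))) {
    lb <- inc$lobes[k, ]
    d2 <- (pts[, 1] - lb["x"])^2 + (pts[, 2] - lb["y"])^2 + (pts[, 3] - lb["z"])^2
    f <- f + lb["amp"] * exp(-d2 / (2 * lb["sigma"]^2))
  }
  peak <- sum(inc$lobes[, "amp"])  # upper bound attained near lobe overlap
  ifelse(f >= peak / 2, inc$density * f / peak, 0)
}

#' Rasterize a phantom scene to its ground-truth fluorophore map
#'
#' Produces the 3D fluorophore density map (a.u. per mm^3) on the scene's
#' voxel grid. Voxels overlapping an inclusion boundary are resolved by
#' regular supersampling (`ss^3` subsamples per voxel); inclusions smaller
#' than a voxel deposit their full analytic integral into the containing
#' voxel so that total fluorophore mass is conserved.
#'
#' @param scene A [phantom_scene()].
#' @param ss Supersampling factor per axis (default 5).
#' @return A numeric array of dim `c(nx, ny, nz)`.
#' @export
rasterize_scene <- function(scene, ss = 5L) {
  stopifnot(inherits(scene, "phantom_scene"))
  g <- scene$grid
  vol <- array(0, dim = c(g$nx, g$ny, g$nz))
  for (inc in scene$inclusions) {
    if (inc$density == 0) next
    if (inc$shape != "blob" &&
        all(inclusion_bbox(inc)[2, ] - inclusion_bbox(inc)[1, ] <
            g$voxel_size)) {
      # sub-voxel inclusion: point deposition, exact conservation
      idx <- pmin(pmax(ceiling(inc$center / g$voxel_size), 1L),
                  c(g$nx, g$ny, g$nz))
      vol[idx[1], idx[2], idx[3]] <- vol[idx[1], idx[2], idx[3]] +
        inclusion_integral(inc) / g$voxel_volume
      next
    }
    bb <- inclusion_bbox(inc)
    i0 <- pmax(floor(bb[1, ] / g$voxel_size) + 1, 1)
    i1 <- pmin(ceiling(bb[2, ] / g$voxel_size), c(g$nx, g$ny, g$nz))
    sub <- (seq_len(ss) - 0.5) / ss  # subcell centers in [0,1]
    for (iz in i0[3]:i1[3]) for (iy in i0[2]:i1[2]) {
      xs <- rep((i0[1]:i1[1] - 1) * g$voxel_size[1], each = ss) +
        rep(sub * g$voxel_size[1], times = i1[1] - i0[1] + 1)
      nsx <- length(xs)
      ys <- (iy - 1 + sub) * g$voxel_size[2]
      zs <- (iz - 1 + sub) * g$voxel_size[3]
      pts <- cbind(rep(xs, times = ss * ss),
                   rep(rep(ys, each = nsx), times = ss),
                   rep(zs, each = nsx * ss))
      d <- switch(inc$shape,
        sphere = ifelse(rowSums(sweep(pts, 2, inc$center)^2) <= inc$radius^2,
                        inc$density, 0),
        cylinder = ifelse((pts[, 1] - inc$center[1])^2 +
                            (pts[, 3] - inc$center[3])^2 <= inc$radius^2 &
                          abs(pts[, 2] - inc$center[2]) <= inc$length / 2,
                          inc$density, 0),
        blob = blob_density_at(inc, pts))
      m <- matrix(d, nrow = nsx)  # rows: x-subsamples, cols: (y,z) subsamples
      frac <- rowsum(rowMeans(m), rep(i0[1]:i1[1], each = ss)) / ss
      vol[i0[1]:i1[1], iy, iz] <- vol[i0[1]:i1[1], iy, iz] + frac
    }
  }
  vol
}

#' Two-bead resolution phantom
#'
#' Two point-like fluorescent microspheres at a common depth, laterally
#' separated along x and centered in the field of view -- the standard
#' fixture for characterizing the tomographic point-spread function. The
#' defaults reproduce 50 um beads at ~750 um depth. Each bead carries unit
#' total fluorophore mass; at zero separation the beads merge into a single
#' source of doubled mass.
#'
#' @param depth Bead depth (mm), default 0.75.
#' @param diameter Bead diameter in um, default 50.
#' @param separation Lateral center-to-center separation (mm), default 1.
#' @param grid A [voxel_grid()] (default 5 x 5 x 2 mm at 0.25/0.25/0.1 mm).
#' @param props Slab [optical_properties()].
#' @return A [phantom_scene()]; its ground-truth map comes from
#'   [rasterize_scene()].
#' @export
make_bead_phantom <- function(depth = 0.75, diameter = 50, separation = 1,
                              grid = voxel_grid(c(5, 5, 2)),
                              props = optical_properties()) {
  stopifnot(depth > 0, diameter > 0, separation >= 0)
  r <- diameter / 2000  # um -> mm radius
  if (depth + r > grid$extent[3])
    stop("bead at depth ", depth, " mm lies outside the ", grid$extent[3],
         " mm volume")
  cx <- grid$extent[1] / 2
  cy <- grid$extent[2] / 2
  unit_density <- 1 / (4 / 3 * pi * r^3)  # unit total mass per bead
  incs <- if (separation == 0) {
    list(inclusion("sphere", c(cx, cy, depth), radius = r,
                   density = 2 * unit_density))
  } else {
    list(inclusion("sphere", c(cx - separation / 2, cy, depth), radius = r,
                   density = unit_density),
         inclusion("sphere", c(cx + separation / 2, cy, depth), radius = r,
                   density = unit_density))
  }
  phantom_scene(props = props, grid = grid, inclusions = incs,
                label = sprintf("beads d=%gum z=%gmm sep=%gmm",
                                diameter, depth, separation))
}

#' Fluorescein capillary-tube phantom
#'
#' A glass capillary (cylinder along y, ~3 uL volume realized as a 0.5 mm
#' inner-radius tube) filled with fluorescein at the given concentration,
#' placed at the given depth in a scattering slab -- the linearity fixture.
#' Fluorophore density is proportional to concentration; the reference
#' series uses 25, 2.5 and 0.25 uM at 1.3 mm depth.
#'
#' @param concentration Fluorescein concentration in uM, >= 0.
#' @param depth Tube axis depth (mm), default 1.3.
#' @param grid A [voxel_grid()] (default 5 x 5 x 2 mm).
#' @param props Slab [optical_properties()]; the Intralipid phantom defaults
#'   to the tissue values.
#' @param volume_uL Tube volume in uL (default 3); sets the tube length.
#' @param radius Tube inner radius (mm), default 0.5.
#' @return A [phantom_scene()].
#' @export
make_tube_phantom <- function(concentration, depth = 1.3,
                              grid = voxel_grid(c(5, 5, 2)),
                              props = optical_properties(),
                              volume_uL = 3, radius = 0.5) {
  stopifnot(concentration >= 0, depth > 0)
  len <- volume_uL / (pi * radius^2)  # uL = mm^3
  len <- min(len, grid$extent[2] - 2 * radius)  # keep inside the volume
  cx <- grid$extent[1] / 2
  cy <- grid$extent[2] / 2
  incs <- if (concentration > 0) {
    list(inclusion("cylinder", c(cx, cy, depth), radius = radius,
                   length = len, density = concentration))
  } else list()
  phantom_scene(props = props, grid = grid, inclusions = incs,
                label = sprintf("fluorescein tube %guM z=%gmm",
                                concentration, depth))
}

#' Longitudinal tumor-growth/regression series
#'
#' Emulates an inducible-oncogene experiment: a blob-shaped tumor whose true
#' cell count rises `growth_fold`-fold over the induction (DoX-on) phase and
#' decays back to baseline after withdrawal (DoX-off). The blob is a sum of
#' Gaussian lobes thresholded at half maximum, its shape perturbed
#' stochastically at each timepoint; densities are scaled so the integrated
#' count matches the prescribed trajectory exactly. Cells per voxel derive
#' from a nominal 12.5 um diameter cell.
#'
#' @param growth_fold Peak/baseline cell-count ratio, > 0 (default 10).
#' @param n_timepoints Number of acquisitions, >= 2 (default 6).
#' @param seed Integer RNG seed; the series regenerates bit-identically.
#' @param baseline_cells True count at the first timepoint (default 1e5,
#'   a small but detectable tumor).
#' @param grid A [voxel_grid()].
#' @param props Slab [optical_properties()].
#' @param depth Tumor center depth (mm), default 1.
#' @return An object of class `tumor_time_series`: a list of records with
#'   `day`, `scene`, `true_cell_count`, `dox_state`, plus the nominal
#'   `cell_volume` (mm^3).
#' @export
make_tumor_series <- function(growth_fold = 10, n_timepoints = 6, seed = 1,
                              baseline_cells = 1e5,
                              grid = voxel_grid(c(5, 5, 2)),
                              props = optical_properties(), depth = 1) {
  stopifnot(growth_fold > 0, n_timepoints >= 2)
  set.seed(seed)
  n_on <- ceiling(n_timepoints / 2)
  days <- round(seq(0, 7 * (n_timepoints - 1), length.out = n_timepoints))
  # log-linear growth to peak during DoX-on, decay back to baseline after
  counts <- c(exp(seq(log(baseline_cells), log(baseline_cells * growth_fold),
                      length.out = n_on)),
              if (n_timepoints > n_on)
                exp(seq(log(baseline_cells * growth_fold), log(baseline_cells),
                        length.out = n_timepoints - n_on + 1))[-1])
  cell_volume <- 4 / 3 * pi * (12.5 / 2000)^3  # 12.5 um diameter cell, mm^3
  cx <- grid$extent[1] / 2
  cy <- grid$extent[2] / 2
  records <- vector("list", n_timepoints)
  for (t in seq_len(n_timepoints)) {
    n_lobes <- 3L
    lobes <- cbind(
      x = cx + stats::rnorm(n_lobes, 0, 0.12),
      y = cy + stats::rnorm(n_lobes, 0, 0.12),
      z = depth + stats::rnorm(n_lobes, 0, 0.06),
      sigma = stats::runif(n_lobes, 0.25, 0.35),
      amp = stats::runif(n_lobes, 0.7, 1))
    inc <- inclusion("blob", center = c(cx, cy, depth), density = 1,
                     lobes = lobes)
    scene <- phantom_scene(props = props, grid = grid, inclusions = list(inc),
                           label = sprintf("tumor day %d", days[t]))
    vol <- rasterize_scene(scene, ss = 2L)
    raw_cells <- sum(vol) * grid$voxel_volume / cell_volume
    inc$density <- counts[t] / raw_cells  # scale to the prescribed count
    scene$inclusions <- list(inc)
    records[[t]] <- list(day = days[t], scene = scene,
                         true_cell_count = counts[t],
                         dox_state = if (t <= n_on) "on" else "off")
  }
  structure(list(records = records, cell_volume = cell_volume,
                 growth_fold = growth_fold, seed = seed),
            class = "tumor_time_series")
}

#' @export
print.tumor_time_series <- function(x, ...) {
  cat(sprintf("Tumor time series: %d timepoints, %g-fold growth (seed %d)\n",
              length(x$records), x$growth_fold, x$seed))
  for (r in x$records)
    cat(sprintf("  day %3d  DoX %-3s  %.3g cells\n",
                r$day, r$dox_state, r$true_cell_count))
  invisible(x)
}

#' Cells per voxel of a rasterized tumor map
#'
#' Converts a fluorophore-density map (a.u. per mm^3, with densities in
#' cell-packing units) to cells per voxel:
#' `cells = density * voxel_volume / cell_volume`.
#'
#' @param density_map 3D density array from [rasterize_scene()].
#' @param grid The matching [voxel_grid()].
#' @param cell_volume Nominal single-cell volume (mm^3); default from a
#'   12.5 um diameter.
#' @return Array of cells per voxel.
#' @export
cells_per_voxel <- function(density_map, grid,
                            cell_volume = 4 / 3 * pi * (12.5 / 2000)^3) {
  density_map * grid$voxel_volume / cell_volume
}
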