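#' Assemble the Born-linear Jacobian (sensitivity) matrix
#'
#' Builds the `m x n` model matrix `A` linking voxel fluorophore density to
#' detector readings under the Born approximation:
#' `A[(s,d), v] = G_x(r_s -> r_v) * G_m(r_v -> r_d) * voxel_volume`,
#' where the emission Green's function is obtained by reciprocity
#' (launching from the detector position). Rows are kept for every
#' superpixel whose source-detector separation is within the geometry's
#' limit -- including the zero-separation center detector, which is used for
#' simulation and gating but flagged out of the inversion measurement
#' vector.
#'
#' Two engines are available: `"diffusion"` evaluates the semi-infinite
#' extrapolated-boundary Green's function in closed form (fast, the
#' default); `"mc"` runs one Monte-Carlo transport simulation and exploits
#' the lateral translation invariance of the homogeneous slab, so a single
#' fluence map serves all sources and detectors.
#'
#' Row ordering: `row = (s - 1) * n_det + d` with sources in raster order
#' (x fastest) and detectors in array order (detector x fastest); this is
#' the same flattening rule as [flatten_scan()].
#'
#' @param geometry A [scan_geometry()].
#' @param grid A [voxel_grid()].
#' @param props [optical_properties()] of the slab.
#' @param engine `"diffusion"` or `"mc"`.
#' @param photons Photon budget for the `"mc"` engine (default 1e6).
#' @param seed Seed for the `"mc"` engine.
#' @param thickness Slab thickness for the `"mc"` engine (default: grid
#'   depth + 1 mm of backing tissue).
#' @return An object of class `jacobian_model`: `matrix` (dense rows for
#'   the included detectors, [measurement_size()] of them),
#'   `excluded_matrix` (rows for the kept-but-excluded detectors, i.e. the
#'   center superpixel), `offsets` (kept detector offsets with their
#'   `included` flag), `geometry`, `grid`, and provenance fields. The two
#'   matrices are kept apart so the inversion works on `matrix` directly,
#'   without subsetting a multi-gigabyte copy.
#' @export
assemble_jacobian <- function(geometry, grid, props = optical_properties(),
                              engine = c("diffusion", "mc"),
                              photons = 1e6, seed = 1, thickness = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(geometry, "scan_geometry"), inherits(grid, "voxel_grid"),
            inherits(props, "optical_properties"))
  if (grid$extent[3] > grid$max_depth + 1e-12)
    stop("grid exceeds the maximum reconstruction depth")
  sources <- build_scan_grid(geometry$fov, geometry$scan_step)
  off <- detector_offsets(geometry)
  keep <- off$separation <= geometry$max_sd_separation + 1e-12
  if (any(!keep))
    message(sum(!keep), " detector(s) beyond the ", geometry$max_sd_separation,
            " mm source-detector separation limit excluded from the model")
  off_kept <- off[keep, , drop = FALSE]
  musp <- reduced_scattering(props)
  mut <- props$mu_a + musp
  if (engine == "diffusion") {
    D <- 1 / (3 * mut)
    mueff <- sqrt(3 * props$mu_a * mut)
    parts <- cpp_diffusion_jacobian(sources,
                                    as.matrix(off_kept[, c("dx", "dy")]),
                                    off_kept$included,
                                    grid$xc, grid$yc, grid$zc,
                                    D, mueff, 1 / mut, 2 * D,
                                    grid$voxel_volume,
                                    min(grid$voxel_size) / 2)
  } else {
    parts <- mc_jacobian_matrix(sources, off_kept, grid, props, photons,
                                seed, thickness)
  }
  structure(list(matrix = parts$included, excluded_matrix = parts$excluded,
                 geometry = geometry, grid = grid, props = props,
                 offsets = off_kept, engine = engine,
                 photons = if (engine == "mc") photons else NA,
                 seed = if (engine == "mc") seed else NA),
            class = "jacobian_model")
}

# Monte-Carlo engine: one fluence map on an extended grid whose lateral
# voxel centers sit at +/-(pitch/2 + k*pitch) around the source, so every
# (voxel - source) and (voxel - detector) displacement arising from the
# raster (sources on the voxel-corner lattice, detector offsets multiples
# of the pitch) hits a map voxel center exactly. Valid for laterally
# homogeneous slabs only.
mc_jacobian_matrix <- function(sources, off_kept, grid, props, photons, seed,
                               thickness) {
  dx <- grid$voxel_size[1]; dy <- grid$voxel_size[2]
  if (abs(dx - dy) > 1e-12)
    stop("mc engine requires square lateral voxels")
  step_ok <- function(v) all(abs(v / dx - round(v / dx)) < 1e-9)
  if (!step_ok(sources[, 1]) || !step_ok(sources[, 2]) ||
      !step_ok(off_kept$dx) || !step_ok(off_kept$dy))
    stop("mc engine requires scan positions and detector offsets on the ",
         "lateral voxel lattice")
  if (is.null(thickness)) thickness <- grid$extent[3] + 1
  max_disp <- max(grid$extent[1:2]) +
    max(abs(c(off_kept$dx, off_kept$dy, 0)))
  K <- ceiling(max_disp / dx) + 1L
  nxe <- 2L * K
  ext_grid <- voxel_grid(c(nxe * dx, nxe * dy, grid$extent[3]),
                         c(dx, dy, grid$voxel_size[3]),
                         max_depth = grid$extent[3])
  scene <- phantom_scene(props = props, thickness = thickness, grid = ext_grid)
  fm <- run_mc(scene, source = c(K * dx, K * dy), photons = photons,
               seed = seed)
  phi <- fm$values
  # index of displacement d (multiple of dx/2 on the half-offset lattice)
  lk <- function(disp) {
    i <- round((K * dx + disp) / dx + 0.5)
    if (any(i < 1 | i > nxe)) stop("displacement outside extended map")
    i
  }
  n <- grid$n
  nd_in <- sum(off_kept$included)
  nd_ex <- sum(!off_kept$included)
  A <- matrix(0, nrow(sources) * nd_in, n)
  E <- matrix(0, nrow(sources) * nd_ex, n)
  for (s in seq_len(nrow(sources))) {
    gx <- phi[lk(grid$xc - sources[s, 1]), lk(grid$yc - sources[s, 2]), ,
              drop = FALSE]
    di <- de <- 0
    for (d in seq_len(nrow(off_kept))) {
      gm <- phi[lk(grid$xc - sources[s, 1] - off_kept$dx[d]),
                lk(grid$yc - sources[s, 2] - off_kept$dy[d]), , drop = FALSE]
      row <- as.vector(gx) * as.vector(gm) * grid$voxel_volume
      if (off_kept$included[d]) {
        di <- di + 1
        A[(s - 1) * nd_in + di, ] <- row
      } else {
        de <- de + 1
        E[(s - 1) * nd_ex + de, ] <- row
      }
    }
  }
  list(included = A, excluded = E)
}

#' @export
print.jacobian_model <- function(x, ...) {
  cat(sprintf(
    "Jacobian model (%s engine): %d inversion rows + %d excluded-detector rows x %d voxels\n",
    x$engine, nrow(x$matrix), nrow(x$excluded_matrix), ncol(x$matrix)))
  invisible(x)
}

#' Forward projection of a fluorophore map
#'
#' Computes the noiseless measurement vector `b = A x` for a fluorophore
#' density map `x` on the Jacobian's voxel grid. Exactly linear by
#' construction.
#'
#' @param A A [assemble_jacobian()] model.
#' @param x Fluorophore map: 3D array on `A$grid` or a flat vector of
#'   length `A$grid$n` (x fastest, then y, then z).
#' @return Numeric vector over all kept detectors (length
#'   `n_scan * n_det_kept`, in [flatten_scan()] order with
#'   `included_only = FALSE`).
#' @export
forward_project <- function(A, x) {
  stopifnot(inherits(A, "jacobian_model"))
  if (is.array(x) && length(dim(x)) == 3L) {
    if (!all(dim(x) == c(A$grid$nx, A$grid$ny, A$grid$nz)))
      stop("fluorophore map dimensions ", paste(dim(x), collapse = "x"),
           " do not match the Jacobian grid ",
           paste(c(A$grid$nx, A$grid$ny, A$grid$nz), collapse = "x"))
    x <- as.vector(x)
  }
  if (length(x) != ncol(A$matrix))
    stop("fluorophore vector length ", length(x),
         " does not match the Jacobian (", ncol(A$matrix), " voxels)")
  if (any(x < 0)) stop("fluorophore density must be non-negative")
  off <- A$offsets
  nd <- nrow(off)
  ns <- nrow(A$matrix) / max(sum(off$included), 1L)
  out <- matrix(0, nd, ns)
  if (any(off$included))
    out[off$included, ] <- matrix(drop(A$matrix %*% x),
                                  sum(off$included), ns)
  if (any(!off$included))
    out[!off$included, ] <- matrix(drop(A$excluded_matrix %*% x),
                                   sum(!off$included), ns)
  as.vector(out)
}

#' Add measurement noise to a projection
#'
#' `gaussian_relative` adds independent zero-mean Gaussian noise with
#' standard deviation `level * b_i` per element (clipped at zero);
#' `shot` draws Poisson counts at an expected `level` counts per unit
#' signal and rescales, emulating photon shot noise.
#'
#' @param b Noiseless measurement vector, >= 0.
#' @param model `"gaussian_relative"` or `"shot"`.
#' @param level Noise level: relative SD for `gaussian_relative`; counts
#'   per unit signal for `shot`.
#' @param seed Integer seed.
#' @return Noisy vector, same length, non-negative.
#' @export
add_noise <- function(b, model = "gaussian_relative", level = 0.01, seed = 1) {
  stopifnot(is.numeric(b), level >= 0)
  if (!model %in% c("gaussian_relative", "shot"))
    stop("unknown noise model '", model, "'")
  if (level == 0) return(b)
  set.seed(seed)
  if (model == "gaussian_relative") {
    pmax(b + stats::rnorm(length(b), 0, level * b), 0)
  } else {
    stats::rpois(length(b), b * level) / level
  }
}

#' Raw scan container
#'
#' Wraps the measurement array of a raster scan as
#' `data[ix, iy, d]`: the reading of kept detector `d` (array order,
#' detector x fastest; see [detector_offsets()]) at scan position
#' `(ix, iy)`. When all superpixels are within the separation limit this is
#' a reshaped view of the 4D (scan x scan x detector-grid) array, available
#' via [as_detector_array()]. The center detector is part of the raw data
#' even though it is excluded from the inversion vector.
#'
#' @param data 3D numeric array `(n_scan_x, n_scan_y, n_det_kept)`.
#' @param geometry The [scan_geometry()].
#' @param power Excitation power the data were acquired at (mW), default 1.
#' @param meta Free-form metadata list.
#' @return An object of class `raw_scan`.
#' @export
raw_scan <- function(data, geometry, power = 1, meta = list()) {
  stopifnot(inherits(geometry, "scan_geometry"))
  off <- detector_offsets(geometry)
  nd_kept <- sum(off$separation <= geometry$max_sd_separation + 1e-12)
  if (length(dim(data)) == 3L) {
    stopifnot(dim(data)[3] == nd_kept)
  } else stop("data must be a 3D array (scan_x, scan_y, detector)")
  if (any(data < 0)) stop("intensities must be non-negative")
  structure(list(data = data, geometry = geometry, power = power,
                 meta = meta), class = "raw_scan")
}

#' @export
print.raw_scan <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Raw scan: %d x %d positions x %d detectors (power %g mW)\n",
              d[1], d[2], d[3], x$power))
  invisible(x)
}

#' Flatten a raw scan to the measurement vector
#'
#' The single documented flattening rule: element
#' `(s - 1) * n_det + d` of the output is detector `d` at scan position
#' `s`, with `s = ix + (iy - 1) * n_scan_x` (x fastest) and `d` running
#' over detector offsets in array order. With `included_only = TRUE`
#' (the inversion convention) the excluded detectors -- the zero-separation
#' center superpixel by default -- are dropped, giving a vector of length
#' [measurement_size()].
#'
#' @param scan A [raw_scan()].
#' @param included_only Drop excluded detectors (default `TRUE`).
#' @return Numeric vector.
#' @seealso [unflatten_scan()] for the exact inverse.
#' @export
flatten_scan <- function(scan, included_only = TRUE) {
  stopifnot(inherits(scan, "raw_scan"))
  d <- dim(scan$data)
  # permute to (detector, scan_x, scan_y) then flatten: detector fastest
  v <- as.vector(aperm(scan$data, c(3, 1, 2)))
  if (included_only) {
    off <- kept_offsets(scan$geometry)
    v <- v[rep(off$included, times = d[1] * d[2])]
  }
  v
}

#' Rebuild the 3D raw-scan array from a flattened vector
#'
#' Exact inverse of [flatten_scan()] for the full (all kept detectors)
#' vector.
#'
#' @param b Flat vector of length `n_scan * n_det_kept`.
#' @param geometry The [scan_geometry()].
#' @return 3D array `(n_scan_x, n_scan_y, n_det_kept)`.
#' @export
unflatten_scan <- function(b, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  nd <- nrow(kept_offsets(geometry))
  nsx <- geometry$n_scan_x; nsy <- geometry$n_scan_y
  if (length(b) != nd * nsx * nsy)
    stop("vector length ", length(b), " does not match geometry (",
         nd * nsx * nsy, ")")
  aperm(array(b, dim = c(nd, nsx, nsy)), c(2, 3, 1))
}

# Detector offsets within the separation limit (the modeled superpixels).
kept_offsets <- function(geometry) {
  off <- detector_offsets(geometry)
  off[off$separation <= geometry$max_sd_separation + 1e-12, , drop = FALSE]
}

#' Normalize a raw scan by excitation power
#'
#' Divides all intensities by the excitation power (mW) so scans acquired
#' at different powers (1-5 mW in the reference protocol) become
#' comparable; the stored power is reset to 1.
#'
#' @param scan A [raw_scan()].
#' @param power Excitation power (mW), > 0; defaults to the scan's own.
#' @return A power-normalized [raw_scan()].
#' @export
normalize_by_power <- function(scan, power = scan$power) {
  stopifnot(inherits(scan, "raw_scan"))
  if (power <= 0) stop("power must be > 0 (zero power)")
  scan$data <- scan$data / power
  scan$meta$normalized_from_power <- power
  scan$power <- 1
  scan
}

#' Simulate a raster scan of a phantom
#'
#' Generates synthetic raw data for a phantom scene: rasterizes the scene,
#' forward-projects it through the Jacobian, applies the noise model, and
#' arranges the result as a [raw_scan()] (all kept detectors, including the
#' center superpixel).
#'
#' @param scene A [phantom_scene()].
#' @param A A [assemble_jacobian()] model on the scene's grid.
#' @param noise_level Relative Gaussian noise SD (default 0.01); 0 for
#'   noiseless data.
#' @param noise_model Passed to [add_noise()].
#' @param seed Integer seed for the noise.
#' @param power Simulated excitation power (mW); the stored intensities are
#'   scaled by it, as raw data would be.
#' @return A [raw_scan()]; the ground-truth map is in `meta$truth`.
#' @export
simulate_scan <- function(scene, A, noise_level = 0.01,
                          noise_model = "gaussian_relative", seed = 1,
                          power = 1) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(A, "jacobian_model"))
  truth <- rasterize_scene(scene)
  b <- forward_project(A, truth)
  b <- add_noise(b, model = noise_model, level = noise_level, seed = seed)
  raw_scan(unflatten_scan(b * power, A$geometry), A$geometry, power = power,
           meta = list(truth = truth, noise_level = noise_level,
                       noise_model = noise_model, seed = seed,
                       label = scene$label))
}
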