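#' Optical properties of a homogeneous tissue slab
#'
#' Bundles the bulk optical coefficients that govern photon transport in a
#' turbid medium: the scattering coefficient `mu_s`, the absorption
#' coefficient `mu_a`, the Henyey-Greenstein scattering anisotropy `g`
#' (the mean cosine of the single-scattering deflection angle), and the
#' refractive index `n`. The defaults are typical of mouse skin and mammary
#' tissue at 561 nm.
#'
#' The reduced scattering coefficient `mu_s' = mu_s * (1 - g)` and the
#' effective attenuation coefficient
#' `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s'))` are derived quantities,
#' available through [reduced_scattering()] and [effective_attenuation()].
#'
#' @param mu_s Scattering coefficient (mm^-1), > 0.
#' @param mu_a Absorption coefficient (mm^-1), >= 0.
#' @param g Scattering anisotropy, in (-1, 1).
#' @param n Refractive index, >= 1.
#' @return An object of class `optical_properties`.
#' @examples
#' op <- optical_properties(mu_s = 20, mu_a = 0.1, g = 0.85)
#' reduced_scattering(op)   # 3 mm^-1
#' effective_attenuation(op) # ~0.964 mm^-1
#' @export
optical_properties <- function(mu_s = 20, mu_a = 0.1, g = 0.85, n = 1.37) {
  stopifnot(is.numeric(mu_s), length(mu_s) == 1L,
            is.numeric(mu_a), length(mu_a) == 1L,
            is.numeric(g), length(g) == 1L,
            is.numeric(n), length(n) == 1L)
  if (mu_s <= 0) stop("mu_s must be > 0 (got ", mu_s, ")")
  if (mu_a < 0) stop("mu_a must be >= 0 (got ", mu_a, ")")
  if (g <= -1 || g >= 1) stop("g must lie in (-1, 1) (got ", g, ")")
  if (n < 1) stop("refractive index n must be >= 1 (got ", n, ")")
  if (mu_s * (1 - g) <= 0) stop("reduced scattering mu_s*(1-g) must be positive")
  structure(list(mu_s = mu_s, mu_a = mu_a, g = g, n = n),
            class = "optical_properties")
}

#' @rdname optical_properties
#' @param x An `optical_properties` object.
#' @export
reduced_scattering <- function(x) {
  stopifnot(inherits(x, "optical_properties"))
  x$mu_s * (1 - x$g)
}

#' @rdname optical_properties
#' @export
effective_attenuation <- function(x) {
  stopifnot(inherits(x, "optical_properties"))
  musp <- reduced_scattering(x)
  sqrt(3 * x$mu_a * (x$mu_a + musp))
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "Optical properties: mu_s = %g mm^-1, mu_a = %g mm^-1, g = %g, n = %g\n",
    x$mu_s, x$mu_a, x$g, x$n))
  cat(sprintf("  reduced scattering mu_s' = %g mm^-1, mu_eff = %.4g mm^-1\n",
              reduced_scattering(x), effective_attenuation(x)))
  invisible(x)
}

#' Reconstruction voxel grid
#'
#' Defines the 3D voxel lattice on which fluorophore density is represented.
#' Coordinates are right-handed with `z` positive into the tissue and the
#' origin at the top-left scan corner on the tissue surface; all lengths are
#' in mm. A voxel's position is its center; indexing is by
#' `(ix, iy, iz)` with `x` varying fastest in the flattened voxel vector.
#'
#' @param extent Physical size `c(x, y, z)` in mm.
#' @param voxel_size Voxel edge lengths `c(dx, dy, dz)` in mm. The default
#'   `c(0.25, 0.25, 0.1)` uses a finer axial pitch to mitigate the loss of
#'   axial resolution with depth.
#' @param max_depth Maximum admissible reconstruction depth (mm); the grid's
#'   z extent must not exceed it. Default 2 mm.
#' @return An object of class `voxel_grid` with element counts `nx, ny, nz`,
#'   total count `n`, and per-axis center coordinates `xc, yc, zc`.
#' @examples
#' g <- voxel_grid(extent = c(5, 5, 2))
#' g$n  # 20 * 20 * 20 voxels
#' @export
voxel_grid <- function(extent, voxel_size = c(0.25, 0.25, 0.1), max_depth = 2) {
  stopifnot(length(extent) == 3L, length(voxel_size) == 3L,
            all(extent > 0), all(voxel_size > 0))
  counts <- extent / voxel_size
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("grid extent (", paste(extent, collapse = " x "),
         " mm) is not divisible by voxel size (",
         paste(voxel_size, collapse = " x "), " mm)")
  if (extent[3] > max_depth + 1e-12)
    stop("z extent ", extent[3], " mm exceeds the maximum reconstruction depth ",
         max_depth, " mm")
  counts <- as.integer(round(counts))
  centers <- function(k, d) (seq_len(k) - 0.5) * d
  structure(list(
    extent = as.numeric(extent), voxel_size = as.numeric(voxel_size),
    max_depth = max_depth,
    nx = counts[1], ny = counts[2], nz = counts[3],
    n = as.integer(prod(counts)),
    xc = centers(counts[1], voxel_size[1]),
    yc = centers(counts[2], voxel_size[2]),
    zc = centers(counts[3], voxel_size[3]),
    voxel_volume = prod(voxel_size)
  ), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid: %d x %d x %d = %d voxels of %s mm (extent %s mm)\n",
              x$nx, x$ny, x$nz, x$n,
              paste(x$voxel_size, collapse = " x "),
              paste(x$extent, collapse = " x ")))
  invisible(x)
}

#' Raster-scan and detector-array geometry
#'
#' Describes the acquisition geometry: a raster of focused excitation spots
#' (sources) over a square field of view, and a square array of detector
#' superpixels centered on each source position. The superpixel at zero
#' source-detector separation (the center detector) is by default excluded
#' from the measurement vector used for inversion -- its image is retained in
#' the raw scan and drives the source-signal gating -- so a 7 x 7 array
#' contributes 48 detectors.
#'
#' @param fov Scan extent `c(x, y)` in mm (default `c(10, 10)`).
#' @param scan_step Source raster pitch in mm (default 0.25).
#' @param det_shape Detector superpixel array `c(rows, cols)`, odd-sized
#'   (default `c(7, 7)`).
#' @param det_pitch Detector grid spacing in mm (default 0.5).
#' @param max_sd_separation Largest admissible source-detector separation in
#'   mm (default 3.5); offsets beyond it are excluded from the measurement
#'   vector.
#' @param exclude_center Logical; drop the zero-separation detector from the
#'   measurement vector (default `TRUE`).
#' @return An object of class `scan_geometry`.
#' @examples
#' geom <- scan_geometry()
#' measurement_size(geom)  # 41*41 positions x 48 detectors = 80688
#' @export
scan_geometry <- function(fov = c(10, 10), scan_step = 0.25,
                          det_shape = c(7, 7), det_pitch = 0.5,
                          max_sd_separation = 3.5, exclude_center = TRUE) {
  stopifnot(length(fov) == 2L, all(fov >= 0), scan_step > 0,
            length(det_shape) == 2L, all(det_shape >= 1), det_pitch > 0,
            max_sd_separation > 0)
  if (any(det_shape %% 2 == 0))
    stop("detector grid must be odd-sized so that a center (zero-separation) ",
         "detector exists; got ", paste(det_shape, collapse = " x "))
  npos <- fov / scan_step
  if (any(abs(npos - round(npos)) > 1e-9))
    stop("fov (", paste(fov, collapse = " x "),
         " mm) is not an integer multiple of scan_step (", scan_step, " mm)")
  geom <- structure(list(
    fov = as.numeric(fov), scan_step = scan_step,
    det_shape = as.integer(det_shape), det_pitch = det_pitch,
    max_sd_separation = max_sd_separation,
    exclude_center = isTRUE(exclude_center),
    n_scan_x = as.integer(round(npos[1])) + 1L,
    n_scan_y = as.integer(round(npos[2])) + 1L
  ), class = "scan_geometry")
  off <- detector_offsets(geom)
  geom$center_detector_index <- which(off$dx == 0 & off$dy == 0)
  geom$excluded_detectors <- which(!off$included)
  geom
}

#' @export
print.scan_geometry <- function(x, ...) {
  off <- detector_offsets(x)
  cat(sprintf("Scan geometry: %d x %d sources over %s mm at %g mm pitch\n",
              x$n_scan_x, x$n_scan_y, paste(x$fov, collapse = " x "),
              x$scan_step))
  cat(sprintf("  %d x %d detector superpixels at %g mm pitch; %d of %d in the measurement vector\n",
              x$det_shape[1], x$det_shape[2], x$det_pitch,
              sum(off$included), nrow(off)))
  cat(sprintf("  measurement vector length m = %d\n", measurement_size(x)))
  invisible(x)
}

#' Source positions of a raster scan
#'
#' Returns the ordered raster of physical source coordinates for a scan of
#' the given field of view and pitch. The raster is row-major with `x`
#' varying fastest: position index `i = (iy - 1) * n_x + ix`. This ordering
#' is the contract that fixes the layout of the flattened measurement
#' vector.
#'
#' @param fov Scan extent `c(x, y)` in mm; components >= 0.
#' @param step Raster pitch in mm, > 0.
#' @return A numeric matrix with columns `x`, `y` and
#'   `(fov_x/step + 1) * (fov_y/step + 1)` rows.
#' @examples
#' nrow(build_scan_grid(c(10, 10), 0.25))  # 41 * 41 = 1681
#' @export
build_scan_grid <- function(fov, step) {
  stopifnot(length(fov) == 2L, all(fov >= 0), step > 0)
  npos <- fov / step
  if (any(abs(npos - round(npos)) > 1e-9))
    stop("fov (", paste(fov, collapse = " x "),
         " mm) is not an integer multiple of step (", step, " mm)")
  xs <- seq(0, fov[1], by = step)
  ys <- seq(0, fov[2], by = step)
  if (fov[1] == 0) xs <- 0
  if (fov[2] == 0) ys <- 0
  cbind(x = rep(xs, times = length(ys)),
        y = rep(ys, each = length(xs)))
}

#' Detector superpixel offsets relative to the source
#'
#' The detector array is centered on the source position. For a `7 x 7`
#' array at 0.5 mm pitch the offsets span +/-1.5 mm per axis; the corner
#' detectors sit at a Euclidean separation of ~2.12 mm. Offsets farther than
#' `max_sd_separation` from the source, and (by default) the
#' zero-separation center detector, are flagged as not included in the
#' measurement vector.
#'
#' @param geometry A [scan_geometry()] object.
#' @return A data frame with one row per superpixel (row-major over the
#'   detector array, column fastest) and columns `dx`, `dy`, `separation`
#'   (mm), `is_center`, and `included`.
#' @export
detector_offsets <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  half <- (geometry$det_shape - 1L) / 2
  ox <- (seq_len(geometry$det_shape[2]) - 1L - half[2]) * geometry$det_pitch
  oy <- (seq_len(geometry$det_shape[1]) - 1L - half[1]) * geometry$det_pitch
  dx <- rep(ox, times = geometry$det_shape[1])
  dy <- rep(oy, each = geometry$det_shape[2])
  sep <- sqrt(dx^2 + dy^2)
  is_center <- dx == 0 & dy == 0
  included <- sep <= geometry$max_sd_separation + 1e-12
  if (isTRUE(geometry$exclude_center)) included <- included & !is_center
  data.frame(dx = dx, dy = dy, separation = sep,
             is_center = is_center, included = included)
}

#' Length of the flattened measurement vector
#'
#' `m = (number of scan positions) x (number of included detectors)`. For
#' the default geometry (41 x 41 positions, 48 detectors) this is 80,688.
#'
#' @param geometry A [scan_geometry()] object.
#' @return Integer `m`.
#' @export
measurement_size <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  n_det <- sum(detector_offsets(geometry)$included)
  as.integer(geometry$n_scan_x) * as.integer(geometry$n_scan_y) * n_det
}

#' Raw-dataset size accounting
#'
#' Computes the storage footprint of a raster scan's camera frames:
#' `bytes = n_frames * pixels * bit_depth / 8`, with the decimal-megabyte
#' figure `bytes / 10^6` rounded to the nearest integer. A full 41 x 41 scan
#' of 512 x 512 16-bit frames comes to ~881 MB.
#'
#' @param n_frames Number of camera frames (one per scan position), >= 0.
#' @param frame_shape Pixel dimensions `c(rows, cols)` of a frame.
#' @param bit_depth Bits per pixel; must be a multiple of 8.
#' @return A list with `bytes` and `mb` (decimal MB, rounded).
#' @examples
#' raw_dataset_bytes(1681, c(512, 512), 16)$mb  # 881
#' @export
raw_dataset_bytes <- function(n_frames, frame_shape, bit_depth) {
  stopifnot(n_frames >= 0, length(frame_shape) == 2L, all(frame_shape > 0),
            bit_depth > 0)
  if (bit_depth %% 8 != 0)
    stop("bit_depth must be a multiple of 8 (got ", bit_depth, ")")
  bytes <- n_frames * prod(frame_shape) * (bit_depth / 8)
  list(bytes = bytes, mb = round(bytes / 1e6))
}

#' Laser-safety exposure margin
#'
#' Ratio of the maximum permissible exposure (MPE) for skin to the largest
#' energy density actually applied, after harmonizing units (MPE in J/cm^2,
#' applied density in mJ/cm^2). The worst case of the reference protocol
#' (150 mJ/cm^2 against the 1.3 J/cm^2 MPE) leaves a ~9-fold margin.
#'
#' @param mpe Maximum permissible exposure (J/cm^2), > 0.
#' @param max_density Largest applied energy density (mJ/cm^2), > 0.
#' @return A list with `ratio` and its nearest-integer `rounded` value.
#' @examples
#' exposure_margin(1.3, 150)$rounded  # 9
#' @export
exposure_margin <- function(mpe, max_density) {
  stopifnot(is.numeric(mpe), is.numeric(max_density))
  if (mpe <= 0) stop("mpe must be > 0")
  if (max_density <= 0) stop("max_density must be > 0 (zero denominator)")
  ratio <- mpe / (max_density / 1000)
  list(ratio = ratio, rounded = round(ratio))
}
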