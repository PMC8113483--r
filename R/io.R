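#' Serialize geometry, grid and optics to plain lists
#'
#' Round-trippable plain-list forms of the core configuration objects, used
#' by the YAML run-config and the JSON sidecars. `mfmt_from_config()`
#' validates and rebuilds the objects; unknown or missing keys raise an
#' error naming them.
#'
#' @param geometry A [scan_geometry()].
#' @param grid A [voxel_grid()].
#' @param props An [optical_properties()].
#' @return `mfmt_to_config()`: a named list; `mfmt_from_config()`: a list
#'   with elements `geometry`, `grid`, `props`.
#' @export
mfmt_to_config <- function(geometry, grid, props) {
  list(
    geometry = list(fov = geometry$fov, scan_step = geometry$scan_step,
                    det_shape = geometry$det_shape,
                    det_pitch = geometry$det_pitch,
                    max_sd_separation = geometry$max_sd_separation,
                    exclude_center = geometry$exclude_center),
    grid = list(extent = grid$extent, voxel_size = grid$voxel_size,
                max_depth = grid$max_depth),
    optics = list(mu_s = props$mu_s, mu_a = props$mu_a, g = props$g,
                  n = props$n))
}

#' @rdname mfmt_to_config
#' @param config A list as produced by `mfmt_to_config()` (e.g. parsed from
#'   YAML or JSON).
#' @export
mfmt_from_config <- function(config) {
  need <- c("geometry", "grid", "optics")
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys))
    stop("run config is missing key(s): ", paste(missing_keys, collapse = ", "))
  gkeys <- setdiff(names(config$geometry),
                   c("fov", "scan_step", "det_shape", "det_pitch",
                     "max_sd_separation", "exclude_center"))
  if (length(gkeys))
    stop("unknown geometry key(s): ", paste(gkeys, collapse = ", "))
  geometry <- do.call(scan_geometry, lapply(config$geometry, unlist))
  grid <- do.call(voxel_grid, lapply(config$grid, unlist))
  props <- do.call(optical_properties, lapply(config$optics, unlist))
  list(geometry = geometry, grid = grid, props = props)
}

#' Read/write a run configuration as YAML
#'
#' @param config A config list (see [mfmt_to_config()]; may carry extra
#'   run keys such as `seed`, `noise`, `engine`, `phantom`).
#' @param path File path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Write / read a 3D volume as a multi-page TIFF with JSON sidecar
#'
#' One 32-bit float page per z slice (ImageJ-compatible), values min-max
#' scaled to `[0, 1]`; the scale, offset, dimensions and voxel size go to
#' `<path>.json` so the round trip is lossless to float precision.
#'
#' @param vol 3D numeric array (or a `recon_volume`).
#' @param path Output `.tif` path.
#' @param voxel_size Voxel dimensions (mm) for the sidecar.
#' @param extra Extra metadata stored in the sidecar.
#' @return `write_volume_tiff`: the path, invisibly. `read_volume_tiff`:
#'   a list `values` (3D array), `voxel_size`, `meta`.
#' @export
write_volume_tiff <- function(vol, path, voxel_size = NULL, extra = list()) {
  if (inherits(vol, "recon_volume")) {
    if (is.null(voxel_size)) voxel_size <- vol$grid$voxel_size
    vol <- vol$values
  }
  stopifnot(length(dim(vol)) == 3L)
  lo <- min(vol); hi <- max(vol)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(vol)[3]), function(iz)
    t((vol[, , iz] - lo) / scale))  # TIFF rows = y
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  meta <- c(list(dim = dim(vol), offset = lo, scale = scale,
                 voxel_size = voxel_size, package = "mfmt",
                 version = as.character(utils::packageVersion("mfmt"))),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  vol <- array(0, dim = d)
  for (iz in seq_len(d[3]))
    vol[, , iz] <- t(pages[[iz]]) * meta$scale + meta$offset
  list(values = vol, voxel_size = meta$voxel_size, meta = meta)
}

#' View a raw scan as the 4D scan-by-detector-grid array
#'
#' Reshapes the kept-detector axis back to the detector superpixel grid
#' (possible whenever every superpixel is within the separation limit, as
#' in the default geometry): result dims
#' `(n_scan_x, n_scan_y, det_cols, det_rows)`.
#'
#' @param scan A [raw_scan()].
#' @return 4D array.
#' @export
as_detector_array <- function(scan) {
  stopifnot(inherits(scan, "raw_scan"))
  g <- scan$geometry
  if (dim(scan$data)[3] != prod(g$det_shape))
    stop("some superpixels are excluded by the separation limit; ",
         "the full detector grid view is unavailable")
  array(scan$data, dim = c(dim(scan$data)[1:2], g$det_shape[2], g$det_shape[1]))
}

#' Write / read a raw scan as multi-page TIFF with JSON sidecar
#'
#' One page per scan position (raster order, x fastest), each page the
#' detector superpixel image; intensities min-max scaled to `[0, 1]` with
#' the scale and full geometry in `<path>.json`.
#'
#' @param scan A [raw_scan()].
#' @param path Output `.tif` path.
#' @return `write_scan_tiff`: the path, invisibly; `read_scan_tiff`: the
#'   [raw_scan()].
#' @export
write_scan_tiff <- function(scan, path) {
  arr <- as_detector_array(scan)  # (sx, sy, jx, jy)
  d <- dim(arr)
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- vector("list", d[1] * d[2])
  for (iy in seq_len(d[2])) for (ix in seq_len(d[1]))
    pages[[(iy - 1) * d[1] + ix]] <- t((arr[ix, iy, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  g <- scan$geometry
  meta <- list(offset = lo, scale = scale, power = scan$power,
               geometry = list(fov = g$fov, scan_step = g$scan_step,
                               det_shape = g$det_shape,
                               det_pitch = g$det_pitch,
                               max_sd_separation = g$max_sd_separation,
                               exclude_center = g$exclude_center),
               n_scan = d[1:2], det_shape = g$det_shape,
               meta = scan$meta[setdiff(names(scan$meta), "truth")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scan_tiff
#' @export
read_scan_tiff <- function(path) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geometry <- do.call(scan_geometry, lapply(meta$geometry, unlist))
  pages <- tiff::readTIFF(path, all = TRUE)
  nsx <- as.integer(meta$n_scan[1]); nsy <- as.integer(meta$n_scan[2])
  ds <- as.integer(meta$det_shape)
  arr <- array(0, dim = c(nsx, nsy, ds[2], ds[1]))
  for (iy in seq_len(nsy)) for (ix in seq_len(nsx))
    arr[ix, iy, , ] <- t(pages[[(iy - 1) * nsx + ix]]) * meta$scale +
      meta$offset
  data3 <- array(arr, dim = c(nsx, nsy, prod(ds)))
  raw_scan(data3, geometry, power = as.numeric(meta$power),
           meta = as.list(meta$meta))
}

#' Write a manifest of run artifacts
#'
#' Records md5 checksums, the package version, the seed, and the config
#' hash for every artifact of a run, so archived runs can be verified and
#' reproduced.
#'
#' @param paths Character vector of artifact files.
#' @param path Output JSON path.
#' @param seed The run seed.
#' @param config The run config list (hashed into the manifest).
#' @export
write_manifest <- function(paths, path, seed = NA, config = NULL) {
  sums <- tools::md5sum(paths[file.exists(paths)])
  manifest <- list(
    package = "mfmt",
    version = as.character(utils::packageVersion("mfmt")),
    seed = seed,
    config_md5 = if (!is.null(config))
      digest_config(config) else NA,
    files = lapply(seq_along(sums), function(i)
      list(path = basename(names(sums)[i]), md5 = unname(sums[i]))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# md5 of the canonical JSON serialization of a config list
digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
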