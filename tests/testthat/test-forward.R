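test_that("jacobian satisfies its structural invariants", {
  geom <- tiny_geometry()
  grid <- tiny_grid()
  A <- tiny_jacobian(geom, grid)
  ns <- nrow(build_scan_grid(geom$fov, geom$scan_step))
  expect_identical(nrow(A$matrix), as.integer(measurement_size(geom)))
  expect_identical(nrow(A$excluded_matrix),
                   as.integer(ns * sum(!A$offsets$included)))
  expect_identical(ncol(A$matrix), grid$n)
  expect_true(all(A$matrix >= 0))
  expect_false(any(rowSums(A$matrix) == 0))
})

test_that("single source-detector sensitivities equal the Green's function product", {
  # exhaustive small instance: one source, one detector, 2-voxel medium
  geom <- scan_geometry(fov = c(0, 0), scan_step = 1, det_shape = c(1, 3),
                        det_pitch = 0.5, exclude_center = FALSE)
  grid <- voxel_grid(c(1, 1, 0.4), c(1, 1, 0.2))  # 2 voxels, stacked in z
  props <- optical_properties()
  A <- assemble_jacobian(geom, grid, props)
  off <- detector_offsets(geom)
  mut <- props$mu_a + reduced_scattering(props)
  for (d in seq_len(nrow(off))) for (v in 1:2) {
    r_v <- c(grid$xc[1], grid$yc[1], grid$zc[v])
    expected <- diffusion_green(props, c(0, 0, 0), r_v) *
      diffusion_green(props, c(off$dx[d], off$dy[d], 0), r_v) *
      grid$voxel_volume
    expect_equal(A$matrix[d, v], expected, tolerance = 1e-10)
  }
})

test_that("sensitivity decays with depth and probes deeper at larger separations", {
  geom <- scan_geometry(fov = c(0, 0), scan_step = 1, det_shape = c(1, 7),
                        det_pitch = 0.5, exclude_center = FALSE)
  grid <- voxel_grid(c(0.5, 0.5, 2), c(0.5, 0.5, 0.1))  # one voxel column
  A <- assemble_jacobian(geom, grid)
  off <- detector_offsets(geom)
  # small separation: monotone decay below the shallow sensitivity peak
  d_near <- which(off$separation == 0.5)[1]
  s_near <- A$matrix[d_near, ]
  peak <- which.max(s_near)
  expect_true(all(diff(s_near[peak:length(s_near)]) < 0))
  # depth of maximum sensitivity non-decreasing with separation
  seps <- sort(unique(off$separation))
  depth_of_max <- vapply(seps, function(s) {
    d <- which(off$separation == s)[1]
    grid$zc[which.max(A$matrix[d, ])]
  }, numeric(1))
  expect_true(all(diff(depth_of_max) >= 0))
  expect_gt(depth_of_max[length(seps)], depth_of_max[1])
})

test_that("monte-carlo and diffusion Jacobians agree on a coarse grid", {
  geom <- scan_geometry(fov = c(1, 1), scan_step = 0.5, det_shape = c(3, 3),
                        det_pitch = 0.5, exclude_center = FALSE)
  grid <- voxel_grid(c(2, 2, 1.5), c(0.5, 0.5, 0.25), max_depth = 2)
  Ad <- assemble_jacobian(geom, grid, engine = "diffusion")
  Am <- assemble_jacobian(geom, grid, engine = "mc", photons = 4e5, seed = 3)
  cmax <- apply(Am$matrix, 2, max)
  sel <- Am$matrix > rep(0.01 * cmax, each = nrow(Am$matrix)) & Ad$matrix > 0
  rel <- abs(Am$matrix[sel] - Ad$matrix[sel]) / Ad$matrix[sel]
  expect_lt(median(rel), 0.15)
})

test_that("forward projection is exactly linear", {
  A <- tiny_jacobian()
  n <- A$grid$n
  set.seed(8)
  x1 <- array(runif(n), dim = c(A$grid$nx, A$grid$ny, A$grid$nz))
  x2 <- array(runif(n), dim = dim(x1))
  n_all <- A$geometry$n_scan_x * A$geometry$n_scan_y * nrow(A$offsets)
  expect_identical(forward_project(A, x1 * 0), rep(0, n_all))
  expect_equal(forward_project(A, 10 * x1), 10 * forward_project(A, x1),
               tolerance = 1e-14)
  expect_equal(forward_project(A, x1 + x2),
               forward_project(A, x1) + forward_project(A, x2),
               tolerance = 1e-12)
  expect_error(forward_project(A, array(1, dim = c(2, 2, 2))),
               "do not match")
})

test_that("noise models are calibrated and reproducible", {
  b <- rep(10, 2000)
  expect_identical(add_noise(b, level = 0), b)
  reps <- vapply(1:50, function(s)
    add_noise(b, "gaussian_relative", 0.01, seed = s), numeric(length(b)))
  expect_equal(stats::sd(as.vector(reps)) / 10, 0.01, tolerance = 0.1)
  expect_identical(add_noise(b, "gaussian_relative", 0.05, seed = 3),
                   add_noise(b, "gaussian_relative", 0.05, seed = 3))
  shot <- add_noise(b, "shot", level = 100, seed = 1)
  expect_equal(mean(shot), 10, tolerance = 0.05)
  expect_error(add_noise(b, "salt_pepper", 0.1), "unknown noise model")
})

test_that("power normalization rescales intensities", {
  geom <- tiny_geometry()
  nd <- nrow(detector_offsets(geom))
  arr <- array(runif(5 * 5 * nd), dim = c(5, 5, nd))
  s1 <- raw_scan(arr, geom, power = 1)
  for (p in 1:5) {  # the protocol's 1-5 mW range
    sp <- raw_scan(arr * p, geom, power = p)
    expect_equal(normalize_by_power(sp)$data, s1$data, tolerance = 1e-12)
  }
  expect_identical(normalize_by_power(s1)$data, arr)
  expect_error(normalize_by_power(raw_scan(arr, geom, power = 1), power = 0),
               "zero power")
})

test_that("scan flattening follows the documented rule and round-trips", {
  geom <- tiny_geometry(exclude_center = FALSE)
  nsx <- geom$n_scan_x; nsy <- geom$n_scan_y
  nd <- nrow(detector_offsets(geom))
  arr <- array(seq_len(nsx * nsy * nd), dim = c(nsx, nsy, nd))
  scan <- raw_scan(arr, geom)
  b <- flatten_scan(scan, included_only = FALSE)
  # corners of the array under rule (s-1)*nd + d, s = ix + (iy-1)*nsx
  expect_identical(b[1], arr[1, 1, 1])
  expect_identical(b[nd], arr[1, 1, nd])
  expect_identical(b[(nsx - 1) * nd + 1], arr[nsx, 1, 1])
  expect_identical(b[(nsx * nsy - 1) * nd + nd], arr[nsx, nsy, nd])
  expect_identical(unflatten_scan(b, geom), arr)
  # excluded center drops exactly the center detector values
  geom_x <- tiny_geometry(exclude_center = TRUE)
  scan_x <- raw_scan(arr, geom_x)
  bi <- flatten_scan(scan_x, included_only = TRUE)
  expect_identical(length(bi), as.integer(measurement_size(geom_x)))
  ci <- which(detector_offsets(geom_x)$is_center)
  expect_false(any(bi == arr[1, 1, ci]))
})

test_that("simulated scans respect geometry and record provenance", {
  A <- tiny_jacobian()
  scene <- phantom_scene(grid = A$grid, inclusions = list(
    inclusion("sphere", c(1, 1, 0.5), radius = 0.3, density = 5)))
  scan <- simulate_scan(scene, A, noise_level = 0.02, seed = 7)
  expect_s3_class(scan, "raw_scan")
  expect_identical(dim(scan$data),
                   c(A$geometry$n_scan_x, A$geometry$n_scan_y,
                     nrow(A$offsets)))
  expect_identical(scan$meta$seed, 7)
  scan2 <- simulate_scan(scene, A, noise_level = 0.02, seed = 7)
  expect_identical(scan$data, scan2$data)
  # zero-inclusion scene: noise-free zero signal
  empty <- phantom_scene(grid = A$grid)
  s0 <- simulate_scan(empty, A, noise_level = 0.01, seed = 1)
  expect_true(all(s0$data == 0))
})
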