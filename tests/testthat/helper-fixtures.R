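# Shared small fixtures: a coarse acquisition geometry and grid that keep
# unit tests fast while exercising the same code paths as the full-scale
# configuration.

tiny_geometry <- function(exclude_center = TRUE)
  scan_geometry(fov = c(2, 2), scan_step = 0.5, det_shape = c(3, 3),
                det_pitch = 0.5, max_sd_separation = 3.5,
                exclude_center = exclude_center)

tiny_grid <- function() voxel_grid(c(2, 2, 1), c(0.5, 0.5, 0.25))

tiny_jacobian <- function(geometry = tiny_geometry(), grid = tiny_grid(),
                          props = optical_properties())
  assemble_jacobian(geometry, grid, props, engine = "diffusion")

# A raw scan holding the given values, for postprocess unit tests:
# a single detector over a 1D raster so the value layout is transparent.
scan_with_values <- function(values, ...) {
  n <- length(values)
  geom <- scan_geometry(fov = c(n - 1, 0), scan_step = 1,
                        det_shape = c(1, 1), det_pitch = 0.5,
                        exclude_center = FALSE)
  raw_scan(array(values, dim = c(n, 1, 1)), geom)
}

# Independent slow proximal-descent (ISTA) oracle for the L1 objective
# ||Ax - b||^2 + lambda ||x||_1, x >= 0. Deliberately naive.
ista_oracle <- function(A, b, lambda, iters = 1e5) {
  L <- 2 * max(eigen(crossprod(A), symmetric = TRUE,
                     only.values = TRUE)$values)
  x <- numeric(ncol(A))
  for (i in seq_len(iters)) {
    g <- 2 * drop(crossprod(A, A %*% x - b))
    x <- pmax(x - g / L - lambda / L, 0)
  }
  x
}

l1_objective <- function(A, b, lambda, x)
  sum((drop(A %*% x) - b)^2) + lambda * sum(abs(x))
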