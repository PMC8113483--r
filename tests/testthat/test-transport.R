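test_that("Henyey-Greenstein sampling has the right mean cosine", {
  set.seed(1)
  expect_lt(abs(mean(sample_scatter_cosine(1e5, 0))), 0.01)
  set.seed(2)
  expect_equal(mean(sample_scatter_cosine(1e5, 0.85)), 0.85,
               tolerance = 0.012)
  set.seed(3); a <- sample_scatter_cosine(100, 0.85)
  set.seed(3); b <- sample_scatter_cosine(100, 0.85)
  expect_identical(a, b)
  expect_true(all(abs(a) <= 1))
  expect_error(sample_scatter_cosine(10, 1), "< 1")
})

test_that("Monte-Carlo weight ledger conserves energy", {
  grid <- voxel_grid(c(4, 4, 2), c(0.25, 0.25, 0.1))
  sc <- phantom_scene(grid = grid, thickness = 3)
  fm <- run_mc(sc, c(2, 2), photons = 5e4, seed = 4)
  expect_equal(fm$absorbed + fm$reflected + fm$transmitted, 1,
               tolerance = 0.005)
  expect_true(all(fm$values >= 0))
  expect_error(run_mc(sc, c(2, 2, 0.5)), "surface")
})

test_that("pure absorption reduces to Beer-Lambert within Monte-Carlo error", {
  props <- optical_properties(mu_s = 1e-6, mu_a = 2, g = 0)
  grid <- voxel_grid(c(1, 1, 2), c(0.25, 0.25, 0.1))
  sc <- phantom_scene(props = props, grid = grid, thickness = 2)
  n_batch <- 8
  prof <- matrix(0, n_batch, grid$nz)
  for (k in seq_len(n_batch)) {
    fm <- run_mc(sc, c(0.5, 0.5), photons = 2e4, seed = 100 + k)
    # the beam enters at a voxel corner; its straight path deposits in
    # the voxel whose lower corner that is
    prof[k, ] <- fm$values[3, 3, ] / fm$values[3, 3, 1]
  }
  m <- colMeans(prof)
  se <- apply(prof, 2, stats::sd) / sqrt(n_batch)
  expected <- exp(-props$mu_a * (grid$zc - grid$zc[1]))
  dev <- abs(m - expected)
  expect_true(all(dev[2:15] <= 3 * pmax(se[2:15], 1e-4)))
})

test_that("Monte-Carlo fluence matches the diffusion Green's function at depth", {
  props <- optical_properties()  # mu_s' = 3 mm^-1, 1 transport mfp = 1/3 mm
  grid <- voxel_grid(c(4, 4, 2), c(0.25, 0.25, 0.1))
  sc <- phantom_scene(props = props, grid = grid, thickness = 3)
  fm <- run_mc(sc, c(2, 2), photons = 3e5, seed = 9)
  mc_prof <- fm$values[8, 8, ]  # voxel column at (1.875, 1.875)
  pts <- cbind(1.875, 1.875, grid$zc)
  dg <- diffusion_green(props, c(2, 2, 0), pts)
  sel <- grid$zc >= 1 / reduced_scattering(props) + 0.1 & grid$zc <= 1.6
  rel <- abs(mc_prof[sel] - dg[sel]) / dg[sel]
  expect_true(all(rel < 0.10))
})

test_that("doubling the photon budget shrinks the relative error ~ 1/sqrt(2)", {
  grid <- voxel_grid(c(2, 2, 1), c(0.25, 0.25, 0.25))
  sc <- phantom_scene(grid = grid, thickness = 2)
  f1 <- run_mc(sc, c(1, 1), photons = 2e4, seed = 5)
  f2 <- run_mc(sc, c(1, 1), photons = 4e4, seed = 6)
  sel <- f1$hits > 50 & f2$hits > 50
  ratio <- median(f2$rel_error[sel] / f1$rel_error[sel])
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.12)
})

test_that("diffusion Green's function is reciprocal and decays correctly", {
  props <- optical_properties()
  a <- c(1, 1, 0.8); b <- c(2.2, 1.4, 0.8)
  expect_equal(diffusion_green(props, a, b), diffusion_green(props, b, a),
               tolerance = 1e-14)
  # far field ~ exp(-mu_eff d) / d
  mueff <- effective_attenuation(props)
  d1 <- 3; d2 <- 4
  g1 <- diffusion_green(props, c(0, 0, 5), c(d1, 0, 5))
  g2 <- diffusion_green(props, c(0, 0, 5), c(d2, 0, 5))
  expect_equal(g1 / g2, exp(-mueff * (d1 - d2)) * d2 / d1, tolerance = 0.02)
  expect_equal(mueff, 0.9643651, tolerance = 1e-6)
  expect_error(diffusion_green(props, c(0, 0, 1), c(0, 0, 1)), "singularity")
})

test_that("transport is reciprocal between surface sources", {
  # fluence near surface point s2 from a pencil beam at s1 matches the
  # fluence near s1 from a pencil beam at s2 (coarse grid, 3 SE)
  grid <- voxel_grid(c(3, 3, 1), c(0.5, 0.5, 0.25))
  sc <- phantom_scene(grid = grid, thickness = 2)
  s1 <- c(1, 1.5); s2 <- c(2, 1.5)
  n_batch <- 6
  v12 <- v21 <- numeric(n_batch)
  for (k in seq_len(n_batch)) {
    f1 <- run_mc(sc, s1, photons = 4e4, seed = 200 + k)
    f2 <- run_mc(sc, s2, photons = 4e4, seed = 300 + k)
    # both voxels sit at the same displacement magnitude from their
    # source: (+0.75, -0.25) from s1 and (-0.75, -0.25) from s2
    v12[k] <- f1$values[4, 3, 2]  # center (1.75, 1.25)
    v21[k] <- f2$values[3, 3, 2]  # center (1.25, 1.25)
  }
  se <- sqrt(stats::var(v12) / n_batch + stats::var(v21) / n_batch)
  expect_lt(abs(mean(v12) - mean(v21)), 3 * max(se, 1e-6))
})
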