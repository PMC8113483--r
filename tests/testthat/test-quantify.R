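test_that("slice cell extrapolation follows the area ratio", {
  expect_equal(estimate_slice_cells(1.0, 0.1, 500), 5000)
  expect_equal(estimate_slice_cells(0.7, 0.7, 123), 123)
  # density invariance: doubling sub-area and count changes nothing
  expect_equal(estimate_slice_cells(2, 0.2, 400),
               estimate_slice_cells(2, 0.4, 800))
  expect_error(estimate_slice_cells(0.5, 0.6, 10), "exceeds")
})

test_that("tumor totals match a synthetic histology oracle", {
  # homogeneous synthetic tumor: nuclei uniform in a cylinder of radius
  # 0.5 mm, height 0.45 mm, sliced at 4.5 um -> 100 slices
  set.seed(61)
  n_nuclei <- 20000
  r <- 0.5 * sqrt(stats::runif(n_nuclei))
  th <- stats::runif(n_nuclei, 0, 2 * pi)
  z <- stats::runif(n_nuclei, 0, 0.45)
  slice_of <- pmin(floor(z / 0.0045) + 1, 100)
  A1 <- pi * 0.5^2
  slices <- lapply(1:100, function(i) {
    xs <- r[slice_of == i] * cos(th[slice_of == i])
    ys <- r[slice_of == i] * sin(th[slice_of == i])
    # counted sub-area: the central disc of radius 0.25 mm
    A2 <- pi * 0.25^2
    list(A1 = A1, A2 = A2, C_sub = sum(xs^2 + ys^2 <= 0.25^2))
  })
  est <- tumor_total_cells(slices)
  expect_equal(est, n_nuclei, tolerance = 0.10)
  expect_equal(tumor_total_cells(slices[5]),
               estimate_slice_cells(slices[[5]]$A1, slices[[5]]$A2,
                                    slices[[5]]$C_sub))
})

test_that("density heterogeneity biases the extrapolation as expected", {
  # sampled region twice as dense as the rest (half the area each):
  # expected bias 2*rho/(1.5*rho) - 1 = +33%
  set.seed(62)
  A1 <- 1; A2 <- 0.5
  rho_dense <- 4000; rho_sparse <- 2000
  bias <- replicate(50, {
    C_sub <- stats::rpois(1, rho_dense * A2)
    truth <- rho_dense * A2 + rho_sparse * (A1 - A2)
    estimate_slice_cells(A1, A2, C_sub) / truth - 1
  })
  expect_gt(mean(bias), 0.15)
  expect_lt(mean(bias), 0.45)
})

test_that("calibration fit recovers linear relationships", {
  sig <- c(1, 2, 3, 4)
  cal <- fit_calibration(sig, 2 * sig)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$rmse, 0, tolerance = 1e-12)
  expect_equal(unname(predict(cal, 10)), 20, tolerance = 1e-12)
  # noisy recovery at the reference study size (n = 8, 5% noise)
  set.seed(71)
  true_slope <- 3e4
  s8 <- stats::runif(8, 1, 20)
  cells <- true_slope * s8 * (1 + stats::rnorm(8, 0, 0.05))
  cal8 <- fit_calibration(s8, cells)
  expect_equal(cal8$slope, true_slope, tolerance = 0.10)
  # order invariance
  perm <- sample(8)
  cal8p <- fit_calibration(s8[perm], cells[perm])
  expect_equal(cal8$slope, cal8p$slope, tolerance = 1e-12)
  expect_error(fit_calibration(rep(2, 4), 1:4), "rank-deficient")
})

test_that("integrated signal and volume follow the mask", {
  vol <- array(0, dim = c(4, 4, 3))
  vol[2, 2, 2] <- 5
  grid <- voxel_grid(c(2, 2, 0.3), c(0.5, 0.5, 0.1))
  rv <- structure(list(values = vol, grid = grid), class = "recon_volume")
  full <- structure(list(mask = vol > 0, n_voxels = sum(vol > 0),
                         thresholds = 1, mi = NA, chosen = 1,
                         degenerate = FALSE),
                    class = "threshold_report")
  empty <- structure(list(mask = vol > 10, n_voxels = 0L, thresholds = 1,
                          mi = NA, chosen = 1, degenerate = TRUE),
                     class = "threshold_report")
  expect_equal(integrated_signal(rv, full), 5)
  expect_equal(integrated_signal(rv, empty), 0)
  rv2 <- rv; rv2$values <- 3 * rv$values
  expect_equal(integrated_signal(rv2, full), 15)
  expect_equal(tumor_volume(rv, full), grid$voxel_volume)
  expect_equal(tumor_volume(rv, empty), 0)
  # full mask: count x voxel volume = grid volume
  all_mask <- structure(list(mask = array(TRUE, dim(vol)),
                             n_voxels = length(vol), thresholds = 0,
                             mi = NA, chosen = 0, degenerate = FALSE),
                        class = "threshold_report")
  expect_equal(tumor_volume(rv, all_mask), prod(grid$extent))
})

test_that("integrated signal is invariant to voxel-order permutation", {
  set.seed(81)
  vol <- array(stats::runif(60), dim = c(5, 4, 3))
  mask <- vol > 0.4
  rep_ <- structure(list(mask = mask, n_voxels = sum(mask)),
                    class = "threshold_report")
  grid <- voxel_grid(c(2.5, 2, 0.3), c(0.5, 0.5, 0.1))
  rv <- structure(list(values = vol, grid = grid), class = "recon_volume")
  s1 <- integrated_signal(rv, rep_)
  p <- sample(60)
  rv$values <- array(as.vector(vol)[p], dim = dim(vol))
  rep_$mask <- array(as.vector(mask)[p], dim = dim(mask))
  expect_equal(integrated_signal(rv, rep_), s1, tolerance = 1e-12)
})

test_that("longitudinal summaries normalize volume and apply calibration", {
  grid <- voxel_grid(c(2, 2, 0.5), c(0.5, 0.5, 0.25))
  mk_fit <- function(value, nvox) {
    vol <- array(0, dim = c(4, 4, 2))
    vol[seq_len(nvox)] <- value / nvox
    list(recon = structure(list(values = vol, grid = grid),
                           class = "recon_volume"),
         report = structure(list(mask = vol > 0, n_voxels = sum(vol > 0)),
                            class = "threshold_report"))
  }
  cal <- fit_calibration(c(1, 2, 3), c(100, 200, 300))
  # flat series: fold change 1 throughout
  flat <- longitudinal_summary(list(mk_fit(4, 8), mk_fit(4, 8), mk_fit(4, 8)),
                               cal, days = c(0, 7, 14))
  expect_equal(flat$volume_normalized, rep(1, 3))
  expect_equal(flat$cell_count, rep(400, 3), tolerance = 1e-9)
  # count grows while volume constant: decoupling scenario
  dec <- longitudinal_summary(list(mk_fit(2, 8), mk_fit(6, 8), mk_fit(20, 8)),
                              cal, days = c(0, 3, 6), dox = "on")
  expect_equal(dec$volume_normalized, rep(1, 3))
  expect_true(all(diff(dec$cell_count) > 0))
  expect_equal(dec$volume_normalized[1], 1)
  expect_error(longitudinal_summary(list(mk_fit(1, 2)), cal), "length")
})

test_that("calibrated per-voxel maps sum to the calibrated total", {
  grid <- voxel_grid(c(2, 2, 0.5), c(0.5, 0.5, 0.25))
  vol <- array(stats::runif(32), dim = c(4, 4, 2))
  rv <- structure(list(values = vol, grid = grid), class = "recon_volume")
  mask <- vol > 0.3
  rep_ <- structure(list(mask = mask, n_voxels = sum(mask)),
                    class = "threshold_report")
  cal <- fit_calibration(c(1, 2, 3, 5), c(150, 260, 390, 610))
  m <- calibrated_cell_map(rv, rep_, cal)
  expect_equal(sum(m), unname(predict(cal, integrated_signal(rv, rep_))),
               tolerance = 1e-9)
})
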