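test_that("median filter zeroes values strictly below the global median", {
  s <- scan_with_values(c(1, 2, 3, 4, 5))
  f <- median_noise_filter(s)
  expect_identical(as.vector(f$data), c(0, 0, 3, 4, 5))
  expect_identical(f$meta$median_cut, 3)
  sc <- scan_with_values(rep(7, 5))
  expect_identical(as.vector(median_noise_filter(sc)$data), rep(7, 5))
})

test_that("median filter count matches brute force on small vectors", {
  set.seed(21)
  for (rep in 1:20) {
    vals <- sample(0:9, 8, replace = TRUE)
    f <- median_noise_filter(scan_with_values(vals))
    expect_identical(as.vector(f$data),
                     ifelse(vals < stats::median(vals), 0, vals))
    expect_identical(sum(f$data == 0 & vals != 0),
                     sum(vals < stats::median(vals) & vals != 0))
  }
})

test_that("median filter uses the measurement-vector median when the center is excluded", {
  # center detector is in the raw data but not among the 'data points'
  geom <- scan_geometry(fov = c(0, 0), scan_step = 1, det_shape = c(1, 3),
                        det_pitch = 0.5, exclude_center = TRUE)
  s <- raw_scan(array(c(1, 100, 3), dim = c(1, 1, 3)), geom)  # center = 100
  f <- median_noise_filter(s)
  expect_identical(f$meta$median_cut, 2)  # median of included {1, 3}
})

test_that("center-detector gate applies the mean - 2 SD rule", {
  geom <- scan_geometry(fov = c(4, 0), scan_step = 1, det_shape = c(1, 1),
                        det_pitch = 0.5, exclude_center = FALSE)
  s <- raw_scan(array(c(10, 10, 10, 10, 0), dim = c(5, 1, 1)), geom)
  g <- center_detector_gate(s)
  expect_equal(g$mean, 8)
  expect_equal(g$sd, 4)  # population SD
  expect_equal(g$lower, 0)
  expect_true(all(g$mask))  # bound 0: everything kept
  # all-equal image: zero variance warns, keeps everything
  s2 <- raw_scan(array(rep(3, 5), dim = c(5, 1, 1)), geom)
  expect_warning(g2 <- center_detector_gate(s2), "zero-variance")
  expect_true(all(g2$mask))
})

test_that("gate pass fraction on Gaussian images approaches the 2-sigma tail", {
  geom <- scan_geometry(fov = c(40, 40), scan_step = 1, det_shape = c(1, 1),
                        det_pitch = 0.5, exclude_center = FALSE)
  set.seed(31)
  frac <- replicate(20, {
    img <- array(stats::rnorm(41 * 41, 50, 5), dim = c(41, 41, 1))
    g <- center_detector_gate(raw_scan(pmax(img, 0), geom))
    mean(g$mask)
  })
  expect_equal(mean(frac), stats::pnorm(2), tolerance = 0.005)
})

test_that("mutual information matches direct evaluation and is symmetric", {
  # identity: MI(X, X) = H(X); two-level image half 0s / half 1s -> 1 bit
  x <- matrix(rep(c(0, 1), each = 50), 10, 10)
  expect_equal(mutual_information(x, x, bins = 2), 1, tolerance = 1e-12)
  # known 2x2 joint histogram {0.4, 0.1; 0.1, 0.4}
  a <- rep(c(0, 0, 1, 1), times = c(40, 10, 10, 40))
  b <- rep(c(0, 1, 0, 1), times = c(40, 10, 10, 40))
  p <- c(0.4, 0.1, 0.1, 0.4)
  expected <- sum(p * log2(p / c(0.25, 0.25, 0.25, 0.25)))
  expect_equal(mutual_information(matrix(a, 10), matrix(b, 10), bins = 2),
               expected, tolerance = 1e-12)
  # independence: MI -> 0
  set.seed(41)
  u <- matrix(stats::runif(1e4), 100, 100)
  v <- matrix(stats::runif(1e4), 100, 100)
  expect_lt(mutual_information(u, v, bins = 8), 0.05)
  # symmetry to machine precision
  expect_equal(mutual_information(u, v, bins = 16),
               mutual_information(v, u, bins = 16), tolerance = 1e-15)
  expect_error(mutual_information(u, v[1:50, ]), "identical shapes")
})

test_that("maximum intensity projection picks the per-column maximum", {
  v <- array(0, dim = c(3, 4, 5))
  expect_identical(mip(v), matrix(0, 3, 4))
  v[2, 3, 4] <- 7
  m <- mip(v)
  expect_identical(m[2, 3], 7)
  expect_identical(sum(m != 0), 1L)
  v[2, 3, 1] <- 2; v[2, 3, 5] <- 5
  expect_identical(mip(v)[2, 3], 7)
})

test_that("MI threshold scan selects sensible thresholds", {
  set.seed(51)
  vol <- array(0, dim = c(10, 10, 8))
  vol[4:6, 4:6, 3:5] <- 5 + stats::runif(27)
  vol <- vol + array(stats::runif(800, 0, 0.3), dim = dim(vol))
  # self-similarity: reference = own MIP -> MI maximal at lowest threshold
  rep1 <- mi_threshold_scan(vol, mip(vol), thresholds = 30)
  expect_equal(rep1$chosen, rep1$thresholds[1], tolerance = 1e-12)
  # survival count non-increasing in threshold
  counts <- vapply(rep1$thresholds, function(t) sum(vol >= t), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # thresholds above the maximum: degenerate, all-zero masks
  rep2 <- mi_threshold_scan(vol, mip(vol),
                            thresholds = max(vol) * c(1.5, 2))
  expect_true(rep2$degenerate)
  expect_identical(rep2$n_voxels, 0L)
  expect_error(mi_threshold_scan(vol, mip(vol), thresholds = numeric(0)),
               "empty threshold")
})

test_that("fixed 50% threshold baseline masks at half maximum", {
  vol <- array(c(0, 1, 2, 10), dim = c(2, 2, 1))
  r <- fixed_threshold(vol, 0.5)
  expect_identical(r$n_voxels, 1L)
  expect_true(r$mask[2, 2, 1])
})
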