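test_that("lambda = 0 with orthogonal columns recovers least squares exactly", {
  set.seed(10)
  Q <- qr.Q(qr(matrix(stats::rnorm(40 * 6), 40, 6)))
  x_true <- stats::runif(6, 0.5, 2)
  b <- drop(Q %*% x_true)
  s <- solve_l1(Q, b, lambda = 0, tol = 1e-15, max_iter = 5000)
  expect_equal(as.vector(s$values), x_true, tolerance = 1e-10)
})

test_that("large lambda gives the exact zero solution", {
  set.seed(11)
  M <- matrix(stats::rnorm(30 * 20), 30, 20)
  b <- stats::rnorm(30)
  lmax <- max(abs(2 * crossprod(M, b)))
  s <- solve_l1(M, b, lambda = lmax * (1 + 1e-12))
  expect_identical(as.vector(s$values), rep(0, 20))
  # just below the non-negative activation threshold the solution turns on
  thr <- max(2 * crossprod(M, b))
  s2 <- solve_l1(M, b, lambda = thr * 0.95, tol = 1e-10, max_iter = 2000)
  expect_gt(sum(s2$values), 0)
})

test_that("FISTA matches the slow proximal oracle", {
  set.seed(12)
  M <- matrix(stats::rnorm(20 * 50), 20, 50)
  b <- stats::rnorm(20)
  lmax <- max(abs(2 * crossprod(M, b)))
  for (f in c(0.05, 0.2)) {
    xo <- ista_oracle(M, b, f * lmax, iters = 3e4)
    oo <- l1_objective(M, b, f * lmax, xo)
    s <- solve_l1(M, b, f * lmax, tol = 1e-12, max_iter = 20000)
    expect_lt(abs(s$objective - oo) / oo, 1e-6)
  }
})

test_that("objective trace is non-increasing and solves are deterministic", {
  set.seed(13)
  M <- matrix(stats::rnorm(40 * 30), 40, 30)
  b <- stats::rnorm(40)
  s1 <- solve_l1(M, b, 0.5, tol = 1e-10, max_iter = 3000)
  expect_true(all(diff(s1$trace) <= 1e-12 * abs(s1$trace[-length(s1$trace)])))
  s2 <- solve_l1(M, b, 0.5, tol = 1e-10, max_iter = 3000)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$objective, s2$objective)
})

test_that("the L1 norm of the solution path is non-increasing in lambda", {
  set.seed(14)
  M <- matrix(abs(stats::rnorm(60 * 40)), 60, 40)
  x_true <- numeric(40); x_true[c(5, 17, 31)] <- c(2, 1, 3)
  b <- drop(M %*% x_true) * (1 + stats::rnorm(60, 0, 0.01))
  lmax <- max(abs(2 * crossprod(M, b)))
  lambdas <- 10^seq(log10(lmax) - 3, log10(lmax), length.out = 8)
  l1 <- vapply(lambdas, function(l)
    solve_l1(M, b, l, tol = 1e-9, max_iter = 4000)$l1_norm, numeric(1))
  expect_true(all(diff(l1) <= 1e-8 * max(l1)))
})

test_that("L-curve corner lands low for clean data and high for pure noise", {
  set.seed(15)
  M <- matrix(abs(stats::rnorm(50 * 30)), 50, 30)
  x_true <- numeric(30); x_true[c(3, 12, 25)] <- c(1, 2, 1.5)
  b_clean <- drop(M %*% x_true)
  lmax <- max(abs(2 * crossprod(M, b_clean)))
  cands <- 10^seq(log10(lmax) - 5, log10(lmax), length.out = 9)
  lc <- l_curve_select(M, b_clean, cands, tol = 1e-10, max_iter = 5000)
  # clean data: the corner keeps the data fit tight and the recovered
  # support contains the true support
  sol <- lc$solutions[[which(cands == lc$lambda)]]
  expect_lt(sol$residual_norm / sqrt(sum(b_clean^2)), 0.1)
  x_hat <- as.vector(sol$values)
  expect_true(all(x_hat[c(3, 12, 25)] > 0.05))
  # pure noise: the corner explains almost nothing and x stays near zero
  b_noise <- abs(stats::rnorm(50, 0, 0.05 * mean(b_clean)))
  lmax_n <- max(abs(2 * crossprod(M, b_noise)))
  cands_n <- 10^seq(log10(lmax_n) - 5, log10(lmax_n), length.out = 9)
  lc_n <- l_curve_select(M, b_noise, cands_n, tol = 1e-10, max_iter = 5000)
  sol_n <- lc_n$solutions[[which(cands_n == lc_n$lambda)]]
  expect_lt(sum(as.vector(sol_n$values)), 0.1 * sum(x_true))
})

test_that("L-curve handles single candidates and degenerate curves", {
  set.seed(16)
  M <- matrix(stats::rnorm(20 * 10), 20, 10)
  b <- stats::rnorm(20)
  lc1 <- l_curve_select(M, b, candidates = 0.7)
  expect_identical(lc1$lambda, 0.7)
  # all-zero data: every candidate gives x = 0, a degenerate curve
  expect_warning(lc0 <- l_curve_select(M, rep(0, 20),
                                       candidates = c(1, 2, 4, 8, 16)),
                 "degenerate")
  expect_identical(lc0$lambda, 4)
})

test_that("MI fine-tuning prefers informative regularization levels", {
  # single-blob phantom on the coarse geometry
  A <- tiny_jacobian()
  scene <- phantom_scene(grid = A$grid, inclusions = list(
    inclusion("sphere", c(1, 1, 0.4), radius = 0.3, density = 10)))
  scan <- simulate_scan(scene, A, noise_level = 0.01, seed = 21)
  scan <- median_noise_filter(scan)
  gate <- center_detector_gate(scan)
  ref <- gate$image * gate$mask
  b <- flatten_scan(scan)
  lc <- l_curve_select(A, b)
  ft <- mi_fine_tune(A, b, lc$lambda, ref)
  expect_true(ft$lambda %in% ft$schedule$lambda)
  chosen_mi <- max(ft$schedule$mi, na.rm = TRUE)
  # the chosen lambda beats strongly mis-set regularization
  for (f in c(0.1, 10)) {
    s <- solve_l1(A, b, ft$lambda * f)
    if (any(s$values > 0)) {
      mi_f <- max(mi_threshold_scan(s, ref)$mi)
      expect_gte(chosen_mi, mi_f - 1e-9)
    }
  }
  # factors = {1} returns lambda unchanged
  ft1 <- mi_fine_tune(A, b, lc$lambda, ref, factors = 1)
  expect_identical(ft1$lambda, lc$lambda)
  expect_error(mi_fine_tune(A, b, lc$lambda, ref, factors = c(2, 4)),
               "bracket")
  # absurdly large lambda for every factor: over-regularized
  expect_error(mi_fine_tune(A, b, 1e12, ref, factors = c(0.5, 1, 2)),
               "over-regularized")
})
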