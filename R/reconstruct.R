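#' Reconstruct a 3D fluorophore distribution from a raster scan
#'
#' The main fitting function: runs the full reconstruction pipeline on a
#' raw scan, in the fixed order (1) power normalization, (2) median noise
#' filter, (3) center-detector source-signal gate (mean - 2 SD rule),
#' (4) regularization-weight selection by the L-curve corner followed by
#' mutual-information fine-tuning, (5) the non-negative L1 (FISTA) solve,
#' (6) the mutual-information threshold scan of the reconstructed volume
#' against the gated center-detector image.
#'
#' @param scan A [raw_scan()] (e.g. from [simulate_scan()] or
#'   [read_scan_tiff()]).
#' @param A The [assemble_jacobian()] model matching the scan's geometry.
#' @param lambda Optional fixed regularization weight; when supplied the
#'   L-curve and MI fine-tuning stages are skipped.
#' @param lambda_candidates Candidate grid for [l_curve_select()]
#'   (default: its internal log-spaced grid).
#' @param finetune_factors Factors for [mi_fine_tune()]; `NULL` disables
#'   fine-tuning.
#' @param tol,max_iter Final-solve convergence controls (see [solve_l1()]).
#' @param search_tol,search_max_iter Convergence controls for the
#'   selection sweeps (defaults `1e-4` and 1000): path solutions only
#'   steer the corner search and MI ranking, so they are run looser than
#'   the final solve, which is then polished at `tol` from a warm start.
#' @param n_thresholds,bins Threshold-scan controls (see
#'   [mi_threshold_scan()]).
#' @param gram Optional precomputed [make_gram()] list for this scan, or a
#'   bare `A'A` matrix (with its `eigmax` attribute optional) to share the
#'   b-independent part across scans of the same Jacobian.
#' @param verbose Narrate the pipeline stages.
#' @return An object of class `mfmt_recon` with components `recon` (the
#'   [solve_l1()] result), `report` (the [mi_threshold_scan()] report),
#'   `lambda`, `schedules` (the selection stages), `gate`, `scan` (the
#'   filtered scan), `b` (the measurement vector), and `A`.
#'   Methods: `print`, `summary`, `coef`, `fitted`, `residuals`,
#'   `predict`, `plot`, `simulate`.
#' @export
mfmt_reconstruct <- function(scan, A, lambda = NULL, lambda_candidates = NULL,
                             finetune_factors = c(0.25, 0.5, 1, 2, 4),
                             tol = 1e-6, max_iter = 5000, search_tol = 1e-4,
                             search_max_iter = 1000, n_thresholds = 50,
                             bins = 64, gram = NULL, verbose = FALSE) {
  stopifnot(inherits(scan, "raw_scan"), inherits(A, "jacobian_model"))
  if (!identical(dim(scan$data)[1:2],
                 c(A$geometry$n_scan_x, A$geometry$n_scan_y)) ||
      dim(scan$data)[3] != nrow(A$offsets))
    stop("scan and Jacobian geometries do not match")
  say <- function(...) if (verbose) message(...)
  cl <- match.call()
  if (scan$power != 1) {
    say("normalizing by excitation power (", scan$power, " mW)")
    scan <- normalize_by_power(scan)
  }
  say("median noise filter")
  scan <- median_noise_filter(scan)
  say("center-detector source-signal gate (mean - 2 SD)")
  gate <- center_detector_gate(scan)
  reference <- gate$image * gate$mask
  b <- flatten_scan(scan, included_only = TRUE)
  M <- A$matrix
  gram <- if (is.null(gram)) make_gram(M, b)
          else if (is.matrix(gram)) make_gram(M, b, G = gram)
          else make_gram(M, b, G = gram$G, eigmax = gram$eigmax)
  schedules <- list()
  if (is.null(lambda)) {
    say("selecting lambda: L-curve corner")
    lc <- l_curve_select(A, b, candidates = lambda_candidates, gram = gram,
                         tol = search_tol, max_iter = search_max_iter)
    schedules$l_curve <- lc
    lambda <- lc$lambda
    warm <- as.vector(lc$solutions[[which(lc$schedule$lambda == lambda)]]$values)
    if (!is.null(finetune_factors)) {
      say("fine-tuning lambda by mutual information around ", signif(lambda, 3))
      ft <- mi_fine_tune(A, b, lambda, reference,
                         factors = finetune_factors, bins = bins,
                         n_thresholds = n_thresholds, gram = gram,
                         tol = search_tol, max_iter = search_max_iter)
      schedules$mi_fine_tune <- ft
      lambda <- ft$lambda
      warm <- as.vector(ft$solutions[[ft$best]]$values)
    }
  } else warm <- NULL
  say("final solve at lambda = ", signif(lambda, 4))
  recon <- solve_l1(A, b, lambda, tol = tol, max_iter = max_iter,
                    x0 = warm, gram = gram)
  say("mutual-information threshold scan")
  report <- if (any(recon$values > 0))
    mi_threshold_scan(recon, reference, thresholds = n_thresholds,
                      bins = bins)
  else NULL
  structure(list(recon = recon, report = report, lambda = lambda,
                 schedules = schedules, gate = gate, scan = scan, b = b,
                 A = A, call = cl),
            class = "mfmt_recon")
}

#' @export
print.mfmt_recon <- function(x, ...) {
  cat("Mesoscopic fluorescence tomography reconstruction\n")
  cat(sprintf("  lambda = %.4g (%s)\n", x$lambda,
              if (length(x$schedules)) paste(names(x$schedules),
                                             collapse = " + ")
              else "fixed"))
  print(x$recon)
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' @export
summary.mfmt_recon <- function(object, ...) {
  r <- object$recon
  g <- r$grid
  out <- list(
    lambda = object$lambda,
    stages = names(object$schedules),
    iterations = r$iterations,
    converged = r$converged,
    objective = r$objective,
    residual_norm = r$residual_norm,
    l1_norm = r$l1_norm,
    n_voxels_positive = sum(r$values > 0),
    n_voxels_masked = if (!is.null(object$report)) object$report$n_voxels
                      else NA_integer_,
    integrated_signal = if (!is.null(object$report))
      integrated_signal(r, object$report) else NA_real_,
    volume_mm3 = if (!is.null(object$report))
      tumor_volume(r, object$report) else NA_real_,
    median_cut = object$scan$meta$median_cut,
    gate_lower = object$gate$lower,
    grid = sprintf("%d x %d x %d voxels", g$nx, g$ny, g$nz))
  class(out) <- "summary.mfmt_recon"
  out
}

#' @export
print.summary.mfmt_recon <- function(x, ...) {
  cat("Reconstruction summary\n")
  cat(sprintf("  grid: %s; lambda = %.4g via %s\n", x$grid, x$lambda,
              if (length(x$stages)) paste(x$stages, collapse = " + ")
              else "fixed lambda"))
  cat(sprintf("  solver: %d iterations, %s; objective %.6g (residual %.4g, L1 %.4g)\n",
              x$iterations, if (x$converged) "converged" else "not converged",
              x$objective, x$residual_norm, x$l1_norm))
  cat(sprintf("  preprocessing: median cut %.4g, center-detector gate lower bound %.4g\n",
              x$median_cut, x$gate_lower))
  cat(sprintf("  thresholded: %d voxels, integrated signal %.4g a.u., volume %.4g mm^3\n",
              x$n_voxels_masked, x$integrated_signal, x$volume_mm3))
  invisible(x)
}

#' @export
coef.mfmt_recon <- function(object, as_array = TRUE, ...) {
  if (as_array) object$recon$values else as.vector(object$recon$values)
}

#' @export
fitted.mfmt_recon <- function(object, ...) {
  M <- object$A$matrix
  drop(M %*% as.vector(object$recon$values))
}

#' @export
residuals.mfmt_recon <- function(object, ...) {
  object$b - fitted(object)
}

#' Predict measurements for a fluorophore map
#'
#' With no `newdata`, returns the fitted measurement vector `A x_hat`.
#' With `newdata` (a [phantom_scene()] or a 3D density map on the model
#' grid) returns its forward projection over all modeled detectors.
#'
#' @param object An `mfmt_recon` fit.
#' @param newdata Optional [phantom_scene()] or 3D array.
#' @param ... Unused.
#' @export
predict.mfmt_recon <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  x <- if (inherits(newdata, "phantom_scene")) rasterize_scene(newdata)
       else newdata
  forward_project(object$A, x)
}

#' Simulate noisy measurement replicates from a fit
#'
#' Draws `nsim` replicates of the fitted measurement vector under the
#' relative-Gaussian noise model, at the noise level recorded in the scan
#' metadata (or `level`).
#'
#' @param object An `mfmt_recon` fit.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param level Relative noise SD; default: the scan's recorded level, or
#'   0.01.
#' @param ... Unused.
#' @return A matrix with one column per replicate.
#' @export
simulate.mfmt_recon <- function(object, nsim = 1, seed = 1, level = NULL,
                                ...) {
  if (is.null(level))
    level <- if (!is.null(object$scan$meta$noise_level))
      object$scan$meta$noise_level else 0.01
  mu <- fitted(object)
  out <- matrix(0, length(mu), nsim)
  for (i in seq_len(nsim))
    out[, i] <- add_noise(mu, "gaussian_relative", level, seed + i - 1L)
  out
}

#' Plot a reconstruction as its maximum intensity projection
#'
#' Displays the MIP of the (optionally thresholded) reconstructed volume
#' in physical coordinates.
#'
#' @param x An `mfmt_recon` fit.
#' @param thresholded Apply the MI-selected mask (default `TRUE` when a
#'   report is present).
#' @param ... Passed to [graphics::image()].
#' @export
plot.mfmt_recon <- function(x, thresholded = !is.null(x$report), ...) {
  vol <- x$recon$values
  if (thresholded && !is.null(x$report)) vol <- vol * x$report$mask
  g <- x$recon$grid
  graphics::image(g$xc, g$yc, mip(vol), xlab = "x (mm)", ylab = "y (mm)",
                  main = "Reconstruction MIP", useRaster = TRUE, asp = 1,
                  ...)
  invisible(x)
}
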