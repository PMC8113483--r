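#' Extrapolate the cell count of one histological slice
#'
#' Histology-based ground truth: within a slice, a sub-area `A2` with
#' countable nuclei yields `C_sub` cells; assuming the sub-area's cell
#' density is representative, the whole tumor area `A1` of the slice
#' contains `C_sub * A1 / A2` cells. Density heterogeneity between the
#' counted and extrapolated regions is the dominant uncertainty
#' (~20-30% in practice).
#'
#' @param A1 Total tumor mask area of the slice (mm^2), > 0.
#' @param A2 Counted sub-area (mm^2), 0 < `A2 <= A1`.
#' @param C_sub Cells counted in the sub-area, >= 0.
#' @return Estimated cells in the slice.
#' @examples
#' estimate_slice_cells(1.0, 0.1, 500)  # 5000
#' @export
estimate_slice_cells <- function(A1, A2, C_sub) {
  stopifnot(A1 > 0, A2 > 0, C_sub >= 0)
  if (A2 > A1 + 1e-12)
    stop("counted sub-area A2 (", A2, " mm^2) exceeds the tumor area A1 (",
         A1, " mm^2)")
  C_sub * A1 / A2
}

#' Total tumor cell count from serial sections
#'
#' Sums the per-slice extrapolations over all histological sections of a
#' tumor.
#'
#' @param slices A list where each element has `A1`, `A2`, `C_sub`
#'   (see [estimate_slice_cells()]), or a data frame with those columns.
#' @return Total estimated cells.
#' @export
tumor_total_cells <- function(slices) {
  if (is.data.frame(slices))
    slices <- lapply(seq_len(nrow(slices)), function(i) as.list(slices[i, ]))
  stopifnot(length(slices) >= 1)
  sum(vapply(slices, function(s)
    estimate_slice_cells(s$A1, s$A2, s$C_sub), numeric(1)))
}

#' Fit the signal-to-cell-count calibration
#'
#' Ordinary least squares of ground-truth cell counts against integrated
#' reconstruction signal over independent tumors (n = 8 in the reference
#' calibration). The linear fit converts reconstructed signal to absolute
#' cell numbers; `R^2` and RMSE (in the cell-count scale) quantify the fit.
#'
#' @param signal Integrated reconstruction signal per tumor (a.u., >= 0).
#' @param cells Ground-truth cell counts.
#' @return An object of class `mfmt_calibration` wrapping the `lm` fit,
#'   with `slope`, `intercept`, `r_squared`, `rmse`, `n`.
#' @export
fit_calibration <- function(signal, cells) {
  stopifnot(length(signal) == length(cells), length(signal) >= 3,
            all(signal >= 0))
  if (diff(range(signal)) == 0)
    stop("all signal values are equal: calibration design is rank-deficient")
  fit <- stats::lm(cells ~ signal)
  structure(list(fit = fit,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 n = length(signal)),
            class = "mfmt_calibration")
}

#' @export
print.mfmt_calibration <- function(x, ...) {
  cat(sprintf(
    "Cell-count calibration (n = %d): cells = %.4g * signal + %.4g\n",
    x$n, x$slope, x$intercept))
  cat(sprintf("  R^2 = %.3f, RMSE = %.4g cells\n", x$r_squared, x$rmse))
  invisible(x)
}

#' @export
coef.mfmt_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.mfmt_calibration <- function(object, signal, ...) {
  if (inherits(signal, "data.frame"))
    return(stats::predict(object$fit, signal))
  object$intercept + object$slope * signal
}

#' Integrated reconstruction signal inside the final mask
#'
#' Sum of reconstructed voxel values surviving the threshold -- the
#' quantity the cell-count calibration is built on.
#'
#' @param recon A `recon_volume` (or 3D array).
#' @param report A `threshold_report` whose mask matches the volume.
#' @return Integrated signal (a.u.).
#' @export
integrated_signal <- function(recon, report) {
  vol <- if (inherits(recon, "recon_volume")) recon$values else recon
  stopifnot(inherits(report, "threshold_report"),
            identical(dim(vol), dim(report$mask)))
  sum(vol[report$mask])
}

#' Thresholded tumor volume
#'
#' Surviving-voxel count times voxel volume (mm^3). Volume estimates
#' depend critically on the thresholding stage; relative changes over time
#' are more reliable than absolute values.
#'
#' @param recon A `recon_volume` carrying its grid (or a 3D array, in
#'   which case `grid` must be given).
#' @param report A `threshold_report`.
#' @param grid A [voxel_grid()] when `recon` is a bare array.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(recon, report, grid = NULL) {
  if (inherits(recon, "recon_volume")) grid <- recon$grid
  stopifnot(inherits(report, "threshold_report"), !is.null(grid))
  report$n_voxels * grid$voxel_volume
}

#' Cells per voxel under a calibration
#'
#' Applies the calibration per voxel inside the final mask: each voxel
#' gets `slope * value`, and the intercept is apportioned over the mask in
#' proportion to each voxel's share of the integrated signal -- so the
#' voxel map sums exactly to the calibrated total count.
#'
#' @param recon A `recon_volume`.
#' @param report A `threshold_report`.
#' @param calibration An [fit_calibration()] model.
#' @return 3D array of cells per voxel.
#' @export
calibrated_cell_map <- function(recon, report, calibration) {
  vol <- recon$values * report$mask
  total_sig <- sum(vol)
  out <- calibration$slope * vol
  if (total_sig > 0)
    out <- out + calibration$intercept * vol / total_sig
  out
}

#' Longitudinal summary of reconstructed timepoints
#'
#' Collects per-timepoint integrated signal, calibrated cell count, and
#' thresholded volume (normalized to the first timepoint) for a series of
#' reconstructions of the same animal, carrying the induction (DoX) phase
#' annotations through.
#'
#' @param fits A list of `mfmt_recon` objects (>= 2), chronological.
#' @param calibration Optional [fit_calibration()]; without it the count
#'   columns stay in arbitrary units (`cell_count = NA`).
#' @param days Numeric acquisition days (default `seq_along(fits)`).
#' @param dox Character vector of DoX states (`"on"`/`"off"`), recycled.
#' @return A data frame of class `mfmt_longitudinal` with columns `day`,
#'   `integrated_signal`, `cell_count`, `volume_mm3`, `volume_normalized`,
#'   `dox_state`.
#' @export
longitudinal_summary <- function(fits, calibration = NULL, days = NULL,
                                 dox = NA_character_) {
  stopifnot(is.list(fits), length(fits) >= 2)
  grids <- lapply(fits, function(f) f$recon$grid)
  for (g in grids[-1])
    if (!identical(g[c("nx", "ny", "nz", "voxel_size")],
                   grids[[1]][c("nx", "ny", "nz", "voxel_size")]))
      stop("inconsistent voxel grids across timepoints")
  if (is.null(days)) days <- seq_along(fits)
  stopifnot(length(days) == length(fits), !is.unsorted(days))
  sig <- vapply(fits, function(f)
    integrated_signal(f$recon, f$report), numeric(1))
  vol <- vapply(fits, function(f)
    tumor_volume(f$recon, f$report), numeric(1))
  cells <- if (!is.null(calibration)) predict(calibration, sig)
           else rep(NA_real_, length(fits))
  out <- data.frame(day = days,
                    integrated_signal = sig,
                    cell_count = cells,
                    volume_mm3 = vol,
                    volume_normalized = vol / vol[1],
                    dox_state = rep_len(dox, length(fits)))
  class(out) <- c("mfmt_longitudinal", "data.frame")
  out
}

#' Plot a longitudinal summary
#'
#' Cell count (left axis, log scale) and normalized volume (right axis)
#' against time, with the DoX-on phase shaded.
#'
#' @param x An [longitudinal_summary()] data frame.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mfmt_longitudinal <- function(x, ...) {
  y <- if (all(is.na(x$cell_count))) x$integrated_signal else x$cell_count
  ylab <- if (all(is.na(x$cell_count))) "integrated signal (a.u.)"
          else "cell count"
  graphics::plot(x$day, y, type = "o", pch = 16, log = "y",
                 xlab = "day", ylab = ylab, ...)
  on_idx <- which(x$dox_state == "on")
  if (length(on_idx))
    graphics::rect(min(x$day[on_idx]), min(y) * 0.5, max(x$day[on_idx]),
                   max(y) * 2, col = grDevices::adjustcolor("blue", 0.08),
                   border = NA)
  graphics::par(new = TRUE)
  graphics::plot(x$day, x$volume_normalized, type = "o", pch = 1, lty = 2,
                 axes = FALSE, xlab = "", ylab = "", col = "darkred")
  graphics::axis(4, col.axis = "darkred")
  graphics::mtext("normalized volume", side = 4, line = 2.5,
                  col = "darkred", cex = 0.9)
  invisible(x)
}
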