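#' Median noise filter on raw data
#'
#' Removes system-level background by zeroing every value strictly below
#' the median intensity computed over all measurement-vector data points
#' (the included detectors; 80,688 points for the default 41 x 41 scan with
#' 48 detectors). The cut is applied to the whole raw array, center
#' detector included, and the median is recorded in the scan metadata.
#'
#' @param scan A [raw_scan()].
#' @return The filtered [raw_scan()] with `meta$median_cut` set.
#' @export
median_noise_filter <- function(scan) {
  stopifnot(inherits(scan, "raw_scan"))
  if (length(scan$data) == 0) stop("empty scan")
  med <- stats::median(flatten_scan(scan, included_only = TRUE))
  scan$data[scan$data < med] <- 0
  scan$meta$median_cut <- med
  scan
}

#' Source-signal gate from the center-detector image
#'
#' The zero-separation (center) detector sees the least-diffused signal, so
#' its image across the scan grid localizes the fluorescence sources. To
#' suppress the diffuse halo, scan positions are kept only where the
#' center-detector value lies between `mean - 2 * SD` (population SD over
#' the image) and the maximum. A zero-variance image passes everywhere,
#' with a warning.
#'
#' @param scan A [raw_scan()] whose geometry retains the center detector.
#' @return A list: `mask` (logical `n_scan_x x n_scan_y`), `image` (the
#'   center-detector image), `mean`, `sd`, `lower` (`mean - 2 SD`).
#' @export
center_detector_gate <- function(scan) {
  stopifnot(inherits(scan, "raw_scan"))
  off <- kept_offsets(scan$geometry)
  ci <- which(off$is_center)
  if (length(ci) != 1L)
    stop("no center (zero-separation) detector in this geometry")
  img <- matrix(scan$data[, , ci], dim(scan$data)[1], dim(scan$data)[2])
  mu <- mean(img)
  sd_pop <- sqrt(mean((img - mu)^2))
  if (sd_pop == 0) {
    warning("zero-variance center-detector image; all scan positions kept")
    mask <- array(TRUE, dim = dim(img))
  } else {
    mask <- img >= mu - 2 * sd_pop & img <= max(img)
  }
  list(mask = mask, image = img, mean = mu, sd = sd_pop,
       lower = mu - 2 * sd_pop)
}

#' Mutual information between two images
#'
#' Estimates `MI = sum p(a,b) log2[p(a,b) / (p(a) p(b))]` in bits from the
#' joint histogram of the two images after min-max scaling each to [0, 1]
#' over `bins` equal-width bins. Zero-count bins contribute nothing. The
#' estimator is symmetric and `MI(X, X)` equals the histogram entropy of
#' `X`.
#'
#' @param img_a,img_b Numeric arrays of identical shape.
#' @param bins Number of histogram bins per image (default 64, >= 2).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(img_a, img_b, bins = 64) {
  if (!identical(dim(img_a), dim(img_b)) || length(img_a) != length(img_b))
    stop("images must have identical shapes (got ",
         paste(dim(img_a), collapse = "x"), " vs ",
         paste(dim(img_b), collapse = "x"), ")")
  stopifnot(bins >= 2)
  bin_index <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep(1L, length(v)))
    pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * bins) + 1L, bins)
  }
  ia <- bin_index(as.vector(img_a))
  ib <- bin_index(as.vector(img_b))
  joint <- table(factor(ia, levels = 1:bins), factor(ib, levels = 1:bins))
  p <- joint / sum(joint)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
}

#' Maximum intensity projection
#'
#' Per-(x, y) maximum of a 3D volume over z.
#'
#' @param volume 3D numeric array, or a `recon_volume`.
#' @return Matrix `nx x ny`.
#' @export
mip <- function(volume) {
  if (inherits(volume, "recon_volume")) volume <- volume$values
  stopifnot(length(dim(volume)) == 3L)
  apply(volume, c(1, 2), max)
}

# Bilinear resampling of a 2D image to a target size, sampling both on
# pixel-center normalized coordinates.
resample_bilinear <- function(img, nx_out, ny_out) {
  nx <- nrow(img); ny <- ncol(img)
  if (nx == nx_out && ny == ny_out) return(img)
  map <- function(n_out, n_in) {
    u <- ((seq_len(n_out) - 0.5) / n_out) * n_in + 0.5  # input index space
    pmin(pmax(u, 1), n_in)
  }
  ux <- map(nx_out, nx); uy <- map(ny_out, ny)
  x0 <- pmin(floor(ux), nx - 1L); fx <- ux - x0
  y0 <- pmin(floor(uy), ny - 1L); fy <- uy - y0
  out <- matrix(0, nx_out, ny_out)
  for (j in seq_len(ny_out)) {
    c0 <- img[, y0[j]]; c1 <- img[, y0[j] + 1]
    col <- c0 * (1 - fy[j]) + c1 * fy[j]
    out[, j] <- col[x0] * (1 - fx) + col[x0 + 1] * fx
  }
  out
}

#' Mutual-information threshold scan of a reconstruction
#'
#' The unbiased thresholding stage: the reconstruction is thresholded at a
#' grid of candidate values, the maximum intensity projection of each
#' thresholded volume is compared to the reference raw image via
#' [mutual_information()], and the threshold attaining the maximum MI is
#' selected. The reference (typically the gated center-detector image) is
#' bilinearly resampled to the MIP's pixel grid when the shapes differ.
#'
#' @param recon A `recon_volume` or 3D array.
#' @param reference 2D reference image.
#' @param thresholds Either a count (linearly spaced thresholds strictly
#'   between 0 and the volume maximum; default 50) or an explicit vector.
#' @param bins Histogram bins for the MI estimator (default 64).
#' @return An object of class `threshold_report`: `thresholds`, `mi`,
#'   `chosen` (argmax-MI threshold), `mask` (logical 3D array),
#'   `n_voxels`, `degenerate` (no threshold kept any voxel), plus the MI
#'   settings.
#' @export
mi_threshold_scan <- function(recon, reference, thresholds = 50, bins = 64) {
  vol <- if (inherits(recon, "recon_volume")) recon$values else recon
  stopifnot(length(dim(vol)) == 3L, is.matrix(reference))
  mx <- max(vol)
  if (length(thresholds) == 1L && thresholds == round(thresholds) &&
      thresholds > 1) {
    if (mx <= 0) stop("reconstruction is identically zero; no threshold grid")
    thresholds <- seq(0, mx, length.out = thresholds + 2)[-c(1, thresholds + 2)]
  }
  if (length(thresholds) == 0) stop("empty threshold list")
  ref <- resample_bilinear(reference, dim(vol)[1], dim(vol)[2])
  mi <- vapply(thresholds, function(t) {
    m <- mip(vol * (vol >= t))
    mutual_information(m, ref, bins = bins)
  }, numeric(1))
  chosen <- thresholds[which.max(mi)]
  mask <- vol >= chosen
  degenerate <- all(vapply(thresholds, function(t) !any(vol >= t), logical(1)))
  structure(list(thresholds = thresholds, mi = mi, chosen = chosen,
                 mask = mask, n_voxels = sum(mask), degenerate = degenerate,
                 bins = bins),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    "MI threshold scan: %d thresholds, chosen %.4g (MI %.4g bits), %d voxels kept%s\n",
    length(x$thresholds), x$chosen, max(x$mi), x$n_voxels,
    if (x$degenerate) " [degenerate: all masks empty]" else ""))
  invisible(x)
}

#' Fixed-fraction threshold baseline
#'
#' Thresholds the reconstruction at a fixed fraction of its maximum (50%
#' by default) -- the conventional practice the MI-based scan is designed
#' to replace; provided as a comparison baseline.
#'
#' @param recon A `recon_volume` or 3D array.
#' @param fraction Fraction of the volume maximum (default 0.5).
#' @return A `threshold_report` with a single threshold.
#' @export
fixed_threshold <- function(recon, fraction = 0.5) {
  vol <- if (inherits(recon, "recon_volume")) recon$values else recon
  stopifnot(length(dim(vol)) == 3L, fraction > 0, fraction <= 1)
  t <- fraction * max(vol)
  mask <- vol >= t & vol > 0
  structure(list(thresholds = t, mi = NA_real_, chosen = t, mask = mask,
                 n_voxels = sum(mask), degenerate = !any(mask), bins = NA),
            class = "threshold_report")
}
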