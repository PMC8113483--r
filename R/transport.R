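#' Sample scattering deflection cosines from the Henyey-Greenstein phase
#' function
#'
#' Draws `n` values of `cos(theta)` from the one-parameter Henyey-Greenstein
#' angular distribution with anisotropy `g` (mean cosine `E[cos theta] = g`);
#' `g = 0` reduces to isotropic scattering. Azimuth is uniform and handled
#' inside the Monte-Carlo engine. Uses R's RNG, so `set.seed()` makes draws
#' reproducible.
#'
#' @param n Number of draws.
#' @param g Anisotropy, strictly inside (-1, 1).
#' @return Numeric vector of `cos(theta)` values in `[-1, 1]`.
#' @examples
#' set.seed(1); mean(sample_scatter_cosine(1e5, 0.85))  # ~0.85
#' @export
sample_scatter_cosine <- function(n, g) {
  stopifnot(n >= 1)
  if (abs(g) >= 1) stop("|g| must be < 1 (got g = ", g, ")")
  cpp_hg_cos(as.integer(n), g)
}

#' Monte-Carlo photon transport in a homogeneous slab
#'
#' Runs a CPU Monte-Carlo random walk for a pencil beam entering the slab at
#' `source` on the z = 0 surface, with implicit capture (weight survival
#' `mu_s / (mu_s + mu_a)` per interaction) and Russian roulette below weight
#' 1e-4. Returns the fluence per voxel normalized per launched photon,
#' together with the absorbed / reflected / transmitted weight fractions
#' (which sum to 1 up to roulette noise) and a per-voxel relative-error
#' estimate `1/sqrt(hits)`.
#'
#' The top surface applies Fresnel reflection when `n_rel != 1`; the default
#' is an index-matched boundary (the imaging window's coverslip provides a
#' flat, nearly matched interface).
#'
#' @param scene A [phantom_scene()] supplying slab optics, thickness, and
#'   grid (inclusions do not perturb transport: Born approximation).
#' @param source Surface position `c(x, y)` or `c(x, y, 0)` in mm.
#' @param photons Photons to launch, >= 1e3. Default 1e6.
#' @param seed Integer seed (applied via `set.seed`).
#' @param n_rel Relative refractive index tissue/outside (default 1,
#'   matched).
#' @return An object of class `fluence_map` with elements `values`
#'   (nx x ny x nz array, mm^-2 per photon), `rel_error`, `grid`, `source`,
#'   `photons`, `seed`, and the weight ledger
#'   `absorbed`/`reflected`/`transmitted`.
#' @export
run_mc <- function(scene, source, photons = 1e6, seed = 1, n_rel = 1) {
  stopifnot(inherits(scene, "phantom_scene"), photons >= 1e3)
  if (length(source) == 3L) {
    if (abs(source[3]) > 1e-12)
      stop("source must lie on the z = 0 surface (got z = ", source[3], ")")
    source <- source[1:2]
  }
  stopifnot(length(source) == 2L)
  g <- scene$grid
  op <- scene$props
  set.seed(seed)
  res <- cpp_mc_fluence(c(g$nx, g$ny, g$nz), g$voxel_size, scene$thickness,
                        op$mu_s, op$mu_a, op$g, n_rel,
                        source[1], source[2], as.integer(photons))
  rel <- array(Inf, dim = dim(res$hits))
  nz <- res$hits > 0
  rel[nz] <- 1 / sqrt(res$hits[nz])
  structure(list(values = res$fluence, hits = res$hits, rel_error = rel,
                 grid = g, source = source, photons = photons, seed = seed,
                 absorbed = res$absorbed, reflected = res$reflected,
                 transmitted = res$transmitted),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("Monte-Carlo fluence map: %g photons from (%g, %g) mm, seed %d\n",
              x$photons, x$source[1], x$source[2], x$seed))
  cat(sprintf("  weight: absorbed %.4f, reflected %.4f, transmitted %.4f (sum %.4f)\n",
              x$absorbed, x$reflected, x$transmitted,
              x$absorbed + x$reflected + x$transmitted))
  invisible(x)
}

#' Diffusion-approximation Green's function (semi-infinite slab)
#'
#' Steady-state fluence at `r` due to an isotropic unit point source at
#' `r_src` in a semi-infinite homogeneous medium, using the
#' extrapolated-boundary image-source solution:
#' `G = [exp(-mu_eff r1)/r1 - exp(-mu_eff r2)/r2] / (4 pi D)` with
#' `D = 1/(3 (mu_a + mu_s'))`, `mu_eff = sqrt(3 mu_a (mu_a + mu_s'))`, and
#' the image source mirrored across the extrapolated boundary at
#' `z = -zb`, `zb = 2 A D`. A source given on the surface (z = 0) is
#' represented as a point source at the transport depth
#' `z0 = 1/(mu_a + mu_s')`, the standard pencil-beam reduction. This closed
#' form doubles as the fast Jacobian engine and as a verification oracle
#' for the Monte-Carlo engine.
#'
#' @param props [optical_properties()].
#' @param r_src Source position `c(x, y, z)` in mm (z >= 0).
#' @param r Field position(s): length-3 vector or an `n x 3` matrix.
#' @param A_boundary Boundary mismatch parameter A in `zb = 2 A D`
#'   (default 1: index-matched).
#' @return Fluence value(s), mm^-2 per unit source power.
#' @export
diffusion_green <- function(props, r_src, r, A_boundary = 1) {
  stopifnot(inherits(props, "optical_properties"), length(r_src) == 3L)
  musp <- reduced_scattering(props)
  if (musp <= 0) stop("reduced scattering must be positive")
  mut <- props$mu_a + musp
  D <- 1 / (3 * mut)
  mueff <- sqrt(3 * props$mu_a * mut)
  zb <- 2 * A_boundary * D
  if (is.null(dim(r))) r <- matrix(r, ncol = 3)
  if (r_src[3] < 0 || any(r[, 3] < 0))
    stop("both points must lie inside the medium (z >= 0)")
  zs <- if (r_src[3] == 0) 1 / mut else r_src[3]
  rho2 <- (r[, 1] - r_src[1])^2 + (r[, 2] - r_src[2])^2
  r1 <- sqrt(rho2 + (r[, 3] - zs)^2)
  r2 <- sqrt(rho2 + (r[, 3] + zs + 2 * zb)^2)
  if (any(r1 < 1e-9))
    stop("field point coincides with the source singularity")
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
}
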