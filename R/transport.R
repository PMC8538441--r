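#' Monte Carlo sampling primitives
#'
#' The elementary random-sampling steps of the photon random walk, exposed
#' for inspection and testing; [run_monte_carlo()] uses the identical
#' compiled routines internally.
#'
#' * `sample_step(xi, mu_tot)`: free path length `-ln(xi) / mu_tot` (mm) from
#'   the exponential attenuation law.
#' * `sample_deflection(xi, g)`: deflection cosine from the Henyey-Greenstein
#'   phase function (inverse CDF); `g = 0` reduces to the isotropic `2 xi - 1`.
#' * `sample_azimuth(xi)`: azimuth `2 pi xi` in radians.
#' * `update_direction(dir, cos_theta, psi)`: rotate a unit direction vector
#'   by the sampled deflection and azimuth (norm-preserving spherical
#'   rotation with the usual special case near the z pole).
#' * `deposit_weight(W, mu_a, mu_tot)`: absorbed weight fraction
#'   `W mu_a / mu_tot` dropped at an interaction site.
#'
#' @param xi Random deviate(s) in (0, 1).
#' @param mu_tot Total attenuation coefficient (1/mm), > 0.
#' @param g Anisotropy factor in `[-1, 1]`.
#' @param dir Unit direction vector, length 3.
#' @param cos_theta Deflection cosine in `[-1, 1]`.
#' @param psi Azimuth in radians.
#' @param W Photon weight (> 0).
#' @param mu_a Absorption coefficient, `0 <= mu_a <= mu_tot`.
#' @return `sample_step`, `sample_deflection`, `sample_azimuth` and
#'   `deposit_weight` return numeric vectors; `update_direction` returns a
#'   unit vector of length 3.
#' @name mc_sampling
#' @examples
#' sample_step(exp(-1), mu_tot = 1)   # exactly 1 mm
#' sample_deflection(0.5, g = 0)      # 0: isotropic median
#' @export
sample_step <- function(xi, mu_tot) {
  if (any(xi <= 0 | xi >= 1))
    stop("xi must lie strictly in (0, 1); xi = 0 must be resampled",
         call. = FALSE)
  if (mu_tot <= 0)
    stop("mu_tot must be positive (mu_tot = 0 means free streaming)",
         call. = FALSE)
  mc_sample_step_cpp(as.numeric(xi), mu_tot)
}

#' @rdname mc_sampling
#' @export
sample_deflection <- function(xi, g) {
  stopifnot(all(xi >= 0 & xi <= 1), g >= -1, g <= 1)
  mc_sample_deflection_cpp(as.numeric(xi), g)
}

#' @rdname mc_sampling
#' @export
sample_azimuth <- function(xi) {
  stopifnot(all(xi >= 0 & xi <= 1))
  mc_sample_azimuth_cpp(as.numeric(xi))
}

#' @rdname mc_sampling
#' @export
update_direction <- function(dir, cos_theta, psi) {
  stopifnot(length(dir) == 3, abs(sum(dir^2) - 1) < 1e-9,
            cos_theta >= -1, cos_theta <= 1)
  mc_update_direction_cpp(as.numeric(dir), cos_theta, psi)
}

#' @rdname mc_sampling
#' @export
deposit_weight <- function(W, mu_a, mu_tot) {
  stopifnot(all(W > 0), mu_a >= 0, mu_tot >= mu_a, mu_tot > 0)
  W * mu_a / mu_tot
}

#' Run Monte Carlo photon transport
#'
#' Launches photons uniformly over a top-hat disc at the surface (normal
#' incidence) and propagates them by the hop-drop-spin cycle: a sampled
#' optical depth is consumed across voxels in proportion to the local total
#' attenuation coefficient (unbiased heterogeneous stepping), the absorbed
#' weight fraction is deposited at each interaction, and a new direction is
#' drawn from the Henyey-Greenstein phase function. Low-weight photons are
#' terminated by Russian roulette; photons leaving any face are tallied as
#' escaped. Layer interfaces are index-matched (no Fresnel reflection).
#'
#' The result is normalized per launched photon, so the deposited array is
#' the fraction of incident beam energy absorbed per voxel and
#' `sum(deposited) + escaped` is 1 up to roulette noise.
#'
#' @param geom A `layered_geometry`.
#' @param n_photons Number of photons to launch (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param beam_diameter Beam diameter (mm); defaults to the tumor diameter
#'   (or the full domain for slab geometries).
#' @param beam_center Beam axis position `c(x, y)` in mm; defaults to the
#'   tumor axis (domain center for slabs).
#' @param w_min Roulette weight threshold.
#' @param p_survive Roulette survival probability.
#' @return An `absorption_grid`: list with `deposited` (array, fraction of
#'   launched energy per voxel), `escaped`, `n_photons`, `seed`, `beam`.
#' @examples
#' slab <- build_slab(optical_properties(1, 0, 0), extent = c(10, 10, 10),
#'                    voxel = 1)
#' ag <- run_monte_carlo(slab, n_photons = 1000, seed = 7, beam_diameter = 2)
#' sum(ag$deposited) + ag$escaped  # ~1
#' @export
run_monte_carlo <- function(geom, n_photons, seed = 1,
                            beam_diameter = NULL, beam_center = NULL,
                            w_min = 1e-4, p_survive = 0.1) {
  stopifnot(inherits(geom, "layered_geometry"))
  if (n_photons < 1) stop("n_photons must be >= 1", call. = FALSE)
  if (is.null(beam_diameter))
    beam_diameter <- if (!is.null(geom$tumor)) 2 * geom$tumor$radius
                     else geom$nx * geom$dx
  if (is.null(beam_center))
    beam_center <- if (!is.null(geom$tumor)) geom$tumor$center
                   else c(geom$nx * geom$dx / 2, geom$ny * geom$dy / 2)
  if (beam_diameter > min(geom$nx * geom$dx, geom$ny * geom$dy))
    stop("beam diameter exceeds the domain width", call. = FALSE)

  ids <- geom$material
  # per-id optical property lookup tables, id 0 = inert
  mu_a <- c(0, geom$materials$mu_a)
  mu_s <- c(0, geom$materials$mu_s)
  g <- c(0, geom$materials$g)
  res <- mc_run_transport_cpp(
    as.integer(ids), geom$nx, geom$ny, geom$nz, geom$dx, geom$dy,
    geom$z_edges, mu_a, mu_s, g,
    beam_diameter / 2, beam_center[1], beam_center[2],
    as.integer(n_photons), as.numeric(seed), w_min, p_survive)
  structure(list(
    deposited = array(res$deposited, dim = c(geom$nx, geom$ny, geom$nz)),
    escaped = res$escaped, n_photons = n_photons, seed = seed,
    beam = list(diameter = beam_diameter, center = beam_center,
                profile = "top-hat")
  ), class = "absorption_grid")
}

#' @export
print.absorption_grid <- function(x, ...) {
  cat(sprintf(
    "absorption grid: %d photons, %.4f deposited + %.4f escaped (beam %g mm top-hat)\n",
    x$n_photons, sum(x$deposited), x$escaped, x$beam$diameter))
  invisible(x)
}
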