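#' Optical properties of a turbid medium
#'
#' Bundles the absorption coefficient, scattering coefficient and scattering
#' anisotropy factor of a medium. The total attenuation coefficient
#' `mu_a + mu_s` is always derived (see [mu_total()]), never stored.
#'
#' @param mu_a Absorption coefficient (1/mm), non-negative.
#' @param mu_s Scattering coefficient (1/mm), non-negative.
#' @param g Scattering anisotropy factor (mean cosine of the deflection
#'   angle), in `[-1, 1]`; `g = 0` is isotropic scattering.
#' @return An object of class `optical_properties`.
#' @examples
#' tumor <- optical_properties(mu_a = 0.08, mu_s = 1.28, g = 0.925)
#' mu_total(tumor)
#' @export
optical_properties <- function(mu_a, mu_s, g) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g),
            length(mu_a) == 1, length(mu_s) == 1, length(g) == 1)
  if (mu_a < 0 || mu_s < 0)
    stop("optical coefficients must be non-negative", call. = FALSE)
  if (g < -1 || g > 1)
    stop("anisotropy factor g must lie in [-1, 1]", call. = FALSE)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g),
            class = "optical_properties")
}

#' @rdname optical_properties
#' @param x An `optical_properties` object.
#' @export
mu_total <- function(x) {
  stopifnot(inherits(x, "optical_properties"))
  x$mu_a + x$mu_s
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mu_a = %g /mm, mu_s = %g /mm, g = %g\n",
              x$mu_a, x$mu_s, x$g))
  invisible(x)
}

#' Gold nanorod specification
#'
#' Describes the nanorods loaded into the tumor: cylinder dimensions, the
#' dimensionless absorption and scattering efficiencies `Qa`/`Qs`, and the
#' volume fraction `fv` (nanorod volume over tumor volume).
#'
#' @param length_nm Rod length in nm (> 0).
#' @param diameter_nm Rod diameter in nm (> 0).
#' @param Qa,Qs Dimensionless absorption / scattering efficiencies (>= 0).
#' @param fv Volume fraction of nanorods in the tumor (>= 0).
#' @return An object of class `gnr_spec`.
#' @examples
#' gnr_spec(length_nm = 67, diameter_nm = 10, Qa = 1.7, Qs = 0.07, fv = 1e-4)
#' @export
gnr_spec <- function(length_nm, diameter_nm, Qa, Qs, fv) {
  stopifnot(is.numeric(length_nm), is.numeric(diameter_nm),
            is.numeric(Qa), is.numeric(Qs), is.numeric(fv))
  if (length_nm <= 0 || diameter_nm <= 0)
    stop("nanorod dimensions must be positive", call. = FALSE)
  if (Qa < 0 || Qs < 0)
    stop("efficiencies Qa, Qs must be non-negative", call. = FALSE)
  if (fv < 0)
    stop("volume fraction fv must be non-negative", call. = FALSE)
  structure(list(length_nm = length_nm, diameter_nm = diameter_nm,
                 Qa = Qa, Qs = Qs, fv = fv),
            class = "gnr_spec")
}

#' @export
print.gnr_spec <- function(x, ...) {
  cat(sprintf(
    "gold nanorod: %g x %g nm, Qa = %.4g, Qs = %.4g, fv = %g\n",
    x$length_nm, x$diameter_nm, x$Qa, x$Qs, x$fv))
  invisible(x)
}

#' Effective radius of a nanorod
#'
#' Radius of the sphere with the same volume as the cylindrical rod,
#' `r_eff = (3 V / 4 pi)^(1/3)` with `V = pi (d/2)^2 L`.
#'
#' @param spec A [gnr_spec()].
#' @return Effective radius in nm.
#' @examples
#' gnr_effective_radius(gnr_spec(67, 10, 0, 0, 0))  # ~10.79 nm
#' @export
gnr_effective_radius <- function(spec) {
  stopifnot(inherits(spec, "gnr_spec"))
  V <- pi * (spec$diameter_nm / 2)^2 * spec$length_nm
  (3 * V / (4 * pi))^(1 / 3)
}

#' Nanoparticle contribution to the tissue optical coefficients
#'
#' `mu_np = 0.75 fv Q / r_eff`, evaluated separately for absorption and
#' scattering. `r_eff` is converted from nm to mm internally so the result is
#' in 1/mm, consistent with the tissue coefficients.
#'
#' @param spec A [gnr_spec()].
#' @return Named numeric vector `c(mu_a = ..., mu_s = ...)` in 1/mm.
#' @export
nanoparticle_coefficients <- function(spec) {
  stopifnot(inherits(spec, "gnr_spec"))
  r_eff_mm <- gnr_effective_radius(spec) * 1e-6
  c(mu_a = 0.75 * spec$fv * spec$Qa / r_eff_mm,
    mu_s = 0.75 * spec$fv * spec$Qs / r_eff_mm)
}

#' Mix nanoparticle and host-tissue optical properties
#'
#' Additive mixing of absorption and scattering coefficients; the anisotropy
#' factor of the mixture is taken unchanged from the host medium (the
#' nanorod loading perturbs mu_a and mu_s only).
#'
#' @param medium Host [optical_properties()].
#' @param np_mu_a,np_mu_s Nanoparticle coefficients in 1/mm (>= 0).
#' @return Mixed [optical_properties()].
#' @export
mix_optical_properties <- function(medium, np_mu_a, np_mu_s) {
  stopifnot(inherits(medium, "optical_properties"))
  if (np_mu_a < 0 || np_mu_s < 0)
    stop("nanoparticle coefficients must be non-negative", call. = FALSE)
  optical_properties(medium$mu_a + np_mu_a, medium$mu_s + np_mu_s, medium$g)
}

#' Back out an efficiency from a mixed coefficient
#'
#' Inverse of [nanoparticle_coefficients()] + [mix_optical_properties()]:
#' given the mixed coefficient of the loaded tissue and the bare-host
#' coefficient, returns the efficiency `Q = (mu_mixed - mu_medium) * r_eff /
#' (0.75 fv)`. Used to calibrate `Qa`, `Qs` from published mixed-tissue
#' values when the efficiencies themselves are not available.
#'
#' @param mu_mixed Mixed coefficient (1/mm), `>= mu_medium`.
#' @param mu_medium Host coefficient (1/mm).
#' @param fv Volume fraction (> 0).
#' @param r_eff_nm Effective radius in nm (> 0).
#' @return Dimensionless efficiency `Q`.
#' @export
calibrate_efficiency <- function(mu_mixed, mu_medium, fv, r_eff_nm) {
  if (fv <= 0)
    stop("fv must be positive to calibrate an efficiency", call. = FALSE)
  if (mu_mixed < mu_medium)
    stop("mu_mixed < mu_medium would imply a negative efficiency",
         call. = FALSE)
  if (r_eff_nm <= 0)
    stop("r_eff must be positive", call. = FALSE)
  (mu_mixed - mu_medium) * (r_eff_nm * 1e-6) / (0.75 * fv)
}

#' Default calibrated nanorod specification
#'
#' Builds a [gnr_spec()] for the default 67 x 10 nm rods with `Qa`, `Qs`
#' calibrated so that mixing into the bare tumor reproduces the bundled
#' mixed-tissue anchors at the reference volume fraction (1e-3 by default).
#'
#' @param fv Volume fraction of the returned spec.
#' @param materials Material configuration, see [skin_materials()].
#' @return A [gnr_spec()] with calibrated efficiencies.
#' @examples
#' spec <- calibrated_gnr_spec(fv = 1e-4)
#' tumor_optics_with_gnr(1e-4)
#' @export
calibrated_gnr_spec <- function(fv, materials = skin_materials()) {
  gnr <- attr(materials, "gnr")
  tum <- materials[materials$name == "tumor", ]
  base <- gnr_spec(gnr$length_nm, gnr$diameter_nm, Qa = 0, Qs = 0,
                   fv = gnr$anchor_fv)
  r_eff <- gnr_effective_radius(base)
  Qa <- calibrate_efficiency(gnr$anchor_mu_a, tum$mu_a, gnr$anchor_fv, r_eff)
  Qs <- calibrate_efficiency(gnr$anchor_mu_s, tum$mu_s, gnr$anchor_fv, r_eff)
  gnr_spec(gnr$length_nm, gnr$diameter_nm, Qa = Qa, Qs = Qs, fv = fv)
}

#' @rdname calibrated_gnr_spec
#' @export
tumor_optics_with_gnr <- function(fv, materials = skin_materials()) {
  tum <- materials[materials$name == "tumor", ]
  host <- optical_properties(tum$mu_a, tum$mu_s, tum$g)
  if (fv == 0) return(host)
  np <- nanoparticle_coefficients(calibrated_gnr_spec(fv, materials))
  mix_optical_properties(host, np[["mu_a"]], np[["mu_s"]])
}
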