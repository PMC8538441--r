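# Small fixtures and independent oracle helpers shared across test files.

# coarse skin geometry used by several suites (cheap to build)
coarse_skin <- function(fv = 1e-6, voxel = 1) {
  build_skin_stack(fv = fv, voxel = voxel, fine_surface = FALSE)
}

# independent rotation oracle: build an orthonormal frame around u and rotate
# by (cos_theta, psi) explicitly; any correct direction update must agree on
# the deflection cosine and unit norm even if its azimuth convention differs
rotate_via_frame <- function(u, cos_theta, psi) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  st <- sqrt(1 - cos_theta^2)
  st * cos(psi) * e1 + st * sin(psi) * e2 + cos_theta * u
}

# analytic volume of the default tumor cylinder (mm^3)
tumor_cyl_volume <- function(diameter = 10, length = 3.5)
  pi * (diameter / 2)^2 * length

# total thermal energy of a field relative to 0 degC (J)
field_energy <- function(field) sum(field$cap * field$T)

# brute-force hazard weight lookup, independent of the package tables
oracle_hazard_weight <- function(T) {
  vapply(T, function(x) {
    if (x < 43) 1L
    else if (x < 45) 2L
    else if (x < 50) 2L
    else if (x < 70) 3L
    else if (x < 80) 4L
    else if (x < 100) 5L
    else if (x < 150) 6L
    else if (x < 300) 7L
    else 8L
  }, integer(1))
}
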