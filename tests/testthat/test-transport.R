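test_that("free-path sampling follows the exponential attenuation law", {
  expect_equal(sample_step(exp(-1), mu_tot = 1), 1)
  expect_lt(sample_step(1 - 1e-12, mu_tot = 1), 1e-9) # xi -> 1 gives S -> 0
  expect_error(sample_step(0, 1), "resampled")
  expect_error(sample_step(0.5, 0), "positive")
  set.seed(11)
  s <- sample_step(runif(1e5), mu_tot = 2)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 0.5), 3 * se) # E[S] = 1/mu_tot
})

test_that("Henyey-Greenstein deflection has mean g and isotropic limit", {
  expect_equal(sample_deflection(0.5, g = 0), 0)
  expect_equal(sample_deflection(0.75, g = 0), 0.5)
  set.seed(12)
  for (g in c(0.5, 0.9)) {
    ct <- sample_deflection(runif(1e5), g = g)
    expect_true(all(ct >= -1 & ct <= 1))
    se <- sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se) # HG first moment equals g
  }
  # g = 0: cos(theta) uniform on [-1, 1]
  ct0 <- sample_deflection(runif(1e5), g = 0)
  expect_gt(suppressWarnings(
    stats::ks.test(ct0, "punif", -1, 1)$p.value), 0.001)
})

test_that("azimuth is uniform on [0, 2 pi)", {
  expect_equal(sample_azimuth(0), 0)
  expect_equal(sample_azimuth(0.5), pi)
  set.seed(13)
  psi <- sample_azimuth(runif(1e5))
  counts <- table(cut(psi, breaks = seq(0, 2 * pi, length.out = 37)))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.001)
})

test_that("direction update preserves the norm and the deflection angle", {
  d <- c(0, 0, 1)
  expect_equal(update_direction(d, cos_theta = 1, psi = 1.3), d)
  cth <- 0.6
  expect_equal(update_direction(d, cth, psi = 0),
               c(sqrt(1 - cth^2), 0, cth))
  set.seed(14)
  for (rep in 1:50) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    ct <- runif(1, -1, 1); psi <- runif(1, 0, 2 * pi)
    v <- update_direction(u, ct, psi)
    expect_equal(sum(v^2), 1, tolerance = 1e-9)
    expect_equal(sum(u * v), ct, tolerance = 1e-9)
    # oracle frame rotation produces the same deflection cone
    w <- rotate_via_frame(u, ct, psi)
    expect_equal(sum(u * w), ct, tolerance = 1e-9)
  }
})

test_that("weight deposition follows the single-scattering albedo", {
  expect_equal(deposit_weight(1, mu_a = 2, mu_tot = 4), 0.5)
  expect_equal(deposit_weight(0.8, mu_a = 3, mu_tot = 3), 0.8) # pure absorber
  # geometric decay: after n interactions remaining weight = albedo^n
  W <- 1
  for (n in 1:10) W <- W - deposit_weight(W, mu_a = 1, mu_tot = 5)
  expect_equal(W, (4 / 5)^10)
})

test_that("pure-absorber depth profile matches Beer-Lambert", {
  slab <- build_slab(optical_properties(1, 0, 0), extent = c(10, 10, 10),
                     voxel = 0.25)
  n <- 1e5
  ag <- run_monte_carlo(slab, n_photons = n, seed = 3, beam_diameter = 1)
  prof <- apply(ag$deposited, 3, sum)
  z <- slab$z_edges
  p_bin <- exp(-z[-length(z)]) - exp(-z[-1]) # analytic bin masses
  se <- sqrt(p_bin * (1 - p_bin) / n)
  expect_true(all(abs(prof - p_bin) < 3 * se + 1e-12))
})

test_that("launched weight is conserved and runs are seed-deterministic", {
  geom <- coarse_skin(voxel = 1)
  ag1 <- run_monte_carlo(geom, n_photons = 2e4, seed = 5)
  expect_true(all(ag1$deposited >= 0))
  expect_lt(abs(sum(ag1$deposited) + ag1$escaped - 1), 1e-3)
  ag2 <- run_monte_carlo(geom, n_photons = 2e4, seed = 5)
  expect_identical(ag1$deposited, ag2$deposited) # bit-identical same seed
  ag3 <- run_monte_carlo(geom, n_photons = 2e4, seed = 6)
  expect_false(identical(ag1$deposited, ag3$deposited))
  expect_lt(abs(sum(ag3$deposited) - sum(ag1$deposited)), 0.02)
})

test_that("splitting a material into identical sub-layers changes nothing", {
  opt <- optical_properties(0.5, 5, 0.8)
  slab <- build_slab(opt, extent = c(8, 8, 8), voxel = 0.5)
  split <- slab
  split$materials <- rbind(split$materials, split$materials)
  split$materials$name <- c("top", "bottom")
  split$material[, , 9:16] <- 2L
  a <- run_monte_carlo(slab, n_photons = 5e3, seed = 9, beam_diameter = 4)
  b <- run_monte_carlo(split, n_photons = 5e3, seed = 9, beam_diameter = 4)
  expect_identical(a$deposited, b$deposited)
})

test_that("absorption grids combine linearly over photon batches", {
  geom <- coarse_skin(voxel = 1)
  a <- run_monte_carlo(geom, n_photons = 1e4, seed = 21)
  b <- run_monte_carlo(geom, n_photons = 1e4, seed = 22)
  ab <- (a$deposited + b$deposited) / 2
  c2 <- run_monte_carlo(geom, n_photons = 2e4, seed = 23)
  # agreement within Monte Carlo sampling error on the total absorbed
  expect_lt(abs(sum(ab) - sum(c2$deposited)), 0.02)
})

test_that("invalid beams and geometries are rejected", {
  geom <- coarse_skin(voxel = 1)
  expect_error(run_monte_carlo(geom, n_photons = 0), ">= 1")
  expect_error(run_monte_carlo(geom, n_photons = 10, beam_diameter = 50),
               "exceeds")
})
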