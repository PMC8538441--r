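test_that("stability timestep matches the homogeneous closed form", {
  mk <- function(voxel) thermal_field(build_slab(
    optical_properties(1, 0, 0), rho = 1000, cp = 4000, k = 0.5,
    extent = c(6, 6, 6), voxel = voxel))
  f1 <- mk(0.5)
  d <- 0.5e-3
  expect_equal(stability_timestep(f1), 0.5 * 1000 * 4000 * d^2 / (6 * 0.5))
  # halving the voxel size quarters the timestep
  f2 <- mk(0.25)
  expect_equal(stability_timestep(f2), stability_timestep(f1) / 4)
})

test_that("stability timestep on the skin stack equals an exhaustive scan", {
  geom <- coarse_skin(voxel = 1)
  field <- thermal_field(geom)
  # independent recomputation: per-voxel capacity over summed face conductances
  mats <- geom$materials
  kth <- c(0, mats$k)[geom$material + 1L]; dim(kth) <- dim(geom$material)
  rhocp <- c(0, mats$rho * mats$cp)[geom$material + 1L]
  dim(rhocp) <- dim(geom$material)
  d <- 1e-3 # 1 mm voxels in metres
  nx <- geom$nx; ny <- geom$ny; nz <- geom$nz
  worst <- Inf
  for (i in seq_len(nx)) for (j in seq_len(ny)) for (k in seq_len(nz)) {
    gsum <- 0
    for (nb in list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                    c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))) {
      if (all(nb >= 1) && nb[1] <= nx && nb[2] <= ny && nb[3] <= nz) {
        k1 <- kth[i, j, k]; k2 <- kth[nb[1], nb[2], nb[3]]
        gsum <- gsum + 2 * k1 * k2 / (k1 + k2) * d^2 / d
      }
    }
    worst <- min(worst, rhocp[i, j, k] * d^3 / gsum)
  }
  expect_equal(stability_timestep(field), 0.5 * worst)
})

test_that("uniform field with no source stays exactly unchanged", {
  field <- thermal_field(coarse_skin(voxel = 1), T_init = 37)
  out <- step_temperature(field, 0, dt = stability_timestep(field))
  expect_identical(out$T, field$T)
})

test_that("steps above the stability limit are refused", {
  field <- thermal_field(build_slab(optical_properties(1, 0, 0),
                                    extent = c(4, 4, 4), voxel = 1))
  expect_error(step_temperature(field, 0, dt = field$dt_limit * 2),
               "stability")
})

test_that("two-voxel relaxation matches the analytic linear system", {
  slab <- build_slab(optical_properties(1, 0, 0), rho = 1000, cp = 4000,
                     k = 0.5, extent = c(1, 1, 2), voxel = 1)
  field <- thermal_field(slab, T_init = array(c(0, 100), dim = c(1, 1, 2)))
  G <- 0.5 * (1e-3 * 1e-3) / 1e-3 # k * A / d for 1 mm voxels
  C <- 1000 * 4000 * 1e-9
  dt <- stability_timestep(field)
  expect_equal(field$dt_limit, C / G)
  # analytic: temperature difference decays by (1 - dt G (1/C1 + 1/C2))
  decay <- 1 - dt * G * 2 / C
  E0 <- field_energy(field)
  f <- field
  for (n in 1:50) f <- step_temperature(f, 0, dt)
  expect_equal(diff(as.vector(f$T)), 100 * decay^50, tolerance = 1e-10)
  expect_equal(field_energy(f), E0, tolerance = 1e-12) # adiabatic energy
  expect_equal(mean(f$T), 50) # capacity-weighted mean is invariant
})

test_that("source energy is booked exactly under adiabatic boundaries", {
  slab <- build_slab(optical_properties(1, 0, 0), extent = c(3, 3, 3),
                     voxel = 1)
  field <- thermal_field(slab, T_init = 20)
  q <- array(0, dim = dim(field$T)); q[2, 2, 2] <- 0.05 # W
  dt <- stability_timestep(field)
  f <- field
  for (n in 1:20) f <- step_temperature(f, q, dt)
  expect_equal(field_energy(f) - field_energy(field), 0.05 * dt * 20,
               tolerance = 1e-10)
})

test_that("zero-source steps obey the discrete maximum principle", {
  slab <- build_slab(optical_properties(1, 0, 0), extent = c(4, 4, 4),
                     voxel = 1)
  set.seed(31)
  field <- thermal_field(slab, T_init = array(runif(64, 0, 100),
                                              dim = c(4, 4, 4)))
  f <- field
  lim <- f$dt_limit
  for (n in seq_len(1e4)) {
    dt <- runif(1, 0, lim)
    g <- step_temperature(f, 0, dt)
    expect_true(min(g$T) >= min(f$T) - 1e-12)
    expect_true(max(g$T) <= max(f$T) + 1e-12)
    f <- g
  }
  expect_equal(field_energy(f), field_energy(field), tolerance = 1e-10)
})

test_that("two-material steady state reproduces harmonic-mean interface flux", {
  # 1-D wall: 5 voxels of k1 = 0.2 then 5 of k2 = 0.6, ends held at 0 / 100
  slab <- build_slab(optical_properties(1, 0, 0), rho = 1000, cp = 1000,
                     k = 0.2, extent = c(1, 1, 10), voxel = 1)
  slab$materials <- rbind(slab$materials, slab$materials)
  slab$materials$k <- c(0.2, 0.6)
  slab$materials$name <- c("a", "b")
  slab$material[, , 6:10] <- 2L
  field <- thermal_field(slab)
  field$T[] <- seq(0, 100, length.out = 10)
  field$T[1, 1, 1] <- 0; field$T[1, 1, 10] <- 100
  fixed <- array(FALSE, dim = c(1, 1, 10)); fixed[1, 1, c(1, 10)] <- TRUE
  dt <- stability_timestep(field)
  f <- field
  for (n in 1:4000) f <- step_temperature(f, 0, dt, fixed = fixed)

  # independent steady oracle: solve the tridiagonal conduction system
  A_m2 <- 1e-6; d_m <- 1e-3
  kv <- c(rep(0.2, 5), rep(0.6, 5))
  G <- 2 * kv[-10] * kv[-1] / (kv[-10] + kv[-1]) * A_m2 / d_m
  M <- matrix(0, 8, 8); b <- numeric(8)
  for (r in 1:8) {
    v <- r + 1
    M[r, r] <- -(G[v - 1] + G[v])
    if (r > 1) M[r, r - 1] <- G[v - 1] else b[r] <- b[r] - G[v - 1] * 0
    if (r < 8) M[r, r + 1] <- G[v] else b[r] <- b[r] - G[v] * 100
  }
  T_oracle <- c(0, solve(M, b), 100)
  expect_equal(as.vector(f$T), T_oracle, tolerance = 1e-6)
  # steady flux across every face equals the series-resistance value
  flux <- G * diff(T_oracle)
  expect_lt(diff(range(flux)) / mean(flux), 1e-6)
  expect_equal(mean(flux), 100 / sum(1 / G), tolerance = 1e-9)
  # homogeneous half has a linear profile
  expect_equal(diff(diff(T_oracle[1:5])), rep(0, 3), tolerance = 1e-9)
})

test_that("probe extraction is exact at voxel centers and interpolates", {
  geom <- build_slab(optical_properties(0.5, 0, 0), extent = c(4, 4, 4),
                     voxel = 1)
  ag <- run_monte_carlo(geom, n_photons = 2000, seed = 2, beam_diameter = 2)
  ser <- run_treatment(geom, ag, treatment_schedule(100, 5, 5, 10),
                       T_init = 20, snapshot_interval = 5, record = "full")
  cen <- voxel_centers(geom)
  tr <- probe_series(ser, data.frame(x = cen$x[2], y = cen$y[2], z = cen$z[2]))
  expect_equal(tr[, 1], ser$snapshots[2 + 4 * (1 + 4 * 1) + 0, ])
  # trilinear midway between two voxel centers is the arithmetic mean
  mid <- probe_series(ser, data.frame(x = 1.0, y = cen$y[2], z = cen$z[2]),
                      method = "trilinear")
  v1 <- ser$snapshots[1 + 4 * (1 + 4 * 1), ]
  v2 <- ser$snapshots[2 + 4 * (1 + 4 * 1), ]
  expect_equal(mid[, 1], (v1 + v2) / 2)
  expect_error(probe_series(ser, data.frame(x = 99, y = 1, z = 1)), "outside")
})

test_that("rmse matches hand computations and averages probes", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3) + 0.4), 0.4)
  expect_equal(rmse(c(0, 1, 2), c(1, 1, 1)), sqrt(2 / 3))
  m1 <- cbind(c(0, 0), c(0, 0)); m2 <- cbind(c(1, 1), c(3, 3))
  expect_equal(rmse(m1, m2), 2) # mean of per-probe RMSEs 1 and 3
  expect_error(rmse(1:3, 1:4), "equal")
})

test_that("treatment runs are linear in power and cooled runs peak lower", {
  geom <- coarse_skin(voxel = 1)
  ag <- run_monte_carlo(geom, n_photons = 1e4, seed = 4)
  s0 <- run_treatment(geom, ag, treatment_schedule(0, 15, 15, 60),
                      snapshot_interval = 10, record = "masks")
  expect_true(all(s0$snapshots == 37)) # no power, no heating
  sA <- run_treatment(geom, ag, treatment_schedule(200, 15, 15, 60),
                      snapshot_interval = 10, record = "masks")
  sB <- run_treatment(geom, ag, treatment_schedule(400, 15, 15, 60),
                      snapshot_interval = 10, record = "masks")
  expect_equal(sB$snapshots - 37, 2 * (sA$snapshots - 37), tolerance = 1e-9)
  # thermal confinement: pulsed heating peaks below continuous heating
  cont <- run_treatment(geom, ag, treatment_schedule(400, 60, 0, 60),
                        snapshot_interval = 2, record = "masks")
  puls <- run_treatment(geom, ag, treatment_schedule(400, 15, 15, 60),
                        snapshot_interval = 2, record = "masks")
  expect_lt(max(puls$snapshots), max(cont$snapshots))
})
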