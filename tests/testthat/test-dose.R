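test_that("hazard weights follow the printed temperature bands", {
  tbl <- hazard_weight_table()
  expect_equal(tbl$weight, c(1, 2, 2, 3, 4, 5, 6, 7, 8))
  expect_true(all(tbl$upper[-nrow(tbl)] == tbl$lower[-1])) # partition
  expect_equal(hazard_weight(c(20, 37, 42.9, 43, 44.9, 45, 49.9, 50, 69, 70,
                               85, 120, 200, 301)),
               c(1, 1, 1, 2, 2, 2, 2, 3, 3, 4, 5, 6, 7, 8))
  set.seed(41)
  T <- runif(500, 10, 400)
  expect_equal(hazard_weight(T), oracle_hazard_weight(T))
})

test_that("apoptosis ratio counts the strict 43-50 degC band", {
  expect_equal(apoptosis_ratio(rep(46, 10), rep(TRUE, 10)), 1)
  expect_equal(apoptosis_ratio(rep(37, 10), rep(TRUE, 10)), 0)
  T <- c(44, 45, 49.9, 43, 50, 37, 60, 20) # exactly 3 of 8 strictly in band
  expect_equal(apoptosis_ratio(T, rep(TRUE, 8)), 0.375)
  expect_error(apoptosis_ratio(T, rep(FALSE, 8)), "empty")
  # volume weighting
  expect_equal(apoptosis_ratio(c(46, 37), c(TRUE, TRUE), volumes = c(3, 1)),
               0.75)
})

test_that("thermal hazard is the volume-weighted mean band weight", {
  expect_equal(thermal_hazard(rep(37, 5), rep(TRUE, 5)), 1)
  expect_equal(thermal_hazard(rep(60, 5), rep(TRUE, 5)), 3)
  expect_equal(thermal_hazard(c(37, 37, 44, 44), rep(TRUE, 4)), 1.5)
  expect_error(thermal_hazard(37, FALSE), "empty")
  # monotone under voxel-wise temperature increase
  set.seed(42)
  T <- runif(200, 37, 250)
  for (rep in 1:10) {
    bump <- runif(200, 0, 30)
    expect_gte(thermal_hazard(pmin(T + bump, 300), rep(TRUE, 200)),
               thermal_hazard(T, rep(TRUE, 200)))
  }
})

test_that("time averaging integrates the snapshot series", {
  expect_equal(time_average(rep(0.7, 10), seq(0, 90, 10)), 0.7)
  expect_equal(time_average(c(0, 1), c(0, 360)), 0.5)
  expect_equal(time_average(5, 0), 5) # single snapshot
  expect_error(time_average(numeric(0), numeric(0)), "empty")
  expect_error(time_average(1:3, 1:2), "equal length")
  # refining the sampling interval converges the average (Cauchy)
  f <- function(t) 0.5 + 0.4 * sin(t / 40) * exp(-t / 300)
  t1 <- seq(0, 360, 1); t2 <- seq(0, 360, 0.5)
  expect_lt(abs(time_average(f(t1), t1) - time_average(f(t2), t2)), 1e-3)
})

test_that("effective ratio is the exact quotient", {
  expect_equal(effective_ratio(1, 1), 1)
  expect_equal(effective_ratio(0.5, 1), 0.5)
  expect_equal(effective_ratio(0.8, 1.6), 0.5)
  expect_error(effective_ratio(0.5, 0.5), ">= 1")
  # scaling both starred values leaves the quotient invariant
  expect_equal(effective_ratio(0.3 * 2, 1.2 * 2), effective_ratio(0.3, 1.2))
})

test_that("treatment evaluation matches a brute-force re-computation", {
  geom <- coarse_skin(voxel = 1)
  nvox <- length(geom$material)
  times <- seq(0, 60, 10)
  # synthetic ramp: tumor sweeps through the apoptosis band, ROI warms less
  set.seed(43)
  snaps <- matrix(37, nvox, length(times))
  for (s in seq_along(times)) {
    snaps[which(geom$tumor_mask), s] <- 37 + times[s] / 4 +
      runif(sum(geom$tumor_mask), -2, 2)
    snaps[which(geom$normal_roi_mask), s] <- 37 + times[s] / 8 +
      runif(sum(geom$normal_roi_mask), -1, 1)
  }
  series <- structure(list(times = times, snapshots = snaps,
                           record_idx = NULL, geom = geom),
                      class = "treatment_series")
  rep <- evaluate_treatment(series)

  # independent straightforward oracle
  vol <- voxel_volumes(geom)
  vt <- vol[geom$tumor_mask]; vr <- vol[geom$normal_roi_mask]
  oA <- oH <- numeric(length(times))
  for (s in seq_along(times)) {
    Tt <- snaps[which(geom$tumor_mask), s]
    Tr <- snaps[which(geom$normal_roi_mask), s]
    oA[s] <- sum(vt * (Tt > 43 & Tt < 50)) / sum(vt)
    oH[s] <- sum(vr * oracle_hazard_weight(Tr)) / sum(vr)
  }
  expect_equal(rep$theta_A, oA)
  expect_equal(rep$theta_H, oH)
  trap <- function(y, x) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) /
    (max(x) - min(x))
  expect_equal(rep$theta_A_star, trap(oA, times))
  expect_equal(rep$theta_H_star, trap(oH, times))
  expect_equal(rep$theta_A_eff_star, rep$theta_A_star / rep$theta_H_star)
  expect_true(all(rep$theta_A >= 0 & rep$theta_A <= 1))
  expect_true(all(rep$theta_H >= 1 & rep$theta_H <= 8))
})

test_that("constant uniform fields give the identity dose report", {
  geom <- coarse_skin(voxel = 1)
  nvox <- length(geom$material)
  mk <- function(T_tum, T_roi) {
    snaps <- matrix(37, nvox, 3)
    snaps[which(geom$tumor_mask), ] <- T_tum
    snaps[which(geom$normal_roi_mask), ] <- T_roi
    structure(list(times = c(0, 5, 10), snapshots = snaps, record_idx = NULL,
                   geom = geom), class = "treatment_series")
  }
  body <- evaluate_treatment(mk(37, 37))
  expect_equal(c(body$theta_A_star, body$theta_H_star, body$theta_A_eff_star),
               c(0, 1, 0))
  ideal <- evaluate_treatment(mk(46, 37))
  expect_equal(c(ideal$theta_A_star, ideal$theta_H_star,
                 ideal$theta_A_eff_star), c(1, 1, 1))
})
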