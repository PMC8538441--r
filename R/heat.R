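#' Thermal field over a voxelized geometry
#'
#' Initializes the temperature array and precomputes the explicit
#' finite-difference machinery: per-voxel heat capacity `rho cp V` (J/K) and
#' per-face conductances `G = k_harm A / d` (W/K), where `k_harm = 2 k k' /
#' (k + k')` is the harmonic mean of the two adjacent voxel conductivities.
#' Faces touching inert material (id 0) or a domain boundary get zero
#' conductance, which is the adiabatic closure; optional fixed-temperature
#' far faces and a convective top surface are available through
#' [run_treatment()] and [step_temperature()].
#'
#' @param geom A `layered_geometry`.
#' @param T_init Initial temperature (degrees C), scalar or per-voxel array.
#' @return Object of class `thermal_field` with elements `T` (array, deg C),
#'   `cap`, `Gx`, `Gy`, `Gz`, `geom`, `time` (s) and the cached stability
#'   limit `dt_limit` (s).
#' @examples
#' slab <- build_slab(optical_properties(1, 0, 0), extent = c(4, 4, 4),
#'                    voxel = 1)
#' field <- thermal_field(slab, T_init = 37)
#' stability_timestep(field)
#' @export
thermal_field <- function(geom, T_init = 37) {
  stopifnot(inherits(geom, "layered_geometry"))
  nx <- geom$nx; ny <- geom$ny; nz <- geom$nz
  dz_mm <- diff(geom$z_edges)

  ids <- geom$material
  rho <- c(0, geom$materials$rho)[ids + 1L]
  cp <- c(0, geom$materials$cp)[ids + 1L]
  kth <- c(0, geom$materials$k)[ids + 1L]
  dim(rho) <- dim(cp) <- dim(kth) <- dim(ids)

  vol_m3 <- voxel_volumes(geom) * 1e-9
  cap <- rho * cp * vol_m3

  harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  dz_arr <- array(rep(dz_mm, each = nx * ny), dim = c(nx, ny, nz))
  # x faces: area dy*dz, separation dx (all converted mm -> m)
  Gx <- harm(kth[-nx, , , drop = FALSE], kth[-1, , , drop = FALSE]) *
    (geom$dy * dz_arr[-1, , , drop = FALSE] * 1e-6) / (geom$dx * 1e-3)
  Gy <- harm(kth[, -ny, , drop = FALSE], kth[, -1, , drop = FALSE]) *
    (geom$dx * dz_arr[, -1, , drop = FALSE] * 1e-6) / (geom$dy * 1e-3)
  # z faces: area dx*dy, separation = distance between slice centers
  dz_face <- (dz_mm[-nz] + dz_mm[-1]) / 2
  dzf_arr <- array(rep(dz_face, each = nx * ny), dim = c(nx, ny, nz - 1))
  Gz <- harm(kth[, , -nz, drop = FALSE], kth[, , -1, drop = FALSE]) *
    (geom$dx * geom$dy * 1e-6) / (dzf_arr * 1e-3)

  if (length(T_init) == 1) T_init <- array(T_init, dim = dim(ids))
  stopifnot(all(dim(T_init) == dim(ids)), all(is.finite(T_init)))

  # explicit-scheme stability limit: dt <= cap / sum(face conductances)
  gsum <- array(0, dim = dim(ids))
  if (nx > 1) {
    gsum[-nx, , ] <- gsum[-nx, , , drop = FALSE] + Gx
    gsum[-1, , ] <- gsum[-1, , , drop = FALSE] + Gx
  }
  if (ny > 1) {
    gsum[, -ny, ] <- gsum[, -ny, , drop = FALSE] + Gy
    gsum[, -1, ] <- gsum[, -1, , drop = FALSE] + Gy
  }
  if (nz > 1) {
    gsum[, , -nz] <- gsum[, , -nz, drop = FALSE] + Gz
    gsum[, , -1] <- gsum[, , -1, drop = FALSE] + Gz
  }
  active <- cap > 0 & gsum > 0
  if (!any(active))
    stop("no conducting faces: stability timestep is unbounded", call. = FALSE)
  dt_limit <- min(cap[active] / gsum[active])

  structure(list(T = T_init, cap = cap, Gx = Gx, Gy = Gy, Gz = Gz,
                 geom = geom, time = 0, dt_limit = dt_limit),
            class = "thermal_field")
}

#' @export
print.thermal_field <- function(x, ...) {
  act <- x$cap > 0
  cat(sprintf(
    "thermal field at t = %g s: T in [%.2f, %.2f] degC, dt limit %.4g s\n",
    x$time, min(x$T[act]), max(x$T[act]), x$dt_limit))
  invisible(x)
}

#' Stable explicit timestep
#'
#' Largest safe timestep for the explicit conduction update:
#' `safety * min(cap / sum_faces G)` over active voxels. For a homogeneous
#' medium with cubic voxels this reduces to `safety * rho cp d^2 / (6 k)`.
#'
#' @param field A [thermal_field()].
#' @param safety Safety factor in (0, 1]; default 0.5.
#' @return Timestep in seconds.
#' @export
stability_timestep <- function(field, safety = 0.5) {
  stopifnot(inherits(field, "thermal_field"), safety > 0, safety <= 1)
  safety * field$dt_limit
}

#' Advance the temperature field by one explicit step
#'
#' One explicit finite-difference update: each voxel changes by
#' `dt / (rho cp V) * (q + sum_faces G (T_neighbour - T))`. Steps above the
#' stability limit are refused (they would violate the discrete maximum
#' principle).
#'
#' @param field A [thermal_field()].
#' @param source_q Volumetric source per voxel in W (array congruent with the
#'   field, or scalar 0).
#' @param dt Timestep (s), `<= cap / sum(G)` everywhere.
#' @param fixed Optional logical array of voxels held at their current
#'   temperature (Dirichlet).
#' @param h_top Convective coefficient at the top surface (W/(m^2 K)); 0
#'   disables convection (adiabatic top).
#' @param T_amb Ambient temperature for the convective boundary (deg C).
#' @return The updated `thermal_field`.
#' @export
step_temperature <- function(field, source_q = 0, dt,
                             fixed = NULL, h_top = 0, T_amb = 20) {
  stopifnot(inherits(field, "thermal_field"), dt > 0)
  if (dt > field$dt_limit * (1 + 1e-12))
    stop(sprintf("dt = %g exceeds the stability limit %g s", dt,
                 field$dt_limit), call. = FALSE)
  nvox <- length(field$T)
  q <- if (length(source_q) == 1) rep(as.numeric(source_q), nvox)
       else as.numeric(source_q)
  stopifnot(length(q) == nvox)
  if (is.null(fixed)) fixed <- logical(nvox)
  g <- field$geom
  Tn <- heat_step_cpp(as.numeric(field$T), as.numeric(field$cap),
                      as.numeric(field$Gx), as.numeric(field$Gy),
                      as.numeric(field$Gz), g$nx, g$ny, g$nz,
                      q, dt, as.logical(fixed),
                      h_top, T_amb, g$dx * g$dy * 1e-6)
  field$T <- array(Tn, dim = dim(field$T))
  field$time <- field$time + dt
  field
}

#' Pulsed heating/cooling laser treatment schedule
#'
#' @param P_l Laser power in mW (>= 0).
#' @param tau_h Heating (laser on) duration per cycle (s), > 0.
#' @param tau_c Cooling (laser off) duration per cycle (s), >= 0; 0 gives
#'   continuous heating.
#' @param tau_tot Total elapsed treatment time (s) including cooling phases;
#'   a final partial cycle is truncated at `tau_tot`.
#' @return Object of class `treatment_schedule`.
#' @examples
#' treatment_schedule(P_l = 500, tau_h = 30, tau_c = 30, tau_tot = 360)
#' @export
treatment_schedule <- function(P_l, tau_h, tau_c, tau_tot) {
  stopifnot(is.numeric(P_l), is.numeric(tau_h), is.numeric(tau_c),
            is.numeric(tau_tot))
  if (P_l < 0) stop("laser power must be non-negative", call. = FALSE)
  if (tau_h <= 0 || tau_c < 0 || tau_tot <= 0)
    stop("durations must be positive (tau_c may be 0)", call. = FALSE)
  structure(list(P_l = P_l, tau_h = tau_h, tau_c = tau_c, tau_tot = tau_tot),
            class = "treatment_schedule")
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf("treatment schedule: %g mW, %g s on / %g s off, %g s total\n",
              x$P_l, x$tau_h, x$tau_c, x$tau_tot))
  invisible(x)
}

#' Simulate a pulsed-laser treatment
#'
#' Drives the explicit heat solver with the Monte Carlo absorption grid
#' under an alternating heating/cooling schedule. During heating phases each
#' voxel receives `q = P_l * deposited fraction` watts (the absorption grid
#' is normalized per unit beam power, so the total injected power is
#' `P_l * absorbed fraction`); during cooling phases the source is off.
#' Snapshots of the temperature field are recorded at a fixed interval, at
#' t = 0 and at `tau_tot`.
#'
#' @param geom A `layered_geometry`.
#' @param absorption An `absorption_grid` from [run_monte_carlo()] on the
#'   same geometry.
#' @param schedule A [treatment_schedule()].
#' @param T_init Initial temperature (deg C); 37 for skin, 20 for phantom
#'   runs.
#' @param dt Timestep (s); default [stability_timestep()] of the field.
#' @param snapshot_interval Snapshot spacing (s).
#' @param record `"full"` stores entire fields; `"masks"` stores only the
#'   tumor and normal-ROI voxels (sufficient for dose metrics, far smaller).
#' @param boundary `"adiabatic"` (default) or `"fixed-far"`, which holds the
#'   lateral and bottom faces at `T_init`.
#' @param h_top,T_amb Optional convective top surface (see
#'   [step_temperature()]).
#' @return A `treatment_series`: list with `times` (s), `snapshots` (matrix,
#'   recorded voxels x times), `record_idx` (voxel indices recorded, or NULL
#'   for full fields), `T_final` (array), `geom`, `schedule`, `T_init`.
#' @export
run_treatment <- function(geom, absorption, schedule, T_init = 37, dt = NULL,
                          snapshot_interval = 1, record = c("full", "masks"),
                          boundary = c("adiabatic", "fixed-far"),
                          h_top = 0, T_amb = 20) {
  stopifnot(inherits(geom, "layered_geometry"),
            inherits(absorption, "absorption_grid"),
            inherits(schedule, "treatment_schedule"))
  record <- match.arg(record)
  boundary <- match.arg(boundary)
  if (!all(dim(absorption$deposited) == dim(geom$material)))
    stop("absorption grid does not match the geometry", call. = FALSE)

  field <- thermal_field(geom, T_init)
  if (is.null(dt)) dt <- stability_timestep(field)
  if (dt > field$dt_limit)
    stop("dt exceeds the stability limit", call. = FALSE)
  q <- schedule$P_l * 1e-3 * as.numeric(absorption$deposited) # W per voxel

  snap_times <- unique(c(seq(0, schedule$tau_tot, by = snapshot_interval),
                         schedule$tau_tot))
  record_idx <- NULL
  if (record == "masks") {
    if (is.null(geom$tumor_mask) || is.null(geom$normal_roi_mask))
      stop("record = 'masks' needs tumor and normal-ROI masks", call. = FALSE)
    record_idx <- which(geom$tumor_mask | geom$normal_roi_mask)
  }

  fixed <- array(FALSE, dim = dim(geom$material))
  if (boundary == "fixed-far") {
    fixed[c(1, geom$nx), , ] <- TRUE
    fixed[, c(1, geom$ny), ] <- TRUE
    fixed[, , geom$nz] <- TRUE
  }

  res <- heat_run_cpp(as.numeric(field$T), as.numeric(field$cap),
                      as.numeric(field$Gx), as.numeric(field$Gy),
                      as.numeric(field$Gz), geom$nx, geom$ny, geom$nz,
                      q, schedule$tau_h, schedule$tau_c, schedule$tau_tot,
                      dt, snap_times,
                      if (is.null(record_idx)) integer(0)
                      else as.integer(record_idx - 1L),
                      as.logical(fixed), h_top, T_amb,
                      geom$dx * geom$dy * 1e-6)
  structure(list(times = snap_times, snapshots = res$snapshots,
                 record_idx = record_idx,
                 T_final = array(res$T_final, dim = dim(geom$material)),
                 geom = geom, schedule = schedule, T_init = T_init),
            class = "treatment_series")
}

#' @export
print.treatment_series <- function(x, ...) {
  cat(sprintf(
    "treatment series: %d snapshots over %g s (%s voxels recorded)\n",
    length(x$times), max(x$times),
    if (is.null(x$record_idx)) "all" else length(x$record_idx)))
  invisible(x)
}

#' Sample temperature traces at probe locations
#'
#' Extracts per-probe temperature time series from a full-field
#' `treatment_series`, by nearest-voxel lookup or trilinear interpolation
#' between voxel centers.
#'
#' @param series A `treatment_series` recorded with `record = "full"`.
#' @param locations Data frame or matrix with columns/cols `x`, `y`, `z`
#'   (mm), inside the domain.
#' @param method `"nearest"` or `"trilinear"`.
#' @return Matrix of temperatures, probes in columns, snapshots in rows.
#' @export
probe_series <- function(series, locations, method = c("nearest", "trilinear")) {
  stopifnot(inherits(series, "treatment_series"))
  if (!is.null(series$record_idx))
    stop("probe_series needs a full-field recording", call. = FALSE)
  method <- match.arg(method)
  loc <- as.matrix(as.data.frame(locations)[, c("x", "y", "z")])
  g <- series$geom
  L <- c(g$nx * g$dx, g$ny * g$dy, max(g$z_edges))
  if (any(loc < 0) || any(loc[, 1] > L[1]) || any(loc[, 2] > L[2]) ||
      any(loc[, 3] > L[3]))
    stop("probe location outside the domain", call. = FALSE)
  cen <- voxel_centers(g)
  nvox <- g$nx * g$ny * g$nz
  snaps <- series$snapshots # nvox x n_snap
  out <- matrix(NA_real_, nrow = length(series$times), ncol = nrow(loc))

  for (p in seq_len(nrow(loc))) {
    if (method == "nearest") {
      i <- which.min(abs(cen$x - loc[p, 1]))
      j <- which.min(abs(cen$y - loc[p, 2]))
      k <- which.min(abs(cen$z - loc[p, 3]))
      out[, p] <- snaps[i + g$nx * ((j - 1) + g$ny * (k - 1)), ]
    } else {
      w <- lapply(1:3, function(ax) {
        cc <- cen[[ax]]
        v <- loc[p, ax]
        lo <- findInterval(v, cc)
        if (lo < 1) list(i = c(1L, 1L), w = c(1, 0))
        else if (lo >= length(cc)) list(i = rep(length(cc), 2L), w = c(1, 0))
        else {
          t <- (v - cc[lo]) / (cc[lo + 1] - cc[lo])
          list(i = c(lo, lo + 1L), w = c(1 - t, t))
        }
      })
      acc <- 0
      for (a in 1:2) for (b in 1:2) for (d in 1:2) {
        wt <- w[[1]]$w[a] * w[[2]]$w[b] * w[[3]]$w[d]
        if (wt > 0) {
          idx <- w[[1]]$i[a] + g$nx * ((w[[2]]$i[b] - 1) +
                                         g$ny * (w[[3]]$i[d] - 1))
          acc <- acc + wt * snaps[idx, ]
        }
      }
      out[, p] <- acc
    }
  }
  stopifnot(nvox == nrow(snaps))
  out
}

#' Root-mean-square error between temperature traces
#'
#' Pointwise RMSE between an equal-length simulated and measured trace; for
#' matrices (probes in columns) the per-probe RMSEs are averaged, matching
#' the usual multi-thermocouple validation summary.
#'
#' @param sim,measured Numeric vectors or matrices of equal dimension.
#' @return Scalar RMSE (same units as the traces).
#' @examples
#' rmse(c(0, 1, 2), c(1, 1, 1))  # sqrt(2/3)
#' @export
rmse <- function(sim, measured) {
  sim <- as.matrix(sim); measured <- as.matrix(measured)
  if (!all(dim(sim) == dim(measured)))
    stop("traces must have equal length", call. = FALSE)
  mean(sqrt(colMeans((sim - measured)^2)))
}
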