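#' Treatment-condition grid
#'
#' Cartesian grid of treatment conditions to sweep. The defaults are the
#' full study grid: total treatment time 120-960 s in 120 s steps, laser
#' power 0-2000 mW in 50 mW steps, nanorod volume fraction 1e-3 to 1e-6 in
#' decade steps, and heating/cooling times of 15, 20, 30 or 60 s (equal on
#' and off durations).
#'
#' @param tau_tot Total treatment times (s).
#' @param P_l Laser powers (mW).
#' @param fv Nanorod volume fractions.
#' @param tau_hc Heating/cooling durations (s).
#' @return A `condition_grid` data frame with one row per condition.
#' @examples
#' nrow(condition_grid())  # 2688 conditions
#' condition_grid(tau_tot = 360, P_l = c(400, 500), fv = 1e-6, tau_hc = 30)
#' @export
condition_grid <- function(tau_tot = seq(120, 960, by = 120),
                           P_l = seq(0, 2000, by = 50),
                           fv = 10^-(3:6),
                           tau_hc = c(15, 20, 30, 60)) {
  stopifnot(all(tau_tot > 0), all(P_l >= 0), all(fv >= 0), all(tau_hc > 0))
  grid <- expand.grid(tau_tot = tau_tot, P_l = P_l, fv = fv, tau_hc = tau_hc,
                      KEEP.OUT.ATTRS = FALSE)
  class(grid) <- c("condition_grid", "data.frame")
  grid
}

#' Sweep treatment conditions
#'
#' Evaluates the starred dose metrics for every condition in the grid.
#' Costly stages are shared across conditions that cannot differ:
#' one Monte Carlo transport run per volume fraction (the absorption grid is
#' independent of power and schedule), and one unit-power thermal run per
#' (volume fraction, heating/cooling time, treatment time) — the
#' conduction update is linear in the source, so the temperature-rise field
#' at power `P` is `P` times the unit-power rise. Snapshots are recorded on
#' the tumor and normal-ROI voxels only.
#'
#' @param grid A [condition_grid()].
#' @param voxel Voxel size (mm) of the simulation geometry; the default
#'   0.5 mm is the coarsened sweep profile.
#' @param n_photons Photons per transport run.
#' @param seed Base integer seed; per-volume-fraction substreams are derived
#'   deterministically from it.
#' @param snapshot_interval Dose-metric snapshot spacing (s).
#' @param fine_surface Resolve the thin surface layers with fine z slices
#'   (slower; the coarse profile leaves it off).
#' @param T_init Initial/body temperature (deg C).
#' @param materials Material table, see [skin_materials()].
#' @param checkpoint Optional CSV path: completed rows are appended as each
#'   thermal run finishes and are skipped on re-run (resume support).
#' @param progress Print one line per thermal run.
#' @return A `sweep_result` data frame: the grid columns plus
#'   `theta_A_star`, `theta_H_star`, `theta_A_eff_star`, `seed`.
#' @examples
#' \donttest{
#' grid <- condition_grid(tau_tot = 120, P_l = c(0, 400), fv = 1e-6,
#'                        tau_hc = 30)
#' res <- run_sweep(grid, voxel = 1, n_photons = 5000, seed = 1)
#' select_optimum(res)
#' }
#' @export
run_sweep <- function(grid, voxel = 0.5, n_photons = 1e5, seed = 1,
                      snapshot_interval = 2, fine_surface = FALSE,
                      T_init = 37, materials = skin_materials(),
                      checkpoint = NULL, progress = FALSE) {
  stopifnot(inherits(grid, "condition_grid") || is.data.frame(grid))
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint))
    done <- utils::read.csv(checkpoint)

  fvs <- sort(unique(grid$fv), decreasing = TRUE)
  rows <- vector("list", 0)
  for (fi in seq_along(fvs)) {
    fv <- fvs[fi]
    sub_fv <- grid[grid$fv == fv, , drop = FALSE]
    geom <- build_skin_stack(fv = fv, voxel = voxel,
                             fine_surface = fine_surface,
                             materials = materials)
    mc_seed <- seed + fi - 1L
    absorption <- run_monte_carlo(geom, n_photons = n_photons, seed = mc_seed)

    combos <- unique(sub_fv[, c("tau_hc", "tau_tot")])
    for (ci in seq_len(nrow(combos))) {
      thc <- combos$tau_hc[ci]; ttot <- combos$tau_tot[ci]
      sub <- sub_fv[sub_fv$tau_hc == thc & sub_fv$tau_tot == ttot, ,
                    drop = FALSE]
      if (!is.null(done)) {
        done_here <- done[done$fv == fv & done$tau_hc == thc &
                            done$tau_tot == ttot, , drop = FALSE]
        if (nrow(done_here) == nrow(sub)) {
          rows[[length(rows) + 1]] <- done_here
          next
        }
      }
      if (progress)
        message(sprintf("fv = %g, tau_h/c = %g s, tau_tot = %g s (%d powers)",
                        fv, thc, ttot, nrow(sub)))
      unit <- run_treatment(geom, absorption,
                            treatment_schedule(1, thc, thc, ttot),
                            T_init = T_init,
                            snapshot_interval = snapshot_interval,
                            record = "masks")
      rise <- unit$snapshots - T_init # unit-power temperature rise
      block <- lapply(sub$P_l, function(P) {
        scaled <- unit
        scaled$snapshots <- T_init + P * rise
        rep <- evaluate_treatment(scaled, geom)
        data.frame(tau_tot = ttot, P_l = P, fv = fv, tau_hc = thc,
                   theta_A_star = rep$theta_A_star,
                   theta_H_star = rep$theta_H_star,
                   theta_A_eff_star = rep$theta_A_eff_star,
                   seed = mc_seed)
      })
      block <- do.call(rbind, block)
      rows[[length(rows) + 1]] <- block
      if (!is.null(checkpoint)) {
        prev <- if (file.exists(checkpoint)) utils::read.csv(checkpoint)
                else NULL
        utils::write.csv(rbind(prev, block), checkpoint, row.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Optimal condition per treatment time
#'
#' For each total treatment time, the grid row maximizing the effective
#' apoptosis retention ratio. Ties are broken toward lower laser power, then
#' shorter heating/cooling time.
#'
#' @param result A `sweep_result` (or any data frame with the sweep
#'   columns).
#' @return One row per `tau_tot`, ordered by `tau_tot`.
#' @export
select_optimum <- function(result) {
  stopifnot(nrow(result) > 0,
            all(c("tau_tot", "P_l", "tau_hc", "theta_A_eff_star") %in%
                  names(result)))
  picks <- lapply(split(result, result$tau_tot), function(g) {
    g[order(-g$theta_A_eff_star, g$P_l, g$tau_hc)[1], , drop = FALSE]
  })
  out <- do.call(rbind, picks)
  out <- out[order(out$tau_tot), , drop = FALSE]
  rownames(out) <- NULL
  out
}
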