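#' Thermal hazard weight table
#'
#' Ordered temperature bands with integer hazard weights grading
#' laser-induced thermal effects in tissue, from no damage (weight 1 at or
#' below body temperature and in the biostimulation band) through
#' hyperthermia and reduced enzyme activity (2), protein denaturation (3),
#' welding (4), membrane permeabilization (5), vaporization (6),
#' carbonization (7) and ablation (8). Bands are left-closed above 43
#' degrees C: 43 <= T < 45 and 45 <= T < 50 carry weight 2, 50 <= T < 70
#' weight 3, and so on; T >= 300 carries weight 8.
#'
#' @return A `hazard_weight_table`: data frame with columns `lower`,
#'   `upper` (deg C, bands `[lower, upper)`) and `weight`.
#' @examples
#' hazard_weight_table()
#' hazard_weight(c(37, 44, 60, 120))
#' @export
hazard_weight_table <- function() {
  breaks <- c(-Inf, 43, 45, 50, 70, 80, 100, 150, 300, Inf)
  structure(data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
                       weight = c(1L, 2L, 2L, 3L, 4L, 5L, 6L, 7L, 8L)),
            class = c("hazard_weight_table", "data.frame"))
}

#' @rdname hazard_weight_table
#' @param T_degC Temperatures in degrees C.
#' @param weights A `hazard_weight_table`.
#' @export
hazard_weight <- function(T_degC, weights = hazard_weight_table()) {
  stopifnot(inherits(weights, "hazard_weight_table"))
  weights$weight[findInterval(T_degC, weights$lower[-1]) + 1L]
}

#' Apoptosis ratio of the tumor
#'
#' Fraction of the tumor volume inside the apoptosis temperature band,
#' strictly 43 < T < 50 degrees C. Equals 1 when the whole tumor is in
#' band and 0 at body temperature.
#'
#' @param T_field Temperature array or vector (deg C).
#' @param tumor_mask Logical mask (same shape) selecting tumor voxels; must
#'   be non-empty.
#' @param volumes Optional per-voxel volumes for grids with non-uniform
#'   voxels; equal-volume voxels are assumed when omitted.
#' @return Scalar in `[0, 1]`.
#' @examples
#' apoptosis_ratio(c(46, 46, 37, 55), rep(TRUE, 4))  # 0.5
#' @export
apoptosis_ratio <- function(T_field, tumor_mask, volumes = NULL) {
  if (!any(tumor_mask)) stop("tumor mask is empty", call. = FALSE)
  Tt <- T_field[tumor_mask]
  in_band <- Tt > 43 & Tt < 50
  if (is.null(volumes)) return(mean(in_band))
  v <- volumes[tumor_mask]
  sum(v[in_band]) / sum(v)
}

#' Thermal hazard value of the normal-tissue ROI
#'
#' Volume-weighted mean hazard weight over the normal-tissue region of
#' interest: `sum_j V_j(T) w_j / V_roi` with the band weights of
#' [hazard_weight_table()]. Equals 1 for an undamaged ROI and grows as
#' voxels enter hotter bands.
#'
#' @param T_field Temperature array or vector (deg C).
#' @param roi_mask Logical mask of normal-tissue voxels; non-empty.
#' @param weights A `hazard_weight_table`.
#' @param volumes Optional per-voxel volumes (see [apoptosis_ratio()]).
#' @return Scalar >= 1 under the default weights.
#' @examples
#' thermal_hazard(c(37, 44), c(TRUE, TRUE))  # (1 + 2) / 2
#' @export
thermal_hazard <- function(T_field, roi_mask, weights = hazard_weight_table(),
                           volumes = NULL) {
  if (!any(roi_mask)) stop("normal-tissue ROI mask is empty", call. = FALSE)
  w <- hazard_weight(T_field[roi_mask], weights)
  if (is.null(volumes)) return(mean(w))
  v <- volumes[roi_mask]
  sum(v * w) / sum(v)
}

#' Time-average of a metric series over the treatment
#'
#' Trapezoidal time-integral of a snapshot series divided by the elapsed
#' time, turning the instantaneous apoptosis ratio / hazard value into its
#' "retention" counterpart. A constant series returns its value; a single
#' snapshot is returned as-is.
#'
#' @param series Numeric metric values per snapshot.
#' @param times Non-decreasing snapshot times (s).
#' @return Scalar time-average.
#' @examples
#' time_average(c(0, 1), c(0, 100))  # 0.5
#' @export
time_average <- function(series, times) {
  if (length(series) == 0) stop("empty series", call. = FALSE)
  if (length(series) != length(times))
    stop("series and times must have equal length", call. = FALSE)
  if (any(diff(times) < 0)) stop("times must be non-decreasing", call. = FALSE)
  if (length(series) == 1) return(series)
  span <- times[length(times)] - times[1]
  if (span == 0) return(mean(series))
  sum(diff(times) * (series[-1] + series[-length(series)]) / 2) / span
}

#' Effective apoptosis retention ratio
#'
#' Quotient of the apoptosis retention ratio and the thermal hazard
#' retention value — the treatment-planning objective: high when the tumor
#' stays in the apoptosis band while the surrounding tissue stays cool.
#'
#' @param theta_A_star Apoptosis retention ratio in `[0, 1]`.
#' @param theta_H_star Thermal hazard retention value, >= 1.
#' @return `theta_A_star / theta_H_star`.
#' @export
effective_ratio <- function(theta_A_star, theta_H_star) {
  if (theta_H_star < 1)
    stop("thermal hazard retention value must be >= 1", call. = FALSE)
  theta_A_star / theta_H_star
}

#' Score a simulated treatment
#'
#' Computes the full dose report from a temperature time series: the
#' instantaneous apoptosis ratio of the tumor and thermal hazard value of
#' the normal-tissue ROI at every snapshot, their trapezoidal time-averages
#' (the starred retention metrics), and the effective apoptosis retention
#' ratio (their quotient).
#'
#' @param series A `treatment_series` from [run_treatment()] (full or
#'   mask-recorded).
#' @param geom Geometry with tumor and normal-ROI masks; defaults to the
#'   geometry stored in `series`.
#' @param weights A [hazard_weight_table()].
#' @return A `dose_report`: list with `times`, `theta_A`, `theta_H`,
#'   `theta_A_star`, `theta_H_star`, `theta_A_eff_star`.
#' @export
evaluate_treatment <- function(series, geom = series$geom,
                               weights = hazard_weight_table()) {
  stopifnot(inherits(series, "treatment_series"))
  if (is.null(geom$tumor_mask) || is.null(geom$normal_roi_mask))
    stop("geometry must carry tumor and normal-ROI masks", call. = FALSE)
  vol <- voxel_volumes(geom)
  if (is.null(series$record_idx)) {
    rec <- seq_along(geom$material)
  } else {
    rec <- series$record_idx
  }
  tum_rows <- match(which(geom$tumor_mask), rec)
  roi_rows <- match(which(geom$normal_roi_mask), rec)
  if (any(is.na(tum_rows)) || any(is.na(roi_rows)))
    stop("recorded voxels do not cover the tumor and ROI masks", call. = FALSE)
  v_tum <- vol[geom$tumor_mask]
  v_roi <- vol[geom$normal_roi_mask]

  n_snap <- length(series$times)
  theta_A <- numeric(n_snap)
  theta_H <- numeric(n_snap)
  for (s in seq_len(n_snap)) {
    Tt <- series$snapshots[tum_rows, s]
    Tr <- series$snapshots[roi_rows, s]
    in_band <- Tt > 43 & Tt < 50
    theta_A[s] <- sum(v_tum[in_band]) / sum(v_tum)
    theta_H[s] <- sum(v_roi * hazard_weight(Tr, weights)) / sum(v_roi)
  }
  a_star <- time_average(theta_A, series$times)
  h_star <- time_average(theta_H, series$times)
  structure(list(times = series$times, theta_A = theta_A, theta_H = theta_H,
                 theta_A_star = a_star, theta_H_star = h_star,
                 theta_A_eff_star = effective_ratio(a_star, h_star)),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf(
    paste0("dose report: apoptosis retention %.4f, hazard retention %.4f,",
           " effective ratio %.4f (%d snapshots)\n"),
    x$theta_A_star, x$theta_H_star, x$theta_A_eff_star, length(x$times)))
  invisible(x)
}
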