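#' @title Voxelized layered geometry
#'
#' @description Internal constructor for the voxel domain shared by the
#' photon-transport and heat solvers. The grid is uniform in x and y; the z
#' spacing is given by an edge vector so the thin surface layers can be
#' resolved with finer slices than the bulk. Material id 0 is reserved for
#' inert voxels (outside the physical object): photons stream through them
#' and they do not conduct heat.
#'
#' @param material Integer array `nx x ny x nz` of material ids.
#' @param materials Data frame with one row per material id (row i = id i),
#'   columns `name`, `rho`, `cp`, `k`, `mu_a`, `mu_s`, `g`.
#' @param dx,dy Voxel size in x and y (mm).
#' @param z_edges Monotone vector of z slice boundaries (mm), length nz + 1.
#' @param tumor_mask,normal_roi_mask Logical arrays congruent with `material`.
#' @param tumor Optional list describing the tumor cylinder.
#' @return Object of class `layered_geometry`.
#' @keywords internal
layered_geometry <- function(material, materials, dx, dy, z_edges,
                             tumor_mask = NULL, normal_roi_mask = NULL,
                             tumor = NULL) {
  dims <- dim(material)
  stopifnot(length(dims) == 3, length(z_edges) == dims[3] + 1,
            all(diff(z_edges) > 0), dx > 0, dy > 0)
  if (any(is.na(material)))
    stop("every voxel must have a material", call. = FALSE)
  if (max(material) > nrow(materials))
    stop("material id exceeds material table", call. = FALSE)
  if (!is.null(tumor_mask) && !is.null(normal_roi_mask) &&
      any(tumor_mask & normal_roi_mask))
    stop("tumor and normal-ROI masks must be disjoint", call. = FALSE)
  structure(list(
    material = material, materials = materials,
    dx = dx, dy = dy, z_edges = z_edges,
    nx = dims[1], ny = dims[2], nz = dims[3],
    tumor_mask = tumor_mask, normal_roi_mask = normal_roi_mask,
    tumor = tumor
  ), class = "layered_geometry")
}

#' @export
print.layered_geometry <- function(x, ...) {
  cat(sprintf(
    "layered geometry: %d x %d x %d voxels (%.3g x %.3g mm in-plane, depth %.3g mm)\n",
    x$nx, x$ny, x$nz, x$dx, x$dy, max(x$z_edges)))
  cat(sprintf("  materials: %s\n", paste(x$materials$name, collapse = ", ")))
  if (!is.null(x$tumor_mask))
    cat(sprintf("  tumor: %d voxels (%.1f mm^3); normal ROI: %d voxels\n",
                sum(x$tumor_mask), sum(voxel_volumes(x)[x$tumor_mask]),
                if (is.null(x$normal_roi_mask)) 0L else sum(x$normal_roi_mask)))
  invisible(x)
}

#' Voxel center coordinates and volumes
#'
#' @param geom A `layered_geometry`.
#' @return `voxel_centers` returns a list with vectors `x`, `y`, `z` (mm) of
#'   per-axis voxel centers; `voxel_volumes` returns an `nx x ny x nz` array
#'   of voxel volumes in mm^3 (volumes vary only along z).
#' @export
voxel_centers <- function(geom) {
  list(x = (seq_len(geom$nx) - 0.5) * geom$dx,
       y = (seq_len(geom$ny) - 0.5) * geom$dy,
       z = (geom$z_edges[-1] + geom$z_edges[-(geom$nz + 1)]) / 2)
}

#' @rdname voxel_centers
#' @export
voxel_volumes <- function(geom) {
  dz <- diff(geom$z_edges)
  array(rep(geom$dx * geom$dy * dz, each = geom$nx * geom$ny),
        dim = c(geom$nx, geom$ny, geom$nz))
}

# z slice edges: fine spacing (~fine_dz) across the thin surface layers,
# coarse spacing (~voxel) below. Each layer is subdivided into an integer
# number of equal slices so layer boundaries coincide with voxel faces.
make_z_edges <- function(depth, voxel, layer_bounds, fine_surface, fine_dz) {
  if (!fine_surface)
    return(seq(0, depth, length.out = round(depth / voxel) + 1))
  edges <- 0
  for (b in layer_bounds) {
    t <- b - edges[length(edges)]
    n <- max(1L, ceiling(t / fine_dz))
    edges <- c(edges, edges[length(edges)] + seq_len(n) * t / n)
  }
  rem <- depth - edges[length(edges)]
  n <- max(1L, ceiling(rem / voxel))
  c(edges, edges[length(edges)] + seq_len(n) * rem / n)
}

#' Build the four-layer skin domain with an embedded tumor
#'
#' Voxelizes a cuboid skin domain: epidermis, papillary dermis, reticular
#' dermis and subcutaneous fat stacked from the surface downward (the fat
#' layer is extended to the bottom of the domain), with a cylindrical tumor
#' centered on the beam axis overriding the layers where it intersects.
#' Materials are assigned by voxel center; by default the z grid uses fine
#' slices across the thin surface layers (the 0.08 mm epidermis is far
#' thinner than a practical isotropic voxel) and coarser slices below.
#' The normal-tissue region of interest — the shell of non-tumor voxels
#' within half a tumor diameter of the tumor — is precomputed via
#' [build_normal_roi()].
#'
#' @param fv Gold-nanorod volume fraction in the tumor; tumor optics are
#'   mixed via [tumor_optics_with_gnr()].
#' @param voxel In-plane voxel size and coarse z spacing (mm).
#' @param extent Domain size `c(x, y, z)` in mm.
#' @param fine_surface Use fine z slices (`fine_dz`) across the stacked
#'   surface layers.
#' @param fine_dz Target fine slice thickness (mm).
#' @param materials Material table from [skin_materials()].
#' @param tumor_diameter,tumor_length,tumor_depth Tumor cylinder geometry
#'   (mm): diameter, axial length, and depth of the top face below the
#'   surface.
#' @param roi_shell Width of the normal-tissue ROI shell (mm); default half
#'   the tumor diameter.
#' @return A `layered_geometry` with tumor and normal-ROI masks.
#' @examples
#' geom <- build_skin_stack(fv = 1e-6, voxel = 1, fine_surface = FALSE)
#' geom
#' @export
build_skin_stack <- function(fv = 1e-6, voxel = 0.25, extent = c(30, 30, 10),
                             fine_surface = TRUE, fine_dz = 0.04,
                             materials = skin_materials(),
                             tumor_diameter = 10, tumor_length = 3.5,
                             tumor_depth = 0.1, roi_shell = NULL) {
  stopifnot(voxel > 0, length(extent) == 3, all(extent > 0))
  nx <- round(extent[1] / voxel); ny <- round(extent[2] / voxel)
  if (abs(nx * voxel - extent[1]) > 1e-9 || abs(ny * voxel - extent[2]) > 1e-9)
    stop("voxel size must divide the domain extents", call. = FALSE)
  if (tumor_length <= 0 || tumor_diameter <= 0)
    stop("tumor dimensions must be positive", call. = FALSE)
  if (tumor_depth + tumor_length > extent[3] || tumor_diameter > min(extent[1:2]))
    stop("tumor does not fit inside the domain", call. = FALSE)

  layer_rows <- materials$name != "tumor"
  thick <- materials$thickness_mm[layer_rows]
  bounds <- cumsum(thick[-length(thick)]) # fat extends to the bottom
  z_edges <- make_z_edges(extent[3], voxel, bounds, fine_surface, fine_dz)
  nz <- length(z_edges) - 1

  # mixed tumor optics for the requested nanorod loading
  mats <- materials
  tum_opt <- tumor_optics_with_gnr(fv, materials)
  mats$mu_a[mats$name == "tumor"] <- tum_opt$mu_a
  mats$mu_s[mats$name == "tumor"] <- tum_opt$mu_s

  zc <- (z_edges[-1] + z_edges[-(nz + 1)]) / 2
  layer_of_z <- findInterval(zc, bounds) + 1L # 1..4 from the surface down
  material <- array(rep(layer_of_z, each = nx * ny), dim = c(nx, ny, nz))

  cx <- extent[1] / 2; cy <- extent[2] / 2
  xc <- (seq_len(nx) - 0.5) * voxel
  yc <- (seq_len(ny) - 0.5) * voxel
  in_r <- outer(xc - cx, yc - cy, function(a, b) a^2 + b^2) <=
    (tumor_diameter / 2)^2
  in_z <- zc >= tumor_depth & zc <= tumor_depth + tumor_length
  tumor_mask <- array(FALSE, dim = c(nx, ny, nz))
  tumor_mask[, , in_z] <- in_r
  material[tumor_mask] <- which(mats$name == "tumor")

  geom <- layered_geometry(material, mats, dx = voxel, dy = voxel,
                           z_edges = z_edges, tumor_mask = tumor_mask,
                           tumor = list(radius = tumor_diameter / 2,
                                        length = tumor_length,
                                        top_depth = tumor_depth,
                                        center = c(cx, cy), fv = fv))
  if (is.null(roi_shell)) roi_shell <- tumor_diameter / 2
  geom$normal_roi_mask <- build_normal_roi(geom, shell = roi_shell)
  geom
}

#' Normal-tissue region of interest around the tumor
#'
#' Marks the non-tumor, non-inert voxels whose centers lie within `shell`
#' millimetres (Euclidean, all directions) of the nearest tumor voxel
#' center. This is the normal-tissue volume over which thermal hazard is
#' scored; the default shell is half the tumor diameter.
#'
#' @param geom A `layered_geometry` with a tumor mask.
#' @param shell Shell width in mm (>= 0); 0 gives an empty mask.
#' @return Logical array congruent with the geometry.
#' @export
build_normal_roi <- function(geom, shell = NULL) {
  stopifnot(inherits(geom, "layered_geometry"))
  if (is.null(geom$tumor_mask) || !any(geom$tumor_mask))
    stop("geometry has no tumor mask", call. = FALSE)
  if (is.null(shell)) shell <- geom$tumor$radius
  mask <- array(FALSE, dim = dim(geom$tumor_mask))
  if (shell <= 0) return(mask)

  cen <- voxel_centers(geom)
  idx <- which(geom$tumor_mask, arr.ind = TRUE)
  # surface voxels of the tumor: at least one 6-neighbour outside the mask
  tm <- geom$tumor_mask
  surf <- apply(idx, 1, function(v) {
    i <- v[1]; j <- v[2]; k <- v[3]
    i == 1 || i == geom$nx || !tm[i - 1, j, k] || !tm[i + 1, j, k] ||
      j == 1 || j == geom$ny || !tm[i, j - 1, k] || !tm[i, j + 1, k] ||
      k == 1 || k == geom$nz || !tm[i, j, k - 1] || !tm[i, j, k + 1]
  })
  sidx <- idx[surf, , drop = FALSE]
  tx <- cen$x[sidx[, 1]]; ty <- cen$y[sidx[, 2]]; tz <- cen$z[sidx[, 3]]

  # candidates: non-tumor voxels inside the tumor bounding box grown by shell
  bb_x <- range(cen$x[idx[, 1]]); bb_y <- range(cen$y[idx[, 2]])
  bb_z <- range(cen$z[idx[, 3]])
  ci <- which(cen$x >= bb_x[1] - shell & cen$x <= bb_x[2] + shell)
  cj <- which(cen$y >= bb_y[1] - shell & cen$y <= bb_y[2] + shell)
  ck <- which(cen$z >= bb_z[1] - shell & cen$z <= bb_z[2] + shell)
  cand <- as.matrix(expand.grid(i = ci, j = cj, k = ck))
  keep <- !geom$tumor_mask[cand] & geom$material[cand] > 0L
  cand <- cand[keep, , drop = FALSE]

  within <- roi_within_cpp(cen$x[cand[, 1]], cen$y[cand[, 2]],
                           cen$z[cand[, 3]], tx, ty, tz, shell)
  mask[cand[within, , drop = FALSE]] <- TRUE
  mask
}

#' Homogeneous slab domain
#'
#' A single-material cuboid, mainly for verification runs (Beer-Lambert
#' attenuation, conduction oracles).
#'
#' @param optics An [optical_properties()].
#' @param rho,cp,k Thermal properties (kg/m^3, J/(kg K), W/(m K)).
#' @param extent Domain size `c(x, y, z)` mm.
#' @param voxel Isotropic voxel size (mm).
#' @return A `layered_geometry` without tumor/ROI masks.
#' @export
build_slab <- function(optics, rho = 1000, cp = 4000, k = 0.5,
                       extent = c(10, 10, 10), voxel = 0.5) {
  stopifnot(inherits(optics, "optical_properties"))
  nx <- round(extent[1] / voxel); ny <- round(extent[2] / voxel)
  nz <- round(extent[3] / voxel)
  mats <- data.frame(name = "slab", thickness_mm = extent[3], rho = rho,
                     cp = cp, k = k, mu_a = optics$mu_a, mu_s = optics$mu_s,
                     g = optics$g, stringsAsFactors = FALSE)
  layered_geometry(array(1L, dim = c(nx, ny, nz)), mats, dx = voxel,
                   dy = voxel, z_edges = seq(0, extent[3], length.out = nz + 1))
}

#' Tissue-equivalent phantom preset
#'
#' Cylinder-in-cylinder polyacrylamide phantom used for model validation: a
#' nanorod-loaded core (10 mm diameter, 10 mm deep from the surface) inside
#' a plain phantom cylinder (40 mm diameter, 30 mm long). Thermal properties
#' are those of the polyacrylamide gel (rho 1070 kg/m^3, cp 3810 J/(kg K),
#' k 0.56 W/(m K)). The gel's optical coefficients are not part of the
#' published recipe; the preset ships synthetic water-dominated defaults
#' (weak absorption at 1064 nm, weak scattering) that can be overridden.
#' Voxels outside the outer cylinder are inert (material 0).
#'
#' @param fv Nanorod volume fraction in the core.
#' @param voxel Isotropic voxel size (mm).
#' @param host_optics Optical properties of the plain gel.
#' @param materials Material configuration (for the nanorod calibration).
#' @return A `layered_geometry`; the core is exposed as `tumor_mask`.
#' @export
build_phantom <- function(fv = 2e-5, voxel = 0.5,
                          host_optics = optical_properties(0.014, 0.1, 0.9),
                          materials = skin_materials()) {
  outer_r <- 20; depth <- 30; core_r <- 5; core_depth <- 10
  nxy <- round(2 * outer_r / voxel); nz <- round(depth / voxel)
  z_edges <- seq(0, depth, length.out = nz + 1)

  np <- nanoparticle_coefficients(calibrated_gnr_spec(fv, materials))
  core_opt <- mix_optical_properties(host_optics, np[["mu_a"]], np[["mu_s"]])
  mats <- data.frame(
    name = c("phantom", "core"), thickness_mm = depth,
    rho = 1070, cp = 3810, k = 0.56,
    mu_a = c(host_optics$mu_a, core_opt$mu_a),
    mu_s = c(host_optics$mu_s, core_opt$mu_s),
    g = host_optics$g, stringsAsFactors = FALSE)

  xc <- (seq_len(nxy) - 0.5) * voxel
  zc <- (z_edges[-1] + z_edges[-(nz + 1)]) / 2
  r2 <- outer(xc - outer_r, xc - outer_r, function(a, b) a^2 + b^2)
  material <- array(0L, dim = c(nxy, nxy, nz))
  inside <- r2 <= outer_r^2
  for (k in seq_len(nz)) material[, , k][inside] <- 1L
  core_mask <- array(FALSE, dim = dim(material))
  in_core_z <- zc <= core_depth
  core_mask[, , in_core_z] <- r2 <= core_r^2
  material[core_mask] <- 2L

  geom <- layered_geometry(material, mats, dx = voxel, dy = voxel,
                           z_edges = z_edges, tumor_mask = core_mask,
                           tumor = list(radius = core_r, length = core_depth,
                                        top_depth = 0,
                                        center = c(outer_r, outer_r),
                                        fv = fv))
  geom$normal_roi_mask <- build_normal_roi(geom, shell = core_r)
  geom
}

#' Thermocouple probe locations for the phantom preset
#'
#' Four probes at 1 mm depth, spaced radially outward from the phantom axis.
#'
#' @param radial_mm Radial offsets from the axis (mm).
#' @param depth_mm Probe depth below the surface (mm).
#' @return Data frame with columns `x`, `y`, `z` in mm.
#' @export
phantom_probe_locations <- function(radial_mm = c(0, 5, 10, 15),
                                    depth_mm = 1) {
  data.frame(x = 20 + radial_mm, y = 20, z = depth_mm)
}
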