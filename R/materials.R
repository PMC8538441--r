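#' Material configuration for the skin stack
#'
#' Reads the layered-skin material table (four skin layers plus tumor) from a
#' YAML configuration. Each entry carries the layer thickness, thermal
#' properties (density rho in kg/m^3, specific heat cp in J/(kg K),
#' conductivity k in W/(m K)) and optical properties (mu_a, mu_s in 1/mm and
#' anisotropy g at 1064 nm). The bundled default encodes the standard
#' epidermis / papillary dermis / reticular dermis / subcutaneous fat stack
#' with a squamous-cell-carcinoma tumor.
#'
#' The returned data frame has one row per material in depth order, the tumor
#' last, with attributes `gnr` (nanorod geometry and calibration anchors) and
#' `tumor` (tumor cylinder geometry).
#'
#' @param path Path to a YAML material file; default is the bundled table.
#' @return A data frame with columns `name`, `thickness_mm`, `rho`, `cp`,
#'   `k`, `mu_a`, `mu_s`, `g`.
#' @examples
#' mats <- skin_materials()
#' mats[, c("name", "thickness_mm", "mu_a", "mu_s")]
#' @export
skin_materials <- function(path = system.file("extdata", "skin_materials.yaml",
                                              package = "gnrtherm")) {
  cfg <- yaml::read_yaml(path)
  rows <- c(cfg$layers, list(cfg$tumor))
  cols <- c("name", "thickness_mm", "rho", "cp", "k", "mu_a", "mu_s", "g")
  df <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$thickness_mm)) r$thickness_mm <- r$length_mm
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  for (col in c("thickness_mm", "rho", "cp", "k")) {
    if (any(!is.finite(df[[col]])) || any(df[[col]] <= 0))
      stop("material property '", col, "' must be positive", call. = FALSE)
  }
  if (any(df$mu_a < 0) || any(df$mu_s < 0))
    stop("optical coefficients must be non-negative", call. = FALSE)
  if (any(abs(df$g) > 1))
    stop("anisotropy g must lie in [-1, 1]", call. = FALSE)
  attr(df, "gnr") <- cfg$gnr
  attr(df, "tumor") <- cfg$tumor
  df
}
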