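# 2-D Cartesian tissue grid: lateral coordinate y (columns of nothing --
# first array index), depth z increasing downward from the air--tissue
# boundary at z = 0. A cell (iy, iz) covers the half-open square
# [iy*d, (iy+1)*d) x [iz*d, (iz+1)*d), 0-based indices.

#' Geometry configuration for the skin model
#'
#' Defines the Cartesian simulation domain: an epidermis of configurable
#' thickness and melanin content above a melanin-free dermis, with one buried
#' hair follicle modelled as a vertical rectangle (the plane section of a
#' cylinder) centred laterally. All lengths are in metres and must be
#' positive multiples of the cell size.
#'
#' @param cell_size Cell edge length, m.
#' @param epidermis_thickness Epidermis thickness, m.
#' @param melanin_fraction_epidermis Melanosome volume fraction of the
#'   epidermis.
#' @param melanin_fraction_hair Melanosome volume fraction of the follicle.
#' @param follicle_top_depth Depth of the follicle top below the surface, m.
#' @param follicle_diameter Follicle diameter, m (0 for a control geometry
#'   with no follicle).
#' @param follicle_length Follicle length, m.
#' @param domain_width Lateral domain extent, m.
#' @param domain_depth Domain depth, m.
#' @return A list of class \code{geometry_config}.
#' @export
geometry_config <- function(cell_size = 5e-6,
                            epidermis_thickness = 80e-6,
                            melanin_fraction_epidermis = 0.05,
                            melanin_fraction_hair = 0.30,
                            follicle_top_depth = 200e-6,
                            follicle_diameter = 200e-6,
                            follicle_length = 2000e-6,
                            domain_width = 3000e-6,
                            domain_depth = 4000e-6) {
  cfg <- list(
    cell_size = cell_size,
    epidermis_thickness = epidermis_thickness,
    melanin_fraction_epidermis = melanin_fraction_epidermis,
    melanin_fraction_hair = melanin_fraction_hair,
    follicle_top_depth = follicle_top_depth,
    follicle_diameter = follicle_diameter,
    follicle_length = follicle_length,
    domain_width = domain_width,
    domain_depth = domain_depth
  )
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  lens <- unlist(cfg[c("epidermis_thickness", "follicle_top_depth",
                       "follicle_diameter", "follicle_length",
                       "domain_width", "domain_depth")])
  mult <- lens / cell_size
  if (any(abs(mult - round(mult)) > 1e-6)) {
    stop("all lengths must be integer multiples of cell_size", call. = FALSE)
  }
  if (any(lens[c("domain_width", "domain_depth")] <= 0)) {
    stop("domain extents must be positive", call. = FALSE)
  }
  if (follicle_diameter > 0) {
    if (follicle_top_depth + follicle_length > domain_depth) {
      stop("follicle extends beyond domain_depth", call. = FALSE)
    }
    if (follicle_diameter > domain_width) {
      stop("follicle wider than domain", call. = FALSE)
    }
  }
  structure(cfg, class = "geometry_config")
}

#' Build the 2-D tissue grid
#'
#' Rasterises the geometry onto the Cartesian cell grid: epidermis rows at
#' the top, the follicle as a centred vertical rectangle of \code{HAIR}
#' cells, dermis everywhere else below the surface. Air lies above row
#' \code{iz = 0} and is not stored.
#'
#' @param config A \code{\link{geometry_config}}.
#' @param optics An \code{\link{optics_params}} object carried along for the
#'   transport stage.
#' @return A list of class \code{tissue_grid} with elements
#'   \code{class_map} (character matrix \code{[ny, nz]}, lateral by depth),
#'   \code{geometry}, \code{thermal} (per-class constants) and \code{optics}.
#' @export
build_grid <- function(config = geometry_config(), optics = optics_params()) {
  d <- config$cell_size
  ny <- as.integer(round(config$domain_width / d))
  nz <- as.integer(round(config$domain_depth / d))
  n_epi <- as.integer(round(config$epidermis_thickness / d))

  cls <- matrix("DERMIS", nrow = ny, ncol = nz)
  if (n_epi > 0) cls[, seq_len(n_epi)] <- "EPIDERMIS"

  w_fol <- as.integer(round(config$follicle_diameter / d))
  if (w_fol > 0) {
    z0 <- as.integer(round(config$follicle_top_depth / d))
    z1 <- as.integer(round((config$follicle_top_depth +
                              config$follicle_length) / d))
    y0 <- as.integer(floor((ny - w_fol) / 2))
    cls[(y0 + 1):(y0 + w_fol), (z0 + 1):min(z1, nz)] <- "HAIR"
  }

  structure(list(
    class_map = cls,
    geometry = config,
    thermal = tissue_thermal(),
    optics = optics,
    melanin_fraction = c(EPIDERMIS = config$melanin_fraction_epidermis,
                         DERMIS = 0,
                         HAIR = config$melanin_fraction_hair)
  ), class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<tissue_grid> %d x %d cells (%.0f um), epidermis %.0f um",
              nrow(x$class_map), ncol(x$class_map), g$cell_size * 1e6,
              g$epidermis_thickness * 1e6))
  n_hair <- sum(x$class_map == "HAIR")
  if (n_hair > 0) {
    cat(sprintf(", follicle %.0f um wide at %.0f--%.0f um depth",
                g$follicle_diameter * 1e6, g$follicle_top_depth * 1e6,
                (g$follicle_top_depth + g$follicle_length) * 1e6))
  } else cat(", no follicle")
  cat("\n")
  invisible(x)
}

#' Locate the two temperature probes
#'
#' The epidermal probe sits 20 um below the surface on the beam axis
#' (lateral centre); the follicular probe sits 10 um (2 cells) inside the
#' lateral follicle boundary at 2000 um depth, where the regrowth-supporting
#' pluripotential stem cells are believed to reside.
#'
#' @param grid A \code{\link{build_grid}} result.
#' @param epidermal_depth Depth of the skin probe, m.
#' @param follicle_depth Depth of the follicular probe, m.
#' @param inset Lateral inset of the follicular probe from the follicle
#'   edge, m.
#' @return A list of class \code{probe_set} with 0-based \code{(iy, iz)}
#'   cell indices \code{epidermal} and \code{follicle}.
#' @export
locate_probes <- function(grid, epidermal_depth = 20e-6,
                          follicle_depth = 2000e-6, inset = 10e-6) {
  d <- grid$geometry$cell_size
  ny <- nrow(grid$class_map)
  iz_epi <- as.integer(round(epidermal_depth / d))
  iy_axis <- as.integer(ny %/% 2)
  iz_fol <- as.integer(round(follicle_depth / d))
  if (iz_fol >= ncol(grid$class_map)) {
    stop("follicle probe depth outside domain", call. = FALSE)
  }
  hair_cols <- which(grid$class_map[, iz_fol + 1] == "HAIR")
  if (length(hair_cols) == 0) {
    stop("no HAIR cells at the follicular probe depth; ",
         "grid has no follicle reaching that depth", call. = FALSE)
  }
  iy_fol <- min(hair_cols) - 1L + as.integer(round(inset / d))
  if (grid$class_map[iy_fol + 1, iz_fol + 1] != "HAIR") {
    stop("follicular probe does not fall inside HAIR cells", call. = FALSE)
  }
  structure(list(
    epidermal = c(iy = iy_axis, iz = iz_epi),
    follicle = c(iy = iy_fol, iz = iz_fol)
  ), class = "probe_set")
}

# integer-coded class map for the C++ kernels
.class_map_int <- function(grid) {
  m <- matrix(.class_code[grid$class_map], nrow = nrow(grid$class_map))
  storage.mode(m) <- "integer"
  m
}
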