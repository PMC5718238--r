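# Human-editable run configuration on disk: one YAML file with sections
# mirroring the constructor arguments. Lengths are given in micrometres in
# the file (the natural unit at this scale) and converted to metres here.

.um <- 1e-6

#' Write a run configuration to YAML
#'
#' @param config A \code{\link{run_config}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  g <- config$geometry; o <- config$optics; s <- config$solver
  doc <- list(
    geometry = list(
      cell_size_um = g$cell_size / .um,
      epidermis_thickness_um = g$epidermis_thickness / .um,
      melanin_fraction_epidermis = g$melanin_fraction_epidermis,
      melanin_fraction_hair = g$melanin_fraction_hair,
      follicle_top_depth_um = g$follicle_top_depth / .um,
      follicle_diameter_um = g$follicle_diameter / .um,
      follicle_length_um = g$follicle_length / .um,
      domain_width_um = g$domain_width / .um,
      domain_depth_um = g$domain_depth / .um
    ),
    optics = list(
      melanin_anchor_694_per_m = o$melanin_anchor_694,
      melanin_exponent = o$melanin_exponent,
      blood_fraction_dermis = o$blood_fraction_dermis,
      water_fraction = as.list(o$water_fraction),
      mus500_per_m = as.list(o$mus500),
      f_rayleigh = o$f_rayleigh,
      b_mie = o$b_mie,
      anisotropy_g = o$g
    ),
    spectrum = list(
      shape = config$spectrum_shape,
      cutoff_nm = config$spectrum_cutoff_nm,
      temperature_K = config$spectrum_temperature_K,
      file = config$spectrum_file
    ),
    beam = list(
      fluence_J_cm2 = config$fluence,
      width_um = if (is.null(config$beam_width)) NULL
                 else config$beam_width / .um
    ),
    transport = list(
      n_photons = config$n_photons,
      seed = config$seed,
      residual = config$residual
    ),
    solver = list(
      dt_s = s$dt,
      t_end_s = s$t_end,
      t_extra_s = s$t_extra,
      baseline_C = s$baseline,
      surface_bc = s$surface_bc,
      h_W_m2K = s$h,
      t_ambient_C = s$t_ambient,
      far_bc = s$far_bc,
      far_T_C = s$far_T
    ),
    comparison = list(
      categories = config$categories,
      threshold_C = config$threshold
    ),
    probes = list(
      epidermal_depth_um = config$probe_epidermal_depth / .um,
      follicle_depth_um = config$probe_follicle_depth / .um
    )
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to the package defaults, so a partial file (say,
#' only a \code{transport:} section) is valid.
#'
#' @param path YAML file path.
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  pick <- function(section, key, default) {
    v <- doc[[section]][[key]]
    if (is.null(v)) default else v
  }
  geometry <- geometry_config(
    cell_size = pick("geometry", "cell_size_um", 5) * .um,
    epidermis_thickness = pick("geometry", "epidermis_thickness_um", 80) * .um,
    melanin_fraction_epidermis = pick("geometry",
                                      "melanin_fraction_epidermis", 0.05),
    melanin_fraction_hair = pick("geometry", "melanin_fraction_hair", 0.30),
    follicle_top_depth = pick("geometry", "follicle_top_depth_um", 200) * .um,
    follicle_diameter = pick("geometry", "follicle_diameter_um", 200) * .um,
    follicle_length = pick("geometry", "follicle_length_um", 2000) * .um,
    domain_width = pick("geometry", "domain_width_um", 3000) * .um,
    domain_depth = pick("geometry", "domain_depth_um", 4000) * .um
  )
  od <- optics_params()
  optics <- optics_params(
    melanin_anchor_694 = pick("optics", "melanin_anchor_694_per_m",
                              od$melanin_anchor_694),
    melanin_exponent = pick("optics", "melanin_exponent",
                            od$melanin_exponent),
    blood_fraction_dermis = pick("optics", "blood_fraction_dermis",
                                 od$blood_fraction_dermis),
    water_fraction = unlist(pick("optics", "water_fraction",
                                 as.list(od$water_fraction))),
    mus500 = unlist(pick("optics", "mus500_per_m", as.list(od$mus500))),
    f_rayleigh = pick("optics", "f_rayleigh", od$f_rayleigh),
    b_mie = pick("optics", "b_mie", od$b_mie),
    g = pick("optics", "anisotropy_g", od$g)
  )
  sd <- solver_config()
  solver <- solver_config(
    dt = pick("solver", "dt_s", sd$dt),
    t_end = pick("solver", "t_end_s", NULL),
    t_extra = pick("solver", "t_extra_s", sd$t_extra),
    baseline = pick("solver", "baseline_C", sd$baseline),
    surface_bc = pick("solver", "surface_bc", sd$surface_bc),
    h = pick("solver", "h_W_m2K", sd$h),
    t_ambient = pick("solver", "t_ambient_C", sd$t_ambient),
    far_bc = pick("solver", "far_bc", sd$far_bc),
    far_T = pick("solver", "far_T_C", pick("solver", "baseline_C",
                                           sd$baseline))
  )
  bw <- pick("beam", "width_um", NULL)
  run_config(
    geometry = geometry,
    optics = optics,
    spectrum_cutoff_nm = pick("spectrum", "cutoff_nm", 695),
    spectrum_temperature_K = pick("spectrum", "temperature_K", 5500),
    spectrum_shape = pick("spectrum", "shape", "blackbody"),
    spectrum_file = pick("spectrum", "file", NULL),
    fluence = pick("beam", "fluence_J_cm2", 10),
    n_photons = pick("transport", "n_photons", 1e6),
    seed = pick("transport", "seed", 20120906),
    beam_width = if (is.null(bw)) NULL else bw * .um,
    residual = pick("transport", "residual", "deposit"),
    solver = solver,
    categories = unlist(pick("comparison", "categories",
                             c("FREE_DISCHARGE", "SQUARE_PULSE",
                               "CLOSE_PULSE_STACK", "SPACED_PULSE_STACK"))),
    threshold = pick("comparison", "threshold_C", 70),
    probe_epidermal_depth = pick("probes", "epidermal_depth_um", 20) * .um,
    probe_follicle_depth = pick("probes", "follicle_depth_um", 2000) * .um
  )
}
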