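# Front end: one configuration drives the whole four-category experiment.
# The transport stage runs once per report -- the absorption matrix is per
# unit fluence and independent of the temporal pulse shape -- then one
# thermal run per category.

#' Run configuration
#'
#' Collects every knob of a comparison run. All arguments have the
#' production defaults; \code{\link{make_fixture}} returns small variants
#' for tests.
#'
#' @param geometry A \code{\link{geometry_config}}.
#' @param optics An \code{\link{optics_params}}.
#' @param spectrum_cutoff_nm,spectrum_temperature_K,spectrum_shape Synthetic
#'   spectrum parameters (see \code{\link{make_synthetic_spectrum}}).
#' @param spectrum_file Optional path to a measured two-column spectrum,
#'   overriding the synthetic one.
#' @param fluence Radiant exposure, J/cm^2.
#' @param n_photons Monte Carlo packet count. Production runs should use
#'   >= 1e4 (a warning is issued below that).
#' @param seed Integer RNG seed.
#' @param beam_width Aperture, m; \code{NULL} = full domain width.
#' @param residual Terminal-weight handling (see \code{\link{run_transport}}).
#' @param solver A \code{\link{solver_config}}.
#' @param categories Pulse categories to compare.
#' @param threshold Follicular damage threshold, deg C.
#' @param probe_epidermal_depth,probe_follicle_depth Probe depths, m
#'   (defaults: 20 um and 2000 um).
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(geometry = geometry_config(),
                       optics = optics_params(),
                       spectrum_cutoff_nm = 695,
                       spectrum_temperature_K = 5500,
                       spectrum_shape = "blackbody",
                       spectrum_file = NULL,
                       fluence = 10,
                       n_photons = 1e6,
                       seed = 20120906,
                       beam_width = NULL,
                       residual = "deposit",
                       solver = solver_config(),
                       categories = c("FREE_DISCHARGE", "SQUARE_PULSE",
                                      "CLOSE_PULSE_STACK",
                                      "SPACED_PULSE_STACK"),
                       threshold = 70,
                       probe_epidermal_depth = 20e-6,
                       probe_follicle_depth = 2000e-6) {
  if (fluence <= 0) stop("fluence must be positive", call. = FALSE)
  if (n_photons < 1e4) {
    warning("n_photons below 1e4; production runs need more packets",
            call. = FALSE)
  }
  structure(list(geometry = geometry, optics = optics,
                 spectrum_cutoff_nm = spectrum_cutoff_nm,
                 spectrum_temperature_K = spectrum_temperature_K,
                 spectrum_shape = spectrum_shape,
                 spectrum_file = spectrum_file,
                 fluence = fluence, n_photons = n_photons, seed = seed,
                 beam_width = beam_width, residual = residual,
                 solver = solver, categories = categories,
                 threshold = threshold,
                 probe_epidermal_depth = probe_epidermal_depth,
                 probe_follicle_depth = probe_follicle_depth),
            class = "run_config")
}

.config_spectrum <- function(config) {
  if (!is.null(config$spectrum_file)) {
    read_spectrum(config$spectrum_file, total_fluence = config$fluence)
  } else {
    make_synthetic_spectrum(cutoff_nm = config$spectrum_cutoff_nm,
                            temperature_K = config$spectrum_temperature_K,
                            shape = config$spectrum_shape,
                            total_fluence = config$fluence)
  }
}

#' Run the full pulse-structure comparison
#'
#' Builds the grid and spectrum, executes the Monte Carlo transport once,
#' then one ADI thermal run per configured pulse category, and assembles the
#' comparison report (peak temperatures, percent-excess matrix, threshold
#' flags, provenance).
#'
#' @param config A \code{\link{run_config}}.
#' @param verbose Print per-stage progress.
#' @return A list of class \code{comparison_report} with elements
#'   \code{metrics} (\code{\link{peak_metrics}}), \code{histories},
#'   \code{absorption}, \code{grid}, \code{probes}, \code{config} and
#'   \code{provenance}.
#' @export
run_comparison <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("[grid] building %s", format(config$geometry$domain_width))
  grid <- build_grid(config$geometry, optics = config$optics)
  probes <- locate_probes(grid,
                          epidermal_depth = config$probe_epidermal_depth,
                          follicle_depth = config$probe_follicle_depth)
  spectrum <- .config_spectrum(config)

  say("[transport] %g photons, seed %d", config$n_photons, config$seed)
  absorption <- run_transport(grid, spectrum, config$n_photons, config$seed,
                              beam_width = config$beam_width,
                              residual = config$residual)

  histories <- list()
  for (cat in config$categories) {
    say("[thermal] %s", cat)
    train <- standard_train(cat, total_fluence = config$fluence)
    histories[[cat]] <- run_simulation(absorption, train, grid,
                                       cfg = config$solver, probes = probes)
  }
  metrics <- peak_metrics(histories, threshold = config$threshold)

  provenance <- list(
    seed = config$seed,
    n_photons = config$n_photons,
    fluence_J_cm2 = config$fluence,
    spectrum_sha1 = .spectrum_hash(spectrum),
    package_version = as.character(utils::packageVersion("iplheat")),
    schema_version = 1L
  )
  structure(list(metrics = metrics, histories = histories,
                 absorption = absorption, grid = grid, probes = probes,
                 config = config, provenance = provenance),
            class = "comparison_report")
}

# content hash of the spectral weights (provenance only): polynomial
# rolling hash mod 2^31 - 1, exact in double arithmetic
.spectrum_hash <- function(spectrum) {
  v <- format(c(spectrum$weights, spectrum$total_fluence), digits = 12)
  h <- 0
  for (b in utf8ToInt(paste(v, collapse = ","))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d categories, %g photons, seed %d, %.3g J/cm^2\n",
              length(x$histories), x$provenance$n_photons,
              x$provenance$seed, x$provenance$fluence_J_cm2))
  print(x$metrics)
  invisible(x)
}

#' Small deterministic fixture configurations
#'
#' Reduced domains and photon counts sized so the full pipeline completes in
#' seconds, for tests and quick exploration.
#'
#' \describe{
#'   \item{tiny_grid}{100 x 100 cells (0.5 x 0.5 mm) with a short shallow
#'     follicle and its probe depth at 250 um; 2e4 photons.}
#'   \item{homogeneous_slab}{uniform dermis, no epidermis pigment contrast,
#'     no follicle.}
#'   \item{no_follicle}{default layering but zero follicle diameter (probe
#'     location fails, by design).}
#' }
#'
#' @param kind Fixture name.
#' @return A \code{\link{run_config}}.
#' @export
make_fixture <- function(kind = c("tiny_grid", "homogeneous_slab",
                                  "no_follicle")) {
  kind <- match.arg(kind)
  small_solver <- solver_config(dt = 1e-4, t_extra = 0.01)
  if (kind == "tiny_grid") {
    geo <- geometry_config(domain_width = 500e-6, domain_depth = 500e-6,
                           follicle_top_depth = 150e-6,
                           follicle_diameter = 100e-6,
                           follicle_length = 300e-6)
    run_config(geometry = geo, n_photons = 2e4, solver = small_solver,
               probe_follicle_depth = 250e-6)
  } else if (kind == "homogeneous_slab") {
    geo <- geometry_config(domain_width = 500e-6, domain_depth = 500e-6,
                           epidermis_thickness = 0,
                           melanin_fraction_epidermis = 0,
                           follicle_diameter = 0)
    run_config(geometry = geo, n_photons = 2e4, solver = small_solver)
  } else {
    geo <- geometry_config(domain_width = 1000e-6, domain_depth = 3000e-6,
                           follicle_diameter = 0)
    run_config(geometry = geo, n_photons = 2e4, solver = small_solver)
  }
}

#' Write / read a comparison report
#'
#' The report body is versioned JSON (metrics, tally, provenance,
#' configuration echo); probe traces go to sibling delimited-text files, one
#' per category; the absorption matrix to the grid-array container.
#' Timestamps are deliberately excluded so a rerun with the same
#' configuration and seed reproduces the files byte for byte.
#'
#' @param report A \code{\link{run_comparison}} result.
#' @param dir Output directory; created if missing.
#' @return \code{write_report}: the directory, invisibly;
#'   \code{read_report}: the parsed report body.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  body <- list(
    schema_version = 1L,
    provenance = report$provenance,
    tally = as.list(report$absorption$tally),
    threshold_C = report$metrics$threshold,
    peaks = report$metrics$table,
    excess_rise_pct = as.list(report$metrics$excess_rise_pct),
    excess_abs_pct = as.list(report$metrics$excess_abs_pct),
    probes = lapply(report$probes, as.list)
  )
  jsonlite::write_json(body, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (cat in names(report$histories)) {
    write_traces(report$histories[[cat]],
                 file.path(dir, paste0("trace_", tolower(cat), ".tsv")))
  }
  write_grid_array(report$absorption$deposited,
                   file.path(dir, "absorption.tsv"),
                   meta = list(units = "per_m_per_unit_exposure",
                               cell_size_m = report$absorption$cell_size,
                               seed = report$absorption$rng_seed,
                               n_photons = report$absorption$n_photons))
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  jsonlite::fromJSON(file.path(dir, "report.json"))
}
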