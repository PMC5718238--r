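# ADI thermal stage: the Monte Carlo absorption matrix, modulated by the
# pulse train's instantaneous power fraction, drives the 2-D heat-flow
# equation  rho c dT/dt = div(k grad T) + H(y, z, t).

#' Solver configuration
#'
#' @param dt Time step, s. The ADI scheme is unconditionally stable; the
#'   default 50 us resolves the shortest (100 us) pulse rise times and is
#'   checked by a self-convergence test.
#' @param t_end Simulation end time, s; \code{NULL} to run to the train
#'   envelope plus \code{t_extra} (so post-pulse probe peaks are captured).
#' @param t_extra Padding after the train envelope when \code{t_end} is
#'   \code{NULL}, s.
#' @param baseline Initial tissue temperature, deg C.
#' @param surface_bc \code{"convective"} (Newton cooling with \code{h} to
#'   \code{t_ambient}) or \code{"adiabatic"}.
#' @param h Surface heat-transfer coefficient, W m^-2 K^-1.
#' @param t_ambient Ambient air temperature, deg C.
#' @param far_bc \code{"fixed"} (deep and lateral boundaries held at
#'   \code{far_T}) or \code{"adiabatic"}.
#' @param far_T Far-field temperature, deg C; defaults to the baseline.
#' @param track_peak_field Record the running per-cell maximum temperature.
#' @return A list of class \code{solver_config}.
#' @export
solver_config <- function(dt = 5e-5, t_end = NULL, t_extra = 0.03,
                          baseline = 35,
                          surface_bc = c("convective", "adiabatic"),
                          h = 10, t_ambient = 20,
                          far_bc = c("fixed", "adiabatic"), far_T = baseline,
                          track_peak_field = FALSE) {
  surface_bc <- match.arg(surface_bc)
  far_bc <- match.arg(far_bc)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  structure(list(dt = dt, t_end = t_end, t_extra = t_extra,
                 baseline = baseline, surface_bc = surface_bc, h = h,
                 t_ambient = t_ambient, far_bc = far_bc, far_T = far_T,
                 track_peak_field = track_peak_field),
            class = "solver_config")
}

# per-cell conductivity and volumetric heat capacity maps
thermal_maps <- function(grid) {
  th <- grid$thermal
  k_by <- structure(th$k, names = th$class)
  rc_by <- structure(th$rho * th$c, names = th$class)
  list(k = matrix(k_by[grid$class_map], nrow = nrow(grid$class_map)),
       rhoc = matrix(rc_by[grid$class_map], nrow = nrow(grid$class_map)))
}

#' Volumetric heat source at a time point
#'
#' \eqn{H(y, z, t) = \mathrm{deposited}(y, z) \times F \times p(t)} where
#' \code{deposited} is the per-unit-exposure absorption matrix, F the
#' radiant exposure and p the train's normalised power fraction; the time
#' integral of H over the train returns the full absorbed energy density.
#'
#' @param absorption An \code{\link{run_transport}} result.
#' @param train A \code{\link{pulse_train}}.
#' @param fluence Radiant exposure, J/cm^2.
#' @param t Time, s (scalar).
#' @return Matrix of source density, W/m^3.
#' @export
volumetric_source <- function(absorption, train, fluence, t) {
  stopifnot(inherits(absorption, "absorption_grid"),
            inherits(train, "pulse_train"), length(t) == 1)
  absorption$deposited * (fluence * 1e4) * power_fraction(train, t)
}

#' One ADI step of the heat-flow equation
#'
#' Advances the temperature field by one Peaceman-Rachford step (implicit in
#' the lateral direction, then implicit in depth; tridiagonal solves per
#' line), with harmonic-mean interface conductances for heterogeneous
#' conductivity. Exposed at this granularity so the scheme can be checked
#' against closed-form diffusion solutions; whole runs go through
#' \code{\link{run_simulation}}.
#'
#' @param T Temperature matrix \code{[ny, nz]}, deg C.
#' @param H Source matrix, W/m^3 (same shape).
#' @param k Conductivity matrix, W m^-1 K^-1 (or scalar).
#' @param rhoc Volumetric heat capacity matrix, J m^-3 K^-1 (or scalar).
#' @param dt Time step, s.
#' @param cell_size Cell edge, m.
#' @param cfg A \code{\link{solver_config}} (boundary conditions).
#' @return The advanced temperature matrix.
#' @export
adi_step <- function(T, H, k, rhoc, dt, cell_size, cfg = solver_config()) {
  ny <- nrow(T); nz <- ncol(T)
  if (length(k) == 1) k <- matrix(k, ny, nz)
  if (length(rhoc) == 1) rhoc <- matrix(rhoc, ny, nz)
  if (length(H) == 1) H <- matrix(H, ny, nz)
  if (!all(dim(H) == dim(T))) stop("mismatched grid shapes", call. = FALSE)
  .adi_step_cpp(T, k, rhoc, H, 1.0, dt, cell_size,
                if (cfg$surface_bc == "convective") 1L else 0L,
                cfg$h, cfg$t_ambient,
                if (cfg$far_bc == "fixed") 1L else 0L, cfg$far_T)
}

#' Run the thermal stage for one pulse train
#'
#' Initialises the field at the baseline temperature and advances the ADI
#' scheme to \code{t_end}, driving it with the absorption matrix modulated
#' by the train's power fraction (evaluated at step midpoints, which is
#' exact for the piecewise-linear trains when segment breakpoints fall on
#' the step grid). Both probes are sampled every step.
#'
#' @param absorption A \code{\link{run_transport}} result.
#' @param train A \code{\link{pulse_train}}.
#' @param grid The \code{\link{build_grid}} the absorption was computed on.
#' @param cfg A \code{\link{solver_config}}.
#' @param probes A \code{\link{locate_probes}} result; located on
#'   \code{grid} if omitted.
#' @param fluence Radiant exposure, J/cm^2; defaults to the spectrum fluence
#'   recorded in \code{absorption}.
#' @return A list of class \code{thermal_history}: \code{times},
#'   \code{epidermal_trace}, \code{follicle_trace} (deg C),
#'   \code{peak_epidermal}, \code{peak_follicle}, \code{baseline},
#'   \code{category}, \code{T_final} and (optional) \code{peak_field}.
#' @export
run_simulation <- function(absorption, train, grid, cfg = solver_config(),
                           probes = locate_probes(grid),
                           fluence = absorption$total_fluence) {
  stopifnot(inherits(absorption, "absorption_grid"),
            inherits(train, "pulse_train"), inherits(grid, "tissue_grid"))
  if (!all(dim(absorption$deposited) == dim(grid$class_map))) {
    stop("absorption grid does not match the tissue grid", call. = FALSE)
  }
  env <- envelope_duration(train)
  t_end <- if (is.null(cfg$t_end)) env + cfg$t_extra else cfg$t_end
  if (t_end < env) {
    stop("t_end shorter than the train envelope; peaks could be missed",
         call. = FALSE)
  }
  nsteps <- as.integer(ceiling(t_end / cfg$dt))
  t_mid <- (seq_len(nsteps) - 0.5) * cfg$dt
  scales <- (fluence * 1e4) * power_fraction(train, t_mid)

  maps <- thermal_maps(grid)
  res <- .run_thermal_cpp(maps$k, maps$rhoc, absorption$deposited,
                          scales, cfg$dt, grid$geometry$cell_size,
                          cfg$baseline,
                          if (cfg$surface_bc == "convective") 1L else 0L,
                          cfg$h, cfg$t_ambient,
                          if (cfg$far_bc == "fixed") 1L else 0L, cfg$far_T,
                          probes$epidermal[["iy"]], probes$epidermal[["iz"]],
                          probes$follicle[["iy"]], probes$follicle[["iz"]],
                          cfg$track_peak_field)
  structure(list(
    times = res$times,
    epidermal_trace = res$epidermal_trace,
    follicle_trace = res$follicle_trace,
    peak_epidermal = max(res$epidermal_trace),
    peak_follicle = max(res$follicle_trace),
    baseline = cfg$baseline,
    category = train$category,
    fluence = fluence,
    T_final = res$T_final,
    peak_field = if (cfg$track_peak_field) res$peak_field else NULL
  ), class = "thermal_history")
}

#' @export
print.thermal_history <- function(x, ...) {
  cat(sprintf("<thermal_history> %s: peak epidermal %.2f C, peak follicle %.2f C (baseline %.1f C, %d samples)\n",
              x$category, x$peak_epidermal, x$peak_follicle, x$baseline,
              length(x$times)))
  invisible(x)
}

#' Comparison metrics across pulse categories
#'
#' Per category: peak probe temperatures and rises above baseline, the
#' percent excess of the free-discharge epidermal peak rise over every other
#' category's, and whether the follicular probe exceeds the damage
#' threshold. Absolute peaks and rises are both reported, and the percent
#' excess is computed on rises (and on absolute peaks, as
#' \code{excess_absolute}).
#'
#' @param histories Named list of \code{thermal_history}, one per category.
#' @param threshold Follicular damage threshold, deg C.
#' @return A list of class \code{peak_metrics}: \code{table} (data.frame),
#'   \code{excess_rise_pct} / \code{excess_abs_pct} (named vectors, percent
#'   excess of free discharge over each other category, when free discharge
#'   is present) and \code{threshold}.
#' @export
peak_metrics <- function(histories, threshold = 70) {
  stopifnot(length(histories) >= 1,
            all(vapply(histories, inherits, TRUE, "thermal_history")))
  cats <- vapply(histories, function(h) h$category, "")
  names(histories) <- cats
  tab <- data.frame(
    category = cats,
    peak_epidermal = vapply(histories, function(h) h$peak_epidermal, 0),
    peak_follicle = vapply(histories, function(h) h$peak_follicle, 0),
    rise_epidermal = vapply(histories,
                            function(h) h$peak_epidermal - h$baseline, 0),
    rise_follicle = vapply(histories,
                           function(h) h$peak_follicle - h$baseline, 0),
    stringsAsFactors = FALSE
  )
  tab$exceeds_threshold <- tab$peak_follicle >= threshold
  rownames(tab) <- NULL

  excess_rise <- excess_abs <- NULL
  if ("FREE_DISCHARGE" %in% cats && length(cats) > 1) {
    fd <- tab[tab$category == "FREE_DISCHARGE", ]
    oth <- tab[tab$category != "FREE_DISCHARGE", ]
    excess_rise <- 100 * (fd$rise_epidermal - oth$rise_epidermal) /
      oth$rise_epidermal
    excess_abs <- 100 * (fd$peak_epidermal - oth$peak_epidermal) /
      oth$peak_epidermal
    names(excess_rise) <- names(excess_abs) <- oth$category
  }
  structure(list(table = tab, excess_rise_pct = excess_rise,
                 excess_abs_pct = excess_abs, threshold = threshold),
            class = "peak_metrics")
}

#' @export
print.peak_metrics <- function(x, ...) {
  cat("<peak_metrics> threshold", x$threshold, "C\n")
  print(x$table, digits = 4)
  if (!is.null(x$excess_rise_pct)) {
    cat("free-discharge epidermal peak-rise excess (%):\n")
    print(round(x$excess_rise_pct, 2))
  }
  invisible(x)
}
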