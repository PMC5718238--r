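#' @useDynLib iplheat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm runif
#' @importFrom utils modifyList read.table write.table
NULL

#' Tissue classes of the skin model
#'
#' The simulation distinguishes four tissue classes: \code{AIR} above the
#' surface, a melanin-rich \code{EPIDERMIS}, a melanin-free \code{DERMIS}, and
#' \code{HAIR} (the buried follicle, treated as strongly pigmented hair-shaft
#' material).
#'
#' @return Character vector of the four class labels.
#' @export
tissue_classes <- function() c("AIR", "EPIDERMIS", "DERMIS", "HAIR")

# integer codes used on the C++ side (AIR never appears inside the grid)
.class_code <- c(AIR = 0L, EPIDERMIS = 1L, DERMIS = 2L, HAIR = 3L)

#' Thermal constants per tissue class
#'
#' Thermal conductivity k (W m^-1 K^-1), density rho (kg m^-3) and specific
#' heat c (J kg^-1 K^-1) for epidermis, dermis and hair. Diffusivity
#' alpha = k/(rho c) is always derived, never stored.
#'
#' @return A data.frame with one row per non-air tissue class and columns
#'   \code{class}, \code{k}, \code{rho}, \code{c}, \code{alpha}.
#' @export
tissue_thermal <- function() {
  d <- data.frame(
    class = c("EPIDERMIS", "DERMIS", "HAIR"),
    k   = c(0.5, 0.53, 0.24),
    rho = c(1200, 1200, 1210),
    c   = c(3600, 3800, 3500),
    stringsAsFactors = FALSE
  )
  d$alpha <- d$k / (d$rho * d$c)
  d
}

# refractive index and anisotropy per class
.tissue_n <- c(EPIDERMIS = 1.34, DERMIS = 1.37, HAIR = 1.7)
.tissue_g <- 0.789

# -- chromophore absorption -------------------------------------------------
#
# The broadband source interacts with three chromophores: melanin (epidermis
# and follicle), oxyhemoglobin (dermal blood) and water. Melanin follows the
# standard melanosome power law mu_a ~ lambda^-3.48 anchored at 694 nm;
# hemoglobin and water use coarse tabulations of the published curves,
# interpolated linearly on the 1-nm spectral grid.

# whole-blood oxyhemoglobin absorption, 1/m (150 g/L Hb, Prahl compilation,
# coarse nodes; linear interpolation between nodes)
.hbo2_nodes <- data.frame(
  nm = c(500, 520, 540, 560, 576, 590, 600, 620, 650, 700, 750,
         800, 850, 900, 950, 1000, 1050, 1100),
  mu = c(11200, 13600, 23300, 17600, 23800, 6900, 1720, 580, 197, 155, 277,
         437, 567, 642, 650, 570, 480, 390)
)

# pure water absorption, 1/m (visible/NIR compilation, coarse nodes)
.water_nodes <- data.frame(
  nm = c(500, 550, 600, 650, 700, 730, 760, 800, 850, 900,
         950, 975, 1000, 1050, 1100),
  mu = c(0.025, 0.045, 0.23, 0.32, 0.62, 1.8, 2.6, 2.0, 4.3, 6.8,
         38.8, 50.0, 36.3, 15.0, 18.0)
)

.check_wavelength <- function(wavelength_nm) {
  if (any(!is.finite(wavelength_nm)) ||
      any(wavelength_nm < 500) || any(wavelength_nm > 1100)) {
    stop("wavelength must lie within the spectral support [500, 1100] nm",
         call. = FALSE)
  }
}

#' Melanin absorption coefficient
#'
#' Absorption coefficient of melanin-containing tissue, modelled as the
#' interior-melanosome power law \code{mu_a(lambda) = A (lambda/694)^-p}
#' scaled linearly by the melanosome volume fraction. The anchor \code{A}
#' (pure-melanosome absorption at 694 nm) and the exponent are exposed because
#' the concentration-to-absorption conversion is a model parameter, not a
#' universal constant.
#'
#' @param wavelength_nm Wavelength in nm, within [500, 1100].
#' @param melanin_fraction Melanosome volume fraction in [0, 1].
#' @param anchor_694 Pure-melanosome absorption at 694 nm, 1/m.
#' @param exponent Power-law exponent (positive; absorption falls with
#'   wavelength).
#' @return Absorption coefficient, 1/m.
#' @export
melanin_mu_a <- function(wavelength_nm, melanin_fraction,
                         anchor_694 = 3.0e4, exponent = 3.48) {
  .check_wavelength(wavelength_nm)
  if (any(melanin_fraction < 0) || any(melanin_fraction > 1)) {
    stop("melanin_fraction must lie in [0, 1]", call. = FALSE)
  }
  melanin_fraction * anchor_694 * (wavelength_nm / 694)^(-exponent)
}

#' Oxyhemoglobin (whole blood) absorption coefficient
#'
#' @param wavelength_nm Wavelength in nm, within [500, 1100].
#' @return Absorption coefficient of fully oxygenated whole blood, 1/m.
#' @export
oxyhemoglobin_mu_a <- function(wavelength_nm) {
  .check_wavelength(wavelength_nm)
  approx(.hbo2_nodes$nm, .hbo2_nodes$mu, xout = wavelength_nm)$y
}

#' Water absorption coefficient
#'
#' @param wavelength_nm Wavelength in nm, within [500, 1100].
#' @return Absorption coefficient of pure water, 1/m.
#' @export
water_mu_a <- function(wavelength_nm) {
  .check_wavelength(wavelength_nm)
  approx(.water_nodes$nm, .water_nodes$mu, xout = wavelength_nm)$y
}

#' Default optical model parameters
#'
#' Collects every tunable coefficient of the wavelength-dependent optics:
#' the melanin power-law anchor and exponent, chromophore content per tissue
#' (water volume fraction, dermal blood volume fraction) and the reduced
#' scattering law \code{mus'(lambda) = a [f_ray (lambda/500)^-4 +
#' (1 - f_ray) (lambda/500)^-b_mie]} converted to \code{mus} with the shared
#' anisotropy factor g.
#'
#' @param melanin_anchor_694 Pure-melanosome absorption at 694 nm, 1/m
#'   (published melanosome values span roughly 2e4--5e4; the default sits
#'   mid-range).
#' @param melanin_exponent Melanin power-law exponent.
#' @param blood_fraction_dermis Dermal blood volume fraction.
#' @param water_fraction Named water volume fractions per tissue class.
#' @param mus500 Named reduced scattering at 500 nm per tissue class, 1/m.
#' @param f_rayleigh Rayleigh fraction of reduced scattering at 500 nm.
#' @param b_mie Mie power-law exponent.
#' @param g Scattering anisotropy factor, shared by all tissues.
#' @return A list of class \code{ipl_optics}.
#' @export
optics_params <- function(melanin_anchor_694 = 3.0e4,
                          melanin_exponent = 3.48,
                          blood_fraction_dermis = 0.005,
                          water_fraction = c(EPIDERMIS = 0.2, DERMIS = 0.65,
                                             HAIR = 0.1),
                          mus500 = c(EPIDERMIS = 6600, DERMIS = 3000,
                                     HAIR = 4500),
                          f_rayleigh = 0.4,
                          b_mie = 0.9,
                          g = .tissue_g) {
  structure(list(
    melanin_anchor_694 = melanin_anchor_694,
    melanin_exponent = melanin_exponent,
    blood_fraction_dermis = blood_fraction_dermis,
    water_fraction = water_fraction,
    mus500 = mus500,
    f_rayleigh = f_rayleigh,
    b_mie = b_mie,
    g = g
  ), class = "ipl_optics")
}

.reduced_scattering <- function(wavelength_nm, mus500_red, f_ray, b_mie) {
  x <- wavelength_nm / 500
  mus500_red * (f_ray * x^(-4) + (1 - f_ray) * x^(-b_mie))
}

#' Wavelength-dependent optical properties of a tissue class
#'
#' Combines the melanin term (per the configured melanosome fraction), the
#' water/blood background and the Mie + Rayleigh scattering law into the
#' interaction coefficients used by the photon walk.
#'
#' @param tissue One of \code{"EPIDERMIS"}, \code{"DERMIS"}, \code{"HAIR"}.
#'   \code{"AIR"} has no interaction coefficients and is rejected.
#' @param wavelength_nm Wavelength in nm, within [500, 1100]. Vectorised.
#' @param melanin_fraction Melanosome volume fraction of this tissue
#'   (0 for dermis at the defaults).
#' @param params An \code{\link{optics_params}} object.
#' @return A data.frame with columns \code{mu_a}, \code{mu_s} (1/m), \code{g}
#'   and \code{n}.
#' @export
tissue_optics <- function(tissue, wavelength_nm,
                          melanin_fraction = c(EPIDERMIS = 0.05, DERMIS = 0,
                                               HAIR = 0.30)[[tissue]],
                          params = optics_params()) {
  tissue <- match.arg(tissue, tissue_classes())
  if (tissue == "AIR") {
    stop("AIR has no interaction coefficients", call. = FALSE)
  }
  .check_wavelength(wavelength_nm)
  mel <- melanin_mu_a(wavelength_nm, melanin_fraction,
                      anchor_694 = params$melanin_anchor_694,
                      exponent = params$melanin_exponent)
  wf <- params$water_fraction[[tissue]]
  bf <- if (tissue == "DERMIS") params$blood_fraction_dermis else 0
  mu_a <- mel + wf * water_mu_a(wavelength_nm) +
    bf * oxyhemoglobin_mu_a(wavelength_nm)
  mus_red <- .reduced_scattering(wavelength_nm, params$mus500[[tissue]],
                                 params$f_rayleigh, params$b_mie)
  data.frame(
    mu_a = mu_a,
    mu_s = mus_red / (1 - params$g),
    g = params$g,
    n = .tissue_n[[tissue]]
  )
}
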