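# Monte Carlo photon transport: scalar sampling primitives (R, for clarity
# and for oracle tests) and the grid walk itself (C++, for the 10^6-photon
# production runs). Both use the same formulas; the walk is exercised against
# the primitives' closed forms in the test suite.

#' Henyey-Greenstein phase function
#'
#' Angular probability density of the single-scattering deflection,
#' \deqn{P(\theta) = (1 - g^2) / (1 + g^2 - 2 g \cos\theta)^{3/2},}
#' normalised so that its mean over the solid angle is 1 (the density per
#' unit solid angle divided by 1/(4 pi)).
#'
#' @param theta Deflection angle, rad. Vectorised.
#' @param g Anisotropy factor, |g| < 1.
#' @return Phase-function value, dimensionless and strictly positive.
#' @export
hg_phase <- function(theta, g) {
  if (abs(g) >= 1) stop("|g| must be < 1", call. = FALSE)
  (1 - g^2) / (1 + g^2 - 2 * g * cos(theta))^1.5
}

#' Sample the scattering deflection cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein deflection:
#' \deqn{\cos\theta = \frac{1}{2g}\left[1 + g^2 -
#'   \left(\frac{1 - g^2}{1 - g + 2 g R}\right)^2\right]} for g != 0, and
#' the isotropic inverse-CDF \eqn{\cos\theta = 2R - 1} for g = 0.
#'
#' @param g Anisotropy factor, |g| < 1.
#' @param R Uniform variate in [0, 1]. Vectorised.
#' @return cos(theta) in [-1, 1]; its expectation over uniform R equals g.
#' @export
sample_deflection <- function(g, R) {
  if (any(R < 0) || any(R > 1)) stop("R must lie in [0, 1]", call. = FALSE)
  if (g == 0) return(2 * R - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * R)
  ct <- (1 + g^2 - f^2) / (2 * g)
  pmin(1, pmax(-1, ct))
}

#' Sample the azimuthal scattering angle
#'
#' The azimuth is uniform on [0, 2 pi): phi = 2 pi R.
#'
#' @param R Uniform variate in [0, 1). Vectorised.
#' @return Azimuth, rad.
#' @export
sample_azimuth <- function(R) {
  if (any(R < 0) || any(R >= 1)) stop("R must lie in [0, 1)", call. = FALSE)
  2 * pi * R
}

#' Sample the free path length
#'
#' Exponential step sampling, s = -ln(R)/mu_t; the mean step equals the mean
#' free path 1/mu_t.
#'
#' @param mu_t Total attenuation coefficient mu_a + mu_s, 1/m; > 0.
#' @param R Uniform variate in (0, 1]. Vectorised.
#' @return Step length, m.
#' @export
sample_path_length <- function(mu_t, R) {
  if (any(mu_t <= 0)) stop("mu_t must be positive", call. = FALSE)
  if (any(R <= 0) || any(R > 1)) stop("R must lie in (0, 1]", call. = FALSE)
  -log(R) / mu_t
}

#' Weight deposited at an interaction site
#'
#' At each interaction a packet of weight W leaves the absorbed share
#' \eqn{\Delta W = W \mu_a / (\mu_a + \mu_s)} in the current cell; the packet
#' continues with weight \eqn{W - \Delta W}.
#'
#' @param W Packet weight before the interaction, > 0.
#' @param mu_a,mu_s Absorption and scattering coefficients, 1/m, with
#'   \code{mu_a + mu_s > 0}.
#' @return The deposited weight Delta W.
#' @export
deposit_weight <- function(W, mu_a, mu_s) {
  if (any(mu_a + mu_s <= 0)) stop("mu_a + mu_s must be positive", call. = FALSE)
  if (any(W <= 0)) stop("W must be positive", call. = FALSE)
  W * mu_a / (mu_a + mu_s)
}

#' Unpolarised Fresnel reflectance at the skin surface
#'
#' Reflected fraction at the air--epidermis boundary for light incident from
#' air, averaged over polarisations; at normal incidence equals
#' \eqn{((n - 1)/(n + 1))^2}.
#'
#' @param n_tissue Tissue refractive index, >= 1.
#' @param incidence Angle of incidence from the surface normal, rad in
#'   [0, pi/2). Vectorised.
#' @return Reflectance in [0, 1].
#' @export
surface_fresnel <- function(n_tissue, incidence = 0) {
  if (n_tissue < 1) stop("n_tissue must be >= 1", call. = FALSE)
  st <- sin(incidence)
  stt <- st / n_tissue                       # Snell, from air (n = 1)
  ct <- cos(incidence)
  ctt <- sqrt(pmax(0, 1 - stt^2))
  rs <- ((ct - n_tissue * ctt) / (ct + n_tissue * ctt))^2
  rp <- ((n_tissue * ct - ctt) / (n_tissue * ct + ctt))^2
  r <- (rs + rp) / 2
  r[incidence == 0] <- ((n_tissue - 1) / (n_tissue + 1))^2
  pmin(1, r)
}

# per-wavelength coefficient tables for the C++ walk: [600, 3] matrices,
# columns in class-code order EPIDERMIS, DERMIS, HAIR
.optics_tables <- function(grid) {
  lam <- .spectrum_bins()
  classes <- c("EPIDERMIS", "DERMIS", "HAIR")
  mua <- mus <- matrix(0, nrow = length(lam), ncol = 3)
  for (k in seq_along(classes)) {
    op <- tissue_optics(classes[k], lam,
                        melanin_fraction = grid$melanin_fraction[[classes[k]]],
                        params = grid$optics)
    mua[, k] <- op$mu_a
    mus[, k] <- op$mu_s
  }
  list(mua = mua, mus = mus)
}

#' Run the Monte Carlo transport stage
#'
#' Launches weighted photon packets at the surface (uniform irradiance
#' across the beam aperture, normal incidence), walks them through the grid
#' with exponential steps, per-interaction weight deposition and
#' Henyey-Greenstein redirection, and terminates each packet when a
#' hundredth of its original weight remains (residual deposited in the
#' terminal cell by default, so energy is conserved exactly) or when it
#' leaves the domain. Packets escaping through the surface are tallied as
#' diffuse reflectance; deep and lateral escapes as transmittance.
#'
#' @param grid A \code{\link{build_grid}} result.
#' @param spectrum An \code{\link{emission_spectrum}}; each packet draws its
#'   wavelength from it.
#' @param n_photons Number of packets, >= 1.
#' @param seed Integer RNG seed; mandatory, recorded in the result.
#' @param beam_width Aperture width, m; \code{NULL} for the full domain
#'   width. The beam is centred laterally.
#' @param residual \code{"deposit"} (default; terminal residual weight goes
#'   into the current cell) or \code{"discard"} (the tabulated termination
#'   rule taken literally; the lost fraction is reported in the tally).
#' @param lateral_boundary \code{"mirror"} (default; lateral domain faces
#'   reflect, emulating an infinite broad field by symmetry) or
#'   \code{"escape"} (lateral escapes tallied as transmitted).
#' @return A list of class \code{absorption_grid}: \code{deposited}
#'   (\code{[ny, nz]}, absorbed energy density per unit radiant exposure,
#'   (J/m^3)/(J/m^2) = 1/m), \code{tally} (five fractions summing to 1),
#'   \code{n_photons}, \code{rng_seed}, \code{beam_width}, \code{cell_size},
#'   \code{total_fluence} (J/cm^2, from the spectrum).
#' @export
run_transport <- function(grid, spectrum, n_photons, seed,
                          beam_width = NULL,
                          residual = c("deposit", "discard"),
                          lateral_boundary = c("mirror", "escape")) {
  stopifnot(inherits(grid, "tissue_grid"), inherits(spectrum, "emission_spectrum"))
  residual <- match.arg(residual)
  lateral_boundary <- match.arg(lateral_boundary)
  if (n_photons < 1) stop("n_photons must be >= 1", call. = FALSE)
  if (missing(seed) || !is.finite(seed)) {
    stop("an integer RNG seed is required", call. = FALSE)
  }
  d <- grid$geometry$cell_size
  Ly <- nrow(grid$class_map) * d
  if (is.null(beam_width)) beam_width <- Ly
  if (beam_width <= 0 || beam_width > Ly + 1e-12) {
    stop("beam_width must lie in (0, domain_width]", call. = FALSE)
  }
  y0 <- (Ly - beam_width) / 2

  tab <- .optics_tables(grid)
  set.seed(as.integer(seed))
  res <- .mc_transport_cpp(.class_map_int(grid), tab$mua, tab$mus,
                           grid$optics$g, .tissue_n[["EPIDERMIS"]], d,
                           y0, y0 + beam_width,
                           cumsum(spectrum$weights),
                           as.integer(n_photons), 0.01,
                           residual == "deposit",
                           lateral_boundary == "mirror")

  # fractions -> energy density per unit radiant exposure (1/m):
  # a cell holding fraction f of the launched energy F * beam_width (per
  # unit out-of-plane length) has density f * F * beam_width / d^2.
  deposited <- res$numabs / n_photons * beam_width / d^2
  tally <- c(specular_reflected = res$specular_reflected,
             diffuse_reflected = res$diffuse_reflected,
             transmitted = res$transmitted,
             absorbed = res$absorbed,
             terminated_residual = res$terminated_residual)
  structure(list(
    deposited = deposited,
    tally = tally,
    n_photons = as.integer(n_photons),
    rng_seed = as.integer(seed),
    beam_width = beam_width,
    cell_size = d,
    total_fluence = spectrum$total_fluence
  ), class = "absorption_grid")
}

#' @export
print.absorption_grid <- function(x, ...) {
  cat(sprintf("<absorption_grid> %d x %d cells, %.3g photons, seed %d\n",
              nrow(x$deposited), ncol(x$deposited), x$n_photons, x$rng_seed))
  cat(sprintf("  tally: specular %.4f, diffuse refl %.4f, transmitted %.4f, absorbed %.4f, residual %.4f\n",
              x$tally[1], x$tally[2], x$tally[3], x$tally[4], x$tally[5]))
  invisible(x)
}
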