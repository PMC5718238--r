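# Broadband emission spectrum on a fixed 1-nm grid, 500--1100 nm (600 bins).
# The binning is deliberately rigid: arbitrary grids are rejected rather than
# silently resampled, so every consumer sees the same 600-wavelength
# discretisation of the source.

.spectrum_bins <- function() seq(500L, 1099L, by = 1L)

#' Construct an emission spectrum
#'
#' @param weights Relative intensity per 1-nm bin; length 600, non-negative,
#'   not all zero. Normalised to sum to 1.
#' @param total_fluence Radiant exposure carried by the whole spectrum,
#'   J/cm^2.
#' @return A list of class \code{emission_spectrum} with \code{wavelengths}
#'   (bin centres, nm), normalised \code{weights} and \code{total_fluence}.
#' @export
emission_spectrum <- function(weights, total_fluence = 10) {
  if (length(weights) != 600) {
    stop("spectrum must have exactly 600 bins (1 nm from 500 to 1100 nm)",
         call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  s <- sum(weights)
  if (s <= 0) stop("all-zero weight vector", call. = FALSE)
  if (total_fluence <= 0) stop("total_fluence must be positive", call. = FALSE)
  structure(list(
    wavelengths = .spectrum_bins(),
    weights = weights / s,
    total_fluence = total_fluence
  ), class = "emission_spectrum")
}

#' Synthetic filtered-flashlamp spectrum
#'
#' Emulates a filtered xenon-flashlamp emission as a blackbody (Planck)
#' envelope at a configurable plasma temperature, long-pass filtered at a
#' cutoff wavelength and truncated at 1100 nm, on the fixed 1-nm grid. A
#' measured spectrum can be substituted via \code{\link{read_spectrum}}.
#'
#' @param cutoff_nm Long-pass filter edge, nm, within [500, 1100]; bins below
#'   the cutoff carry zero weight. The default 695 nm matches the long-pass
#'   filters typical of photoepilation handpieces.
#' @param temperature_K Blackbody plasma temperature, K.
#' @param shape \code{"blackbody"} or \code{"flat"} (uniform over the pass
#'   band).
#' @param total_fluence Radiant exposure, J/cm^2.
#' @return An \code{\link{emission_spectrum}}.
#' @export
make_synthetic_spectrum <- function(cutoff_nm = 695, temperature_K = 5500,
                                    shape = c("blackbody", "flat"),
                                    total_fluence = 10) {
  shape <- match.arg(shape)
  if (cutoff_nm < 500 || cutoff_nm > 1100) {
    stop("cutoff must lie within [500, 1100] nm", call. = FALSE)
  }
  lam <- .spectrum_bins()
  w <- if (shape == "flat") {
    rep(1, length(lam))
  } else {
    # spectral radiance per unit wavelength, arbitrary scale
    h <- 6.62607015e-34; c0 <- 299792458; kB <- 1.380649e-23
    lm <- lam * 1e-9
    1 / (lm^5 * (exp(h * c0 / (lm * kB * temperature_K)) - 1))
  }
  w[lam < cutoff_nm] <- 0
  emission_spectrum(w, total_fluence = total_fluence)
}

#' @export
print.emission_spectrum <- function(x, ...) {
  nz <- which(x$weights > 0)
  cat(sprintf(
    "<emission_spectrum> 600 x 1 nm bins, support %d--%d nm, %.3g J/cm^2\n",
    x$wavelengths[min(nz)], x$wavelengths[max(nz)], x$total_fluence))
  invisible(x)
}

#' Inverse-CDF wavelength sampling
#'
#' Maps uniform variates in [0, 1) to wavelength bins so that empirical bin
#' frequencies converge to the spectral weights.
#'
#' @param spectrum An \code{\link{emission_spectrum}}.
#' @param u Uniform random variates in [0, 1). Vectorised.
#' @return Wavelengths, nm (bin centres).
#' @export
sample_wavelength <- function(spectrum, u) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (any(u < 0) || any(u >= 1)) stop("u must lie in [0, 1)", call. = FALSE)
  cdf <- cumsum(spectrum$weights)
  idx <- findInterval(u, cdf, left.open = FALSE) + 1L
  spectrum$wavelengths[pmin(idx, 600L)]
}

#' Energy carried by one photon packet
#'
#' Dividing the total radiant exposure equally over the launched packets
#' guarantees that the ensemble carries exactly the configured fluence for
#' any packet count.
#'
#' @param spectrum An \code{\link{emission_spectrum}}.
#' @param n_photons Number of launched packets, >= 1.
#' @return Radiant exposure per packet, J/cm^2.
#' @export
photon_energy <- function(spectrum, n_photons) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (n_photons < 1) stop("n_photons must be >= 1", call. = FALSE)
  spectrum$total_fluence / n_photons
}

#' Read / write a spectrum as two-column delimited text
#'
#' The on-disk format is two whitespace-separated columns
#' (\code{wavelength_nm}, \code{relative_intensity}) with a \code{#} comment
#' header, so a measured lamp spectrum can replace the synthetic default.
#' The wavelength column must be exactly the 1-nm grid 500--1099 nm.
#'
#' @param path File path.
#' @param total_fluence Radiant exposure to attach on read, J/cm^2.
#' @return \code{read_spectrum}: an \code{\link{emission_spectrum}};
#'   \code{write_spectrum}: the path, invisibly.
#' @export
read_spectrum <- function(path, total_fluence = 10) {
  d <- read.table(path, header = FALSE, comment.char = "#",
                  col.names = c("wavelength_nm", "relative_intensity"))
  if (!identical(as.integer(d$wavelength_nm), .spectrum_bins())) {
    stop("spectrum file must use the fixed 1-nm grid 500..1099 nm",
         call. = FALSE)
  }
  emission_spectrum(d$relative_intensity, total_fluence = total_fluence)
}

#' @rdname read_spectrum
#' @param spectrum An \code{\link{emission_spectrum}} to write.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# wavelength_nm relative_intensity", con)
  write.table(data.frame(spectrum$wavelengths, signif(spectrum$weights, 10)),
              con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
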