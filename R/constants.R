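# Physical constants and unit conversions used across the package.
# The keV -> J factor is the 2019 SI exact elementary charge scaled to keV.

KEV_TO_J <- 1.602176634e-16     # J per keV
MGY_PER_MBQ_S <- 1e9            # (mGy/MBq-s) per (Gy/decay)
ELECTRON_MASS_KEV <- 510.998950 # electron rest energy, keV
FINE_STRUCTURE <- 7.2973525693e-3
COMPTON_FM <- 386.15927         # reduced electron Compton wavelength, fm

# Density assumed for both marrow compartments and for the soft-tissue
# transport medium (g/cm^3). Taking AM and IM densities equal makes the
# volume fractions in the cellularity definition interchangeable with mass
# fractions.
TISSUE_DENSITY <- 1.03

#' Default energy grid for continuous beta spectra
#'
#' 1 keV spacing starting at 0.5 keV, extending just past `max_keV`. Finer
#' than any SAF energy grid, so quadrature error in the spectrum-SAF
#' convolution is negligible next to the SAF uncertainty itself.
#'
#' @param max_keV upper energy bound, typically the largest beta endpoint.
#' @return numeric vector of strictly increasing energies in keV.
#' @export
default_energy_grid <- function(max_keV) {
  if (!is.numeric(max_keV) || length(max_keV) != 1L || !is.finite(max_keV) ||
      max_keV <= 0.5) {
    stop("`max_keV` must be a single finite value > 0.5 keV", call. = FALSE)
  }
  seq(0.5, max_keV + 1, by = 1)
}

# Numeric formatting used by every writer: 15 significant digits round-trip
# exactly for the short-decimal constants and generator outputs the package
# produces, while keeping files human-readable.
fmt_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE),
         character(1))
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
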