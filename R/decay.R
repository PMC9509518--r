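# Radionuclide emission data: continuous beta branches plus discrete
# conversion/Auger electron lines, and the per-decay spectrum summaries
# (mean beta energy, total electron energy, low-energy electron counts).

#' Construct a beta decay branch
#'
#' @param endpoint_keV maximum (endpoint) kinetic energy of the branch, keV.
#' @param fraction branching fraction, decays through this branch per decay.
#' @param daughter_Z atomic number of the daughter nucleus (Coulomb field for
#'   the Fermi function). `0` disables the Coulomb correction.
#' @param kind transition shape: `"allowed"` or `"first_forbidden_unique"`.
#' @return a `beta_branch` list.
#' @export
beta_branch <- function(endpoint_keV, fraction, daughter_Z,
                        kind = c("allowed", "first_forbidden_unique")) {
  kind <- match.arg(kind)
  if (!is.numeric(endpoint_keV) || endpoint_keV <= 0) {
    stop("beta branch endpoint must be > 0 keV", call. = FALSE)
  }
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("branching fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(daughter_Z) || daughter_Z < 0) {
    stop("daughter_Z must be >= 0", call. = FALSE)
  }
  structure(list(endpoint_keV = endpoint_keV, fraction = fraction,
                 daughter_Z = daughter_Z, kind = kind),
            class = "beta_branch")
}

#' Construct a discrete electron emission line
#'
#' @param energy_keV line energy, keV.
#' @param yield electrons per decay (may exceed 1 for Auger cascades).
#' @param kind `"conversion"` or `"auger"`.
#' @return a `discrete_emission` list.
#' @export
discrete_emission <- function(energy_keV, yield,
                              kind = c("conversion", "auger")) {
  kind <- match.arg(kind)
  if (!is.numeric(energy_keV) || energy_keV <= 0) {
    stop("discrete emission energy must be > 0 keV", call. = FALSE)
  }
  if (!is.numeric(yield) || yield < 0) {
    stop("discrete emission yield must be >= 0", call. = FALSE)
  }
  structure(list(energy_keV = energy_keV, yield = yield, kind = kind),
            class = "discrete_emission")
}

#' Assemble radionuclide emission data
#'
#' Container for everything the S-value and transport engines need about one
#' nuclide: its beta branches and its discrete conversion/Auger electron
#' lines. Photons are deliberately absent; all downstream quantities are
#' electron-only.
#'
#' @param name nuclide identifier, e.g. `"lu177"`.
#' @param half_life_days physical half-life in days.
#' @param beta_branches list of [beta_branch()] objects (may be empty).
#' @param discrete list of [discrete_emission()] objects (may be empty).
#' @return a `radionuclide` object.
#' @export
radionuclide <- function(name, half_life_days, beta_branches = list(),
                         discrete = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("nuclide name must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(half_life_days) || half_life_days <= 0) {
    stop("half-life must be > 0 days", call. = FALSE)
  }
  stopifnot(is.list(beta_branches), is.list(discrete))
  for (b in beta_branches) {
    if (!inherits(b, "beta_branch")) stop("invalid beta branch", call. = FALSE)
  }
  for (d in discrete) {
    if (!inherits(d, "discrete_emission")) {
      stop("invalid discrete emission", call. = FALSE)
    }
  }
  total <- sum(vapply(beta_branches, `[[`, numeric(1), "fraction"))
  if (total > 1 + 1e-6) {
    stop(sprintf("beta branching fractions sum to %.6f > 1", total),
         call. = FALSE)
  }
  structure(list(name = name, half_life_days = half_life_days,
                 beta_branches = beta_branches, discrete = discrete),
            class = "radionuclide")
}

#' @export
print.radionuclide <- function(x, ...) {
  cat(sprintf("<radionuclide %s>  half-life %.4g d\n", x$name,
              x$half_life_days))
  cat(sprintf("  beta branches: %d (total intensity %.4f)\n",
              length(x$beta_branches), total_beta_intensity(x)))
  cat(sprintf("  discrete lines: %d (%.4g electrons/decay)\n",
              length(x$discrete),
              sum(vapply(x$discrete, `[[`, numeric(1), "yield"))))
  invisible(x)
}

total_beta_intensity <- function(nuclide) {
  sum(vapply(nuclide$beta_branches, `[[`, numeric(1), "fraction"))
}

discrete_table <- function(nuclide) {
  if (length(nuclide$discrete) == 0L) {
    return(data.frame(energy_keV = numeric(0), yield = numeric(0),
                      kind = character(0)))
  }
  data.frame(
    energy_keV = vapply(nuclide$discrete, `[[`, numeric(1), "energy_keV"),
    yield = vapply(nuclide$discrete, `[[`, numeric(1), "yield"),
    kind = vapply(nuclide$discrete, `[[`, character(1), "kind")
  )
}

#' Build the continuous spectrum of one beta branch
#'
#' Evaluates the Fermi-theory spectral shape on `grid` and normalises it so
#' the trapezoidal integral over the grid equals the branching fraction.
#'
#' @param branch a [beta_branch()].
#' @param grid strictly increasing energies (keV) covering
#'   `(0, endpoint_keV]`.
#' @return an `energy_spectrum`: list with `grid` (keV) and `density`
#'   (electrons per decay per keV).
#' @export
build_beta_spectrum <- function(branch, grid) {
  stopifnot(inherits(branch, "beta_branch"))
  if (length(grid) < 2L || any(!is.finite(grid))) {
    stop("energy grid must hold at least two finite values", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("energy grid must be strictly increasing", call. = FALSE)
  }
  if (min(grid) <= 0) stop("energy grid must be positive", call. = FALSE)
  if (max(grid) < branch$endpoint_keV) {
    stop(sprintf("grid ends at %.6g keV, below the %.6g keV endpoint",
                 max(grid), branch$endpoint_keV), call. = FALSE)
  }
  d <- beta_shape(grid, branch$endpoint_keV, branch$daughter_Z,
                  kind = branch$kind)
  area <- trapz(grid, d)
  density <- if (branch$fraction == 0 || area == 0) {
    rep(0, length(grid))
  } else {
    d * (branch$fraction / area)
  }
  structure(list(grid = grid, density = density), class = "energy_spectrum")
}

#' Composite electron emission spectrum of a nuclide
#'
#' Sums all beta branch spectra on a common grid; discrete lines are passed
#' through untouched (never histogrammed, so low-energy Auger energies stay
#' exact).
#'
#' @param nuclide a [radionuclide()].
#' @param grid energy grid in keV; default [default_energy_grid()] up to the
#'   largest endpoint.
#' @return list with `spectrum` (an `energy_spectrum`) and `discrete`
#'   (data frame of lines: `energy_keV`, `yield`, `kind`).
#' @export
composite_electron_spectrum <- function(nuclide, grid = NULL) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (is.null(grid)) {
    max_ep <- if (length(nuclide$beta_branches) > 0L) {
      max(vapply(nuclide$beta_branches, `[[`, numeric(1), "endpoint_keV"))
    } else {
      1
    }
    grid <- default_energy_grid(max_ep)
  }
  density <- rep(0, length(grid))
  for (b in nuclide$beta_branches) {
    density <- density + build_beta_spectrum(b, grid)$density
  }
  list(spectrum = structure(list(grid = grid, density = density),
                            class = "energy_spectrum"),
       discrete = discrete_table(nuclide))
}

#' Mean energy of the composite beta spectrum
#'
#' Energy-weighted mean of the continuous spectrum divided by the total beta
#' intensity, in keV per beta transition.
#'
#' @inheritParams composite_electron_spectrum
#' @return mean beta energy, keV.
#' @export
mean_beta_energy <- function(nuclide, grid = NULL) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (length(nuclide$beta_branches) == 0L) {
    stop("mean beta energy is undefined: nuclide has no beta branches",
         call. = FALSE)
  }
  sp <- composite_electron_spectrum(nuclide, grid)$spectrum
  trapz(sp$grid, sp$grid * sp$density) / trapz(sp$grid, sp$density)
}

#' Count discrete electrons below an energy threshold
#'
#' @inheritParams composite_electron_spectrum
#' @param threshold_keV energy threshold, keV (> 0); lines strictly below it
#'   are counted.
#' @return electrons per decay.
#' @export
count_electrons_below <- function(nuclide, threshold_keV) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (!is.numeric(threshold_keV) || threshold_keV <= 0) {
    stop("threshold must be > 0 keV", call. = FALSE)
  }
  d <- discrete_table(nuclide)
  sum(d$yield[d$energy_keV < threshold_keV])
}

#' Total electron energy emitted per decay
#'
#' Continuous contribution (integral of E times the composite beta density)
#' plus the discrete line sum of yield times energy. This is the electron
#' part of the MIRD mean energy per nuclear transformation.
#'
#' @inheritParams composite_electron_spectrum
#' @return keV per decay.
#' @export
total_electron_energy <- function(nuclide, grid = NULL) {
  stopifnot(inherits(nuclide, "radionuclide"))
  cont <- 0
  if (length(nuclide$beta_branches) > 0L) {
    sp <- composite_electron_spectrum(nuclide, grid)$spectrum
    cont <- trapz(sp$grid, sp$grid * sp$density)
  }
  d <- discrete_table(nuclide)
  cont + sum(d$yield * d$energy_keV)
}
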