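# R-side interface to the condensed-history transport kernel: configuration,
# source sampling tables, tallies and radial summaries.

#' Transport configuration
#'
#' @param n_decays number of decays to simulate (>= 1).
#' @param voxel_side_um cubic voxel side, micrometres (defaults follow the
#'   skeletal model resolution, 50 um, and the hematopoietic stem cell
#'   diameter, 8.2 um).
#' @param tally_extent_um half-width of the cubic tally region, um. Energy
#'   deposited outside the grid still counts towards the deposition total and
#'   the radial profile.
#' @param seed optional integer seed applied before sampling.
#' @param step_fraction fraction of the residual CSDA range per condensed
#'   step, in (0, 0.2]; steps are additionally capped at half a voxel side.
#' @param cutoff_keV energy below which the electron is absorbed locally.
#' @return a `transport_config` list.
#' @export
transport_config <- function(n_decays = 1e5, voxel_side_um = 50,
                             tally_extent_um = 200, seed = NULL,
                             step_fraction = 0.05, cutoff_keV = 1) {
  if (!is.numeric(n_decays) || n_decays < 1) {
    stop("n_decays must be >= 1", call. = FALSE)
  }
  if (!is.numeric(voxel_side_um) || voxel_side_um <= 0) {
    stop("voxel_side_um must be > 0", call. = FALSE)
  }
  if (!is.numeric(step_fraction) || step_fraction <= 0 ||
      step_fraction > 0.2) {
    stop("step_fraction must lie in (0, 0.2]", call. = FALSE)
  }
  if (tally_extent_um < voxel_side_um / 2) {
    stop("tally_extent_um must cover at least the central voxel",
         call. = FALSE)
  }
  n_vox <- (2 * floor(tally_extent_um / voxel_side_um) + 1)^3
  if (n_vox > 3e7) {
    stop("tally grid would hold > 3e7 voxels; reduce tally_extent_um or ",
         "enlarge voxel_side_um", call. = FALSE)
  }
  structure(list(n_decays = as.integer(round(n_decays)),
                 voxel_side_um = voxel_side_um,
                 tally_extent_um = tally_extent_um, seed = seed,
                 step_fraction = step_fraction, cutoff_keV = cutoff_keV),
            class = "transport_config")
}

# Sampling inputs for the kernel: inverse-CDF table of the composite beta
# spectrum plus the discrete line list.
emission_sampler <- function(nuclide) {
  d <- discrete_table(nuclide)
  intensity <- total_beta_intensity(nuclide)
  if (intensity > 0) {
    sp <- composite_electron_spectrum(nuclide)$spectrum
    cdf <- c(0, cumsum((sp$density[-1] + sp$density[-length(sp$density)]) *
                         diff(sp$grid) / 2))
    cdf <- cdf / cdf[length(cdf)]
    keep <- c(TRUE, diff(cdf) > 0)
    list(energy = sp$grid[keep], cdf = cdf[keep], intensity = intensity,
         line_energy = d$energy_keV, line_yield = d$yield)
  } else {
    list(energy = numeric(0), cdf = numeric(0), intensity = 0,
         line_energy = d$energy_keV, line_yield = d$yield)
  }
}

max_emission_energy <- function(nuclide) {
  eps <- vapply(nuclide$beta_branches, `[[`, numeric(1), "endpoint_keV")
  d <- discrete_table(nuclide)
  max(c(eps, d$energy_keV, 1))
}

run_kernel <- function(nuclide, config, source_mode) {
  g <- transport_grid()
  em <- emission_sampler(nuclide)
  # radial profile out to the maximum CSDA range (plus margin)
  r_max <- 1.1 * exp(approx(log(g$energy_keV), log(g$range_um),
                            xout = log(min(max_emission_energy(nuclide), 1e4)),
                            ties = "ordered")$y)
  radial_bin <- config$voxel_side_um / 4
  n_radial <- max(8L, as.integer(ceiling(r_max / radial_bin)) + 1L)
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .transport_simulate(em$energy, em$cdf, em$intensity,
                             em$line_energy, em$line_yield,
                             g$energy_keV, g$range_um, g$collision_fraction,
                             config$n_decays, config$voxel_side_um,
                             config$tally_extent_um, config$step_fraction,
                             config$cutoff_keV, source_mode,
                             radial_bin, n_radial)
  res$radial_bin_um <- radial_bin
  res
}

new_tally <- function(res, config, nuclide_name, source_mode) {
  N <- res$grid_dim
  structure(list(
    nuclide = nuclide_name,
    source = if (source_mode == 0L) "point" else "uniform_voxel",
    voxel_side_um = config$voxel_side_um,
    grid = array(res$grid, dim = c(N, N, N)),
    half_n = res$half_n,
    n_decays = res$n_decays,
    total_emitted_keV = res$total_emitted_keV,
    total_deposited_keV = res$total_deposited_keV,
    radial_keV = res$radial_keV,
    radial_bin_um = res$radial_bin_um,
    radial_overflow_keV = res$radial_overflow_keV,
    central_sums = res$central_sums,
    config = config), class = "deposition_tally")
}

#' @export
print.deposition_tally <- function(x, ...) {
  cat(sprintf("<deposition_tally %s, %s source>\n", x$nuclide, x$source))
  cat(sprintf("  %d decays, %g um voxels, grid %d^3\n", x$n_decays,
              x$voxel_side_um, dim(x$grid)[1]))
  cat(sprintf("  emitted %.4g keV, deposited %.4g keV (%.1f%%)\n",
              x$total_emitted_keV, x$total_deposited_keV,
              100 * x$total_deposited_keV / x$total_emitted_keV))
  invisible(x)
}

#' Simulate a point source and tally voxel energy deposition
#'
#' Samples per-decay electron emissions (beta energies by inverse CDF of the
#' composite spectrum, discrete lines by yield), transports each electron by
#' condensed random-walk steps with continuous energy loss and multiple
#' scattering, and tallies deposited energy in cubic voxels around the
#' origin. Identical seeds give identical tallies.
#'
#' @param nuclide a [radionuclide()].
#' @param config a [transport_config()].
#' @return a `deposition_tally`.
#' @export
simulate_point_source <- function(nuclide, config = transport_config()) {
  stopifnot(inherits(nuclide, "radionuclide"),
            inherits(config, "transport_config"))
  res <- run_kernel(nuclide, config, source_mode = 0L)
  new_tally(res, config, nuclide$name, 0L)
}

#' Fraction of emitted energy self-absorbed in one voxel
#'
#' Homogeneous activity in a single cubic voxel: decay positions are drawn
#' uniformly inside the central voxel and the tallied quantity is the
#' fraction of all emitted electron energy deposited inside that same voxel.
#'
#' @param nuclide a [radionuclide()].
#' @param voxel_side_um voxel side, micrometres.
#' @param config a [transport_config()]; its `voxel_side_um` is overridden.
#' @return list with `fraction`, `se` (delta-method standard error over
#'   decays), `n_decays`, `voxel_side_um`, and the full `tally`.
#' @export
central_voxel_fraction <- function(nuclide, voxel_side_um = 50,
                                   config = transport_config()) {
  stopifnot(inherits(nuclide, "radionuclide"),
            inherits(config, "transport_config"))
  config$voxel_side_um <- voxel_side_um
  config$tally_extent_um <- max(config$tally_extent_um, voxel_side_um)
  res <- run_kernel(nuclide, config, source_mode = 1L)
  s <- res$central_sums
  n <- res$n_decays
  mu_d <- s[["sum_dc"]] / n
  mu_e <- s[["sum_em"]] / n
  f <- mu_d / mu_e
  var_d <- s[["sum_dc2"]] / n - mu_d^2
  var_e <- s[["sum_em2"]] / n - mu_e^2
  cov_de <- s[["sum_dcem"]] / n - mu_d * mu_e
  se <- sqrt(pmax(var_d - 2 * f * cov_de + f^2 * var_e, 0) / n) / mu_e
  list(fraction = f, se = se, n_decays = n, voxel_side_um = voxel_side_um,
       tally = new_tally(res, config, nuclide$name, 1L))
}

#' Radii containing given percentiles of the emitted energy
#'
#' Smallest radius r such that the cumulative energy deposited within r
#' reaches each percentile of the total *emitted* energy, from the tally's
#' radial profile. Monotone in the percentile by construction.
#'
#' @param tally a `deposition_tally`.
#' @param percentiles percentages in (0, 100).
#' @return named numeric vector of radii in micrometres; `NA` where the
#'   percentile is never reached (energy escaping as bremsstrahlung).
#' @export
energy_percentile_radii <- function(tally, percentiles = c(30, 50, 90)) {
  stopifnot(inherits(tally, "deposition_tally"))
  if (any(percentiles <= 0) || any(percentiles >= 100)) {
    stop("percentiles must lie strictly between 0 and 100", call. = FALSE)
  }
  if (tally$total_emitted_keV <= 0) stop("empty tally", call. = FALSE)
  cum <- cumsum(tally$radial_keV)
  edges <- seq_along(cum) * tally$radial_bin_um
  out <- vapply(percentiles, function(p) {
    target <- p / 100 * tally$total_emitted_keV
    i <- which(cum >= target)
    if (length(i) == 0L) return(NA_real_)
    edges[i[1]]
  }, numeric(1))
  names(out) <- paste0("r", fmt_num(percentiles))
  out
}

#' Cumulative radial energy profile
#'
#' @param tally a `deposition_tally`.
#' @return data frame with `r_um` (outer shell edge) and
#'   `cumulative_fraction` of the total emitted energy deposited within r.
#' @export
radial_profile <- function(tally) {
  stopifnot(inherits(tally, "deposition_tally"))
  cum <- cumsum(tally$radial_keV)
  data.frame(r_um = seq_along(cum) * tally$radial_bin_um,
             cumulative_fraction = cum / tally$total_emitted_keV)
}

#' Export a deposition tally
#'
#' Writes the voxel grid as a flat TSV (`ix, iy, iz, energy_keV`, zero voxels
#' omitted), the radial profile, and a JSON manifest echoing the
#' configuration, totals and seed.
#'
#' @param tally a `deposition_tally`.
#' @param dir destination directory.
#' @param stem file-name stem; defaults to `<nuclide>_<voxel side>um`.
#' @return `dir`, invisibly.
#' @export
write_tally <- function(tally, dir, stem = NULL) {
  stopifnot(inherits(tally, "deposition_tally"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(stem)) {
    stem <- sprintf("%s_%sum", tally$nuclide, fmt_num(tally$voxel_side_um))
  }
  idx <- which(tally$grid > 0, arr.ind = TRUE)
  flat <- data.frame(ix = idx[, 1] - tally$half_n - 1L,
                     iy = idx[, 2] - tally$half_n - 1L,
                     iz = idx[, 3] - tally$half_n - 1L,
                     energy_keV = tally$grid[idx])
  flat <- flat[order(flat$ix, flat$iy, flat$iz), ]
  write.table(flat, file.path(dir, paste0(stem, "_tally.tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(radial_profile(tally),
              file.path(dir, paste0(stem, "_radial.tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(nuclide = tally$nuclide, source = tally$source,
                   voxel_side_um = tally$voxel_side_um,
                   n_decays = tally$n_decays,
                   total_emitted_keV = tally$total_emitted_keV,
                   total_deposited_keV = tally$total_deposited_keV,
                   seed = tally$config$seed,
                   step_fraction = tally$config$step_fraction,
                   cutoff_keV = tally$config$cutoff_keV,
                   tally_extent_um = tally$config$tally_extent_um)
  jsonlite::write_json(manifest, file.path(dir, paste0(stem, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
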