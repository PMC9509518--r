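# SAF library: skeletal sites, energy-gridded specific absorbed fraction
# tables, the assembled skeleton model, interpolation and validation.

SAF_SOURCES <- c("AM", "IM", "TBV", "TBS")

#' Construct a skeletal site record
#'
#' Masses of the three spongiosa constituents at one skeletal site plus its
#' reference marrow cellularity. AM and IM mass densities are taken equal
#' (1.03 g/cm^3), so the volume ratio defining cellularity equals the mass
#' ratio and [cellularity()] can be applied to masses directly.
#'
#' @param name site identifier (e.g. `"lumbar_vertebrae"`).
#' @param mass_AM,mass_IM,mass_TB active marrow, inactive marrow and
#'   trabecular bone mass, kg.
#' @param cellularity reference cellularity, in (0, 1].
#' @return a `skeletal_site` list.
#' @export
skeletal_site <- function(name, mass_AM, mass_IM, mass_TB, cellularity) {
  if (!is.character(name) || !nzchar(name)) {
    stop("site name must be a non-empty string", call. = FALSE)
  }
  m <- c(mass_AM, mass_IM, mass_TB)
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("site masses must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(cellularity) || cellularity <= 0 || cellularity > 1) {
    stop("reference cellularity must lie in (0, 1]", call. = FALSE)
  }
  implied <- mass_AM / (mass_AM + mass_IM)
  if (mass_AM + mass_IM > 0 && abs(implied - cellularity) > 0.02) {
    stop(sprintf(
      "site '%s': cellularity %.3f inconsistent with AM/IM masses (imply %.3f)",
      name, cellularity, implied), call. = FALSE)
  }
  structure(list(name = name, mass_AM = mass_AM, mass_IM = mass_IM,
                 mass_TB = mass_TB, cellularity = cellularity),
            class = "skeletal_site")
}

#' Construct an energy-gridded SAF table
#'
#' Specific absorbed fraction by the active marrow target at one skeletal
#' site, for one source compartment and cellularity, tabulated on a strictly
#' increasing monoenergetic electron energy grid.
#'
#' @param site skeletal site name.
#' @param source source compartment: `"AM"`, `"IM"`, `"TBV"` or `"TBS"`.
#' @param energy_keV strictly increasing grid, keV.
#' @param saf SAF values at the grid points, kg^-1.
#' @param cellularity marrow cellularity the table was computed for.
#' @param sex optional `"male"` or `"female"` tag.
#' @return a `saf_table` object.
#' @export
saf_table <- function(site, source, energy_keV, saf, cellularity,
                      sex = NA_character_) {
  source <- match.arg(source, SAF_SOURCES)
  if (length(energy_keV) < 2L || any(!is.finite(energy_keV))) {
    stop("SAF energy grid needs at least two finite points", call. = FALSE)
  }
  if (any(diff(energy_keV) <= 0)) {
    stop("SAF energy grid must be strictly increasing", call. = FALSE)
  }
  if (min(energy_keV) <= 0) stop("SAF grid energies must be > 0", call. = FALSE)
  if (length(saf) != length(energy_keV)) {
    stop("`saf` and `energy_keV` lengths differ", call. = FALSE)
  }
  if (any(!is.finite(saf)) || any(saf < 0)) {
    stop("SAF values must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(cellularity) || cellularity <= 0 || cellularity > 1) {
    stop("cellularity must lie in (0, 1]", call. = FALSE)
  }
  structure(list(site = site, source = source, target = "AM",
                 cellularity = cellularity, sex = sex,
                 energy_keV = energy_keV, saf = saf),
            class = "saf_table")
}

#' @export
print.saf_table <- function(x, ...) {
  cat(sprintf("<saf_table %s: AM <- %s, cellularity %.0f%%, %d energies %g-%g keV>\n",
              x$site, x$source, 100 * x$cellularity, length(x$energy_keV),
              min(x$energy_keV), max(x$energy_keV)))
  invisible(x)
}

#' Interpolate a SAF table at arbitrary electron energies
#'
#' Log-log linear interpolation between bracketing grid points (exact at grid
#' points and for power-law segments, positive by construction). Energies
#' below the grid minimum or above the maximum are clamped to the edge value:
#' below a 10 keV female grid minimum the electron range (< 2.5 um) is far
#' below the 50 um model resolution, so the SAF is effectively saturated, and
#' the 10^4 keV upper edge lies beyond every beta endpoint considered.
#'
#' @param table a [saf_table()].
#' @param energy_keV energies to evaluate, keV (vectorised, all > 0).
#' @return SAF values, kg^-1.
#' @export
interpolate_saf <- function(table, energy_keV) {
  stopifnot(inherits(table, "saf_table"))
  if (any(!is.finite(energy_keV)) || any(energy_keV <= 0)) {
    stop("query energies must be finite and > 0 keV", call. = FALSE)
  }
  e <- pmin(pmax(energy_keV, table$energy_keV[1]),
            table$energy_keV[length(table$energy_keV)])
  # log-log interpolation; zero SAF values handled by flooring at a tiny
  # positive value and snapping back to zero afterwards
  saf <- pmax(table$saf, 1e-300)
  y <- approx(log(table$energy_keV), log(saf), xout = log(e),
              method = "linear", ties = "ordered")$y
  out <- exp(y)
  out[out < 1e-250] <- 0
  # exact at grid points (avoid round-trip error through logs)
  idx <- match(e, table$energy_keV)
  hit <- !is.na(idx)
  out[hit] <- table$saf[idx[hit]]
  out
}

#' Assemble a skeleton model
#'
#' @param sex `"male"` or `"female"`.
#' @param sites list of [skeletal_site()] records.
#' @param tables list of [saf_table()] objects covering every (site, source)
#'   pair at the site's reference cellularity, plus any cellularity-varied
#'   AM self-irradiation tables.
#' @param n_sites expected number of sites (13 for the reference skeleton).
#' @return a `skeleton_model`.
#' @export
skeleton_model <- function(sex = c("male", "female"), sites, tables,
                           n_sites = 13L) {
  sex <- match.arg(sex)
  stopifnot(is.list(sites), is.list(tables))
  site_names <- vapply(sites, `[[`, character(1), "name")
  if (anyDuplicated(site_names)) stop("duplicate site names", call. = FALSE)
  if (length(sites) != n_sites) {
    stop(sprintf("expected %d skeletal sites, got %d", n_sites,
                 length(sites)), call. = FALSE)
  }
  names(sites) <- site_names
  keyed <- list()
  for (tb in tables) {
    stopifnot(inherits(tb, "saf_table"))
    if (!tb$site %in% site_names) {
      stop(sprintf("SAF table references unknown site '%s'", tb$site),
           call. = FALSE)
    }
    keyed[[saf_key(tb$site, tb$source, tb$cellularity)]] <- tb
  }
  model <- structure(list(sex = sex, sites = sites, tables = keyed),
                     class = "skeleton_model")
  validate_skeleton(model)
  model
}

saf_key <- function(site, source, cellularity) {
  sprintf("%s|%s|%04.0f", site, source, round(1000 * cellularity))
}

#' Retrieve one SAF table from a skeleton model
#'
#' @param model a [skeleton_model()].
#' @param site site name.
#' @param source source compartment.
#' @param cellularity cellularity of the requested table; defaults to the
#'   site's reference cellularity.
#' @return a [saf_table()].
#' @export
get_saf <- function(model, site, source, cellularity = NULL) {
  stopifnot(inherits(model, "skeleton_model"))
  if (!site %in% names(model$sites)) {
    stop(sprintf("unknown skeletal site '%s'", site), call. = FALSE)
  }
  if (is.null(cellularity)) cellularity <- model$sites[[site]]$cellularity
  key <- saf_key(site, source, cellularity)
  tb <- model$tables[[key]]
  if (is.null(tb)) {
    stop(sprintf("no SAF table for site '%s', source %s, cellularity %.0f%%",
                 site, source, 100 * cellularity), call. = FALSE)
  }
  tb
}

validate_skeleton <- function(model) {
  for (s in model$sites) {
    for (src in SAF_SOURCES) {
      key <- saf_key(s$name, src, s$cellularity)
      tb <- model$tables[[key]]
      if (is.null(tb)) {
        stop(sprintf(
          "skeleton validation: missing SAF table (site '%s', source %s, reference cellularity %.0f%%)",
          s$name, src, 100 * s$cellularity), call. = FALSE)
      }
      if (src == "AM" && s$mass_AM > 0) {
        phi <- tb$saf * s$mass_AM
        if (any(phi > 1.05)) {
          stop(sprintf(
            "skeleton validation: site '%s' self-SAF implies absorbed fraction %.3f > 1.05 at %g keV",
            s$name, max(phi), tb$energy_keV[which.max(phi)]), call. = FALSE)
        }
      }
    }
  }
  invisible(model)
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat(sprintf("<skeleton_model %s: %d sites, %d SAF tables>\n", x$sex,
              length(x$sites), length(x$tables)))
  cat(sprintf("  total AM %.4g kg, IM %.4g kg, TB %.4g kg\n",
              sum(vapply(x$sites, `[[`, numeric(1), "mass_AM")),
              sum(vapply(x$sites, `[[`, numeric(1), "mass_IM")),
              sum(vapply(x$sites, `[[`, numeric(1), "mass_TB"))))
  invisible(x)
}

tissue_mass <- function(site, tissue) {
  switch(tissue, AM = site$mass_AM, IM = site$mass_IM,
         TB = site$mass_TB, TBV = site$mass_TB, TBS = site$mass_TB,
         stop("unknown tissue '", tissue, "'", call. = FALSE))
}

#' Skeletal-site mass fractions of one tissue
#'
#' Fraction of the whole-skeleton mass of a tissue residing at each site;
#' these are the weights of the skeletal averaging formula. The trabecular
#' bone surface source shares the trabecular bone mass column (a surface has
#' no mass of its own).
#'
#' @param model a [skeleton_model()].
#' @param tissue `"AM"`, `"IM"` or `"TB"` (aliases `"TBV"`, `"TBS"`).
#' @return named numeric vector summing to 1.
#' @export
site_mass_fractions <- function(model, tissue = c("AM", "IM", "TB",
                                                  "TBV", "TBS")) {
  stopifnot(inherits(model, "skeleton_model"))
  tissue <- match.arg(tissue)
  m <- vapply(model$sites, tissue_mass, numeric(1), tissue = tissue)
  tot <- sum(m)
  if (tot <= 0) {
    stop("all-zero ", tissue, " masses: mass fractions undefined",
         call. = FALSE)
  }
  m / tot
}
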