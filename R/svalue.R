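# S-value engine: spectrum-SAF convolution, skeletal and spongiosa
# averaging, cellularity scaling and the rudimentary-model ratio.

#' S-value of one nuclide against one SAF table
#'
#' Convolves the per-decay electron emission spectrum with the SAF table:
#' \deqn{S = 10^9 \left[ \sum_i y_i E_i \Phi(E_i)
#'           + \int n(E)\, E\, \Phi(E)\, dE \right]}
#' with energies converted to joules, \eqn{\Phi} in kg^-1 interpolated at
#' each node ([interpolate_saf()]), the integral evaluated by the trapezoid
#' rule on the beta grid and the factor 10^9 converting Gy per decay to
#' mGy/MBq-s. Discrete lines enter exactly, never histogrammed.
#'
#' @param nuclide a [radionuclide()].
#' @param table a [saf_table()].
#' @param grid optional beta energy grid, keV; default 1 keV bins.
#' @return S-value in mGy/MBq-s.
#' @export
site_s_value <- function(nuclide, table, grid = NULL) {
  stopifnot(inherits(nuclide, "radionuclide"), inherits(table, "saf_table"))
  s <- 0
  d <- discrete_table(nuclide)
  if (nrow(d) > 0L) {
    s <- s + sum(d$yield * d$energy_keV * interpolate_saf(table, d$energy_keV))
  }
  if (length(nuclide$beta_branches) > 0L) {
    sp <- composite_electron_spectrum(nuclide, grid)$spectrum
    phi <- interpolate_saf(table, sp$grid)
    s <- s + trapz(sp$grid, sp$density * sp$grid * phi)
  }
  s * KEV_TO_J * MGY_PER_MBQ_S
}

#' Per-site S-values for every source compartment
#'
#' @param nuclide a [radionuclide()].
#' @param model a [skeleton_model()].
#' @param sources source compartments to evaluate.
#' @param grid optional beta energy grid.
#' @return an `svalue_set`: data frame of (site, source, s_value) plus
#'   metadata, used by the averaging functions.
#' @export
svalue_set <- function(nuclide, model, sources = SAF_SOURCES, grid = NULL) {
  stopifnot(inherits(nuclide, "radionuclide"),
            inherits(model, "skeleton_model"))
  rows <- list()
  for (site in names(model$sites)) {
    for (src in sources) {
      tb <- get_saf(model, site, src)
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, source = src,
        s_value = site_s_value(nuclide, tb, grid))
    }
  }
  entries <- do.call(rbind, rows)
  structure(list(nuclide = nuclide$name, sex = model$sex, entries = entries),
            class = "svalue_set")
}

#' @export
print.svalue_set <- function(x, ...) {
  cat(sprintf("<svalue_set %s (%s): %d entries, mGy/MBq-s>\n", x$nuclide,
              x$sex, nrow(x$entries)))
  print(head(x$entries, 8))
  if (nrow(x$entries) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.svalue_set <- function(x, ...) x$entries

lookup_s <- function(svalues, site, source) {
  e <- svalues$entries
  hit <- e$site == site & e$source == source
  if (!any(hit)) {
    stop(sprintf("svalue_set has no entry for site '%s', source %s",
                 site, source), call. = FALSE)
  }
  e$s_value[hit][1]
}

#' Skeletal-averaged S-value
#'
#' Mass-fraction average over skeletal sites,
#' \deqn{S_{avg} = \sum_x \frac{m_{target,x}}{m_{target,tot}}
#'       \frac{m_{source,x}}{m_{source,tot}} S_x,}
#' the double weighting reflecting both where the activity resides and where
#' the target marrow is. Cross-site irradiation is neglected, so the weights
#' need not sum to one. The target is always active marrow; the source mass
#' column follows the source compartment (trabecular bone mass for both the
#' TBV and TBS sources).
#'
#' @param svalues an [svalue_set()].
#' @param model the matching [skeleton_model()].
#' @param source source compartment to average.
#' @return skeletal-averaged S-value, mGy/MBq-s.
#' @export
skeletal_average <- function(svalues, model, source = SAF_SOURCES) {
  stopifnot(inherits(svalues, "svalue_set"),
            inherits(model, "skeleton_model"))
  source <- match.arg(source)
  w_target <- site_mass_fractions(model, "AM")
  w_source <- site_mass_fractions(model, source)
  total <- 0
  for (site in names(model$sites)) {
    total <- total + w_target[[site]] * w_source[[site]] *
      lookup_s(svalues, site, source)
  }
  total
}

#' Spongiosa-averaged S-value
#'
#' S-value for activity distributed homogeneously over the whole spongiosa,
#' obtained by mass-weighting the skeletal-averaged S-values of the AM, IM
#' and TBS sources:
#' \deqn{S(Sp \leftarrow Sp) = \sum_{src} \frac{m_{src}}{m_{Spongiosa}}
#'       S(AM \leftarrow src)}
#' with \eqn{m_{Spongiosa} = m_{AM} + m_{IM} + m_{TB}}. The trabecular bone
#' surface source carries the trabecular bone mass (a surface has no mass of
#' its own).
#'
#' @inheritParams skeletal_average
#' @return spongiosa S-value, mGy/MBq-s.
#' @export
spongiosa_s_value <- function(svalues, model) {
  stopifnot(inherits(svalues, "svalue_set"),
            inherits(model, "skeleton_model"))
  m_AM <- sum(vapply(model$sites, `[[`, numeric(1), "mass_AM"))
  m_IM <- sum(vapply(model$sites, `[[`, numeric(1), "mass_IM"))
  m_TB <- sum(vapply(model$sites, `[[`, numeric(1), "mass_TB"))
  m_sp <- m_AM + m_IM + m_TB
  if (m_sp <= 0) stop("zero spongiosa mass", call. = FALSE)
  term <- function(m, src) {
    if (m <= 0) return(0)  # empty compartments contribute nothing
    m * skeletal_average(svalues, model, src)
  }
  (term(m_AM, "AM") + term(m_IM, "IM") + term(m_TB, "TBS")) / m_sp
}

#' Marrow cellularity from compartment volumes
#'
#' \deqn{Cellularity = 1 - V_{IM} / (V_{AM} + V_{IM})}
#'
#' Because AM and IM mass densities are taken equal, masses may be passed in
#' place of volumes.
#'
#' @param volume_AM,volume_IM active and inactive marrow volumes (or masses),
#'   both >= 0 and not both zero.
#' @return cellularity in [0, 1].
#' @export
cellularity <- function(volume_AM, volume_IM) {
  if (!is.numeric(volume_AM) || !is.numeric(volume_IM) ||
      volume_AM < 0 || volume_IM < 0) {
    stop("volumes must be >= 0", call. = FALSE)
  }
  if (volume_AM + volume_IM == 0) {
    stop("cellularity undefined: both volumes are zero", call. = FALSE)
  }
  1 - volume_IM / (volume_AM + volume_IM)
}

#' Cellularity dependence of the self-irradiation S-value
#'
#' Relative S(AM <- AM) at one site as the marrow cellularity departs from
#' the reference value, using the cellularity-varied SAF tables of the model.
#'
#' @param nuclide a [radionuclide()].
#' @param model a [skeleton_model()] holding cellularity-varied AM tables.
#' @param site site name.
#' @param cellularities cellularity fractions to evaluate.
#' @param grid optional beta energy grid.
#' @return named numeric vector of S(cellularity) / S(reference); exactly 1
#'   at the reference cellularity.
#' @export
cellularity_curve <- function(nuclide, model, site, cellularities,
                              grid = NULL) {
  stopifnot(inherits(nuclide, "radionuclide"),
            inherits(model, "skeleton_model"))
  ref <- site_s_value(nuclide, get_saf(model, site, "AM"), grid)
  if (ref <= 0) stop("reference S-value is zero", call. = FALSE)
  ref_cell <- model$sites[[site]]$cellularity
  out <- vapply(cellularities, function(cc) {
    if (isTRUE(all.equal(cc, ref_cell))) return(1)
    site_s_value(nuclide, get_saf(model, site, "AM", cellularity = cc),
                 grid) / ref
  }, numeric(1))
  names(out) <- fmt_num(cellularities)
  out
}

#' Ratio of the rudimentary S-value to a model S-value
#'
#' The rudimentary self-irradiation S-value assumes an absorbed fraction of
#' one: total electron energy per decay divided by the target mass. Its ratio
#' to a model S-value measures how much of the emitted energy actually stays
#' in the active marrow.
#'
#' @param nuclide a [radionuclide()].
#' @param mass_AM active marrow mass, kg.
#' @param model_s_value model self-irradiation S-value, mGy/MBq-s.
#' @param grid optional beta energy grid.
#' @return dimensionless ratio.
#' @export
rudimentary_ratio <- function(nuclide, mass_AM, model_s_value, grid = NULL) {
  stopifnot(inherits(nuclide, "radionuclide"))
  if (!is.numeric(mass_AM) || mass_AM <= 0) {
    stop("mass_AM must be > 0", call. = FALSE)
  }
  if (!is.numeric(model_s_value) || model_s_value <= 0) {
    stop("model_s_value must be > 0", call. = FALSE)
  }
  delta_J <- total_electron_energy(nuclide, grid) * KEV_TO_J
  (delta_J / mass_AM * MGY_PER_MBQ_S) / model_s_value
}

#' Write per-site S-values as a tidy TSV
#'
#' One row per (nuclide, sex, site, source, cellularity, s_value).
#'
#' @param svalue_sets list of [svalue_set()] objects.
#' @param model the matching [skeleton_model()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_svalue_table <- function(svalue_sets, model, path) {
  rows <- lapply(svalue_sets, function(sv) {
    e <- sv$entries
    data.frame(nuclide = sv$nuclide, sex = sv$sex, site = e$site,
               source = e$source,
               cellularity = vapply(e$site, function(s)
                 model$sites[[s]]$cellularity, numeric(1)),
               s_value_mGy_per_MBq_s = e$s_value)
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Skeletal-averaged and spongiosa summary table
#'
#' Mirrors the layout of published skeletal-averaged S-value tables: one row
#' per nuclide with the four source-compartment averages, the spongiosa
#' S-value and its fraction of the self-irradiation average.
#'
#' @param svalue_sets list of [svalue_set()] objects.
#' @param model the matching [skeleton_model()].
#' @return data frame.
#' @export
svalue_summary <- function(svalue_sets, model) {
  rows <- lapply(svalue_sets, function(sv) {
    avg <- vapply(SAF_SOURCES, function(src)
      skeletal_average(sv, model, src), numeric(1))
    sp <- spongiosa_s_value(sv, model)
    data.frame(nuclide = sv$nuclide, sex = sv$sex,
               S_AM_AM = avg[["AM"]], S_AM_IM = avg[["IM"]],
               S_AM_TBV = avg[["TBV"]], S_AM_TBS = avg[["TBS"]],
               S_spongiosa = sp, spongiosa_fraction = sp / avg[["AM"]])
  })
  do.call(rbind, rows)
}
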