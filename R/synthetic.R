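# Synthetic-data generator: complete, self-consistent skeleton mass tables,
# SAF libraries (all sources, cellularity-varied self-irradiation) and decay
# fixtures, so the whole pipeline is testable with no external downloads.
#
# The generator emulates the *structure* of published skeletal SAF
# supplements: a 13-site skeleton, four source compartments, energy grids
# spanning 1 (male) or 10 (female) keV to 10^4 keV, self-SAFs saturating at
# 1/mass at low energy and rolling off at high energy, cross-compartment
# SAFs rising from ~0 to a peak and falling again, and self-SAFs growing as
# cellularity drops. It does not attempt to match the magnitudes of any real
# phantom.

SYNTH_SITES <- c("cranium", "mandible", "scapulae", "clavicles", "sternum",
                 "ribs", "cervical_vertebrae", "thoracic_vertebrae",
                 "lumbar_vertebrae", "sacrum", "os_coxae", "femora_proximal",
                 "humeri_proximal")

# Baseline active-marrow distribution (fractions of whole-body AM) and
# reference cellularities, following the adult reference distribution used
# by voxel skeletal models.
SYNTH_AM_FRACTION <- c(0.076, 0.008, 0.028, 0.008, 0.031, 0.161, 0.039,
                       0.161, 0.123, 0.099, 0.175, 0.067, 0.024)
SYNTH_CELLULARITY <- c(0.38, 0.38, 0.48, 0.33, 0.70, 0.70, 0.70, 0.70,
                       0.70, 0.70, 0.48, 0.25, 0.25)

#' Configuration for the synthetic skeleton generator
#'
#' @param seed integer seed; a fixed seed gives byte-identical output trees.
#' @param n_sites number of skeletal sites (13 reproduces the reference
#'   skeleton; smaller values take the first `n_sites` sites).
#' @param total_AM_kg,total_TB_kg whole-skeleton active marrow and trabecular
#'   bone masses to distribute.
#' @param mass_jitter multiplicative log-normal jitter applied to site
#'   masses.
#' @param leak_range low-energy self-absorption leak: self-SAF times AM mass
#'   at the grid minimum equals 1 minus a draw from this range.
#' @param rolloff_range_keV range of the self-SAF roll-off energy scale.
#' @param rolloff_power_range range of the roll-off exponent.
#' @param cross_amplitude peak cross-SAF relative to the self-SAF, named for
#'   the TBS, IM and TBV sources (descending order preserves the physical
#'   source ordering for any emission spectrum).
#' @param cross_rise_keV rise energy scales for TBS, IM, TBV.
#' @param cellularities cellularity set for the varied self-SAF tables.
#' @param cell_w_max,cell_w_scale_keV parameters of the cellularity scaling
#'   weight (see [generate_skeleton()]).
#' @param grid_min_keV SAF grid minimum (1 male, 10 female).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_sites = 13L,
                             total_AM_kg = 1.17, total_TB_kg = 1.0,
                             mass_jitter = 0.10,
                             leak_range = c(0.02, 0.08),
                             rolloff_range_keV = c(300, 500),
                             rolloff_power_range = c(1.1, 1.4),
                             cross_amplitude = c(TBS = 0.65, IM = 0.45,
                                                 TBV = 0.30),
                             cross_rise_keV = c(TBS = 40, IM = 80,
                                                TBV = 150),
                             cellularities = seq(0.1, 1, by = 0.1),
                             cell_w_max = 0.85, cell_w_scale_keV = 60,
                             grid_min_keV = 1) {
  stopifnot(n_sites >= 1, n_sites <= length(SYNTH_SITES),
            total_AM_kg > 0, total_TB_kg > 0,
            all(leak_range > 0), all(rolloff_range_keV > 0),
            all(cross_amplitude > 0), all(cross_rise_keV > 0),
            all(cellularities > 0 & cellularities <= 1),
            cell_w_max >= 0, cell_w_max < 1, cell_w_scale_keV > 0,
            grid_min_keV > 0)
  if (is.unsorted(rev(cross_amplitude)) || is.unsorted(cross_rise_keV)) {
    stop("cross_amplitude must descend and cross_rise_keV ascend over ",
         "TBS, IM, TBV to preserve the source ordering", call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_config")
}

synth_energy_grid <- function(grid_min_keV) {
  g <- c(1, 2, 5, 10, 15, 20, 30, 50, 70, 100, 150, 200, 300, 500, 700,
         1000, 1500, 2000, 3000, 5000, 7000, 10000)
  g[g >= grid_min_keV]
}

#' Generate a synthetic skeleton model
#'
#' Draws site masses around the reference active-marrow distribution,
#' constructs self-irradiation SAFs as a low-energy plateau at
#' `(1 - leak) / mass_AM` times a smooth high-energy roll-off, cross-
#' compartment SAFs as the self shape damped by a rise factor
#' `1 - exp(-E / E_rise)` (zero at low energy, peak, then fall), and
#' cellularity-varied self tables scaled by
#' `w(E) + (1 - w(E)) * c_ref / c` with `w(E) = w_max * E / (E + E_w)`, so
#' low cellularity amplifies low energies most. Everything is validated
#' through the SAF library on assembly.
#'
#' @param config a [synthetic_config()].
#' @param dir optional directory; when given the model is also written via
#'   [write_skeleton()].
#' @param sex `"male"` (1 keV grid minimum) or `"female"` (10 keV).
#' @return a [skeleton_model()].
#' @export
generate_skeleton <- function(config = synthetic_config(), dir = NULL,
                              sex = c("male", "female")) {
  stopifnot(inherits(config, "synthetic_config"))
  sex <- match.arg(sex)
  grid_min <- if (sex == "female") max(config$grid_min_keV, 10) else
    config$grid_min_keV
  egrid <- synth_energy_grid(grid_min)
  set.seed(config$seed + if (sex == "female") 1L else 0L)
  ns <- config$n_sites
  am_frac <- SYNTH_AM_FRACTION[seq_len(ns)]
  am_frac <- am_frac / sum(am_frac)
  jit <- exp(rnorm(ns, 0, config$mass_jitter))
  m_AM <- signif(config$total_AM_kg * am_frac * jit / sum(am_frac * jit), 8)
  cell <- SYNTH_CELLULARITY[seq_len(ns)]
  m_IM <- signif(m_AM * (1 - cell) / cell, 8)
  tb_jit <- exp(rnorm(ns, 0, config$mass_jitter))
  m_TB <- signif(config$total_TB_kg * am_frac * tb_jit /
                   sum(am_frac * tb_jit), 8)
  sites <- lapply(seq_len(ns), function(i) {
    skeletal_site(SYNTH_SITES[i], m_AM[i], m_IM[i], m_TB[i], cell[i])
  })

  tables <- list()
  for (i in seq_len(ns)) {
    leak <- runif(1, config$leak_range[1], config$leak_range[2])
    e0 <- runif(1, config$rolloff_range_keV[1], config$rolloff_range_keV[2])
    pw <- runif(1, config$rolloff_power_range[1],
                config$rolloff_power_range[2])
    phi_self <- (1 - leak) / m_AM[i] / (1 + (egrid / e0)^pw)
    tables[[length(tables) + 1L]] <-
      saf_table(SYNTH_SITES[i], "AM", egrid, signif(phi_self, 8), cell[i],
                sex)
    for (src in c("TBS", "IM", "TBV")) {
      rise <- 1 - exp(-egrid / config$cross_rise_keV[[src]])
      phi <- config$cross_amplitude[[src]] * phi_self * rise
      tables[[length(tables) + 1L]] <-
        saf_table(SYNTH_SITES[i], src, egrid, signif(phi, 8), cell[i], sex)
    }
    w <- config$cell_w_max * egrid / (egrid + config$cell_w_scale_keV)
    for (cc in config$cellularities) {
      if (isTRUE(all.equal(cc, cell[i]))) next
      scale <- w + (1 - w) * cell[i] / cc
      tables[[length(tables) + 1L]] <-
        saf_table(SYNTH_SITES[i], "AM", egrid,
                  signif(phi_self * scale, 8), cc, sex)
    }
  }
  model <- skeleton_model(sex, sites, tables, n_sites = ns)
  if (!is.null(dir)) write_skeleton(model, dir)
  model
}

#' Generate a decay fixture
#'
#' Randomised but structurally faithful nuclide fixtures for testing:
#' `"tb161_like"` keeps a large low-energy conversion/Auger component
#' (more than 10 discrete electrons below 50 keV per decay, at least 20% of
#' the total electron energy in discrete lines), `"y90_like"` a high-energy
#' unique first-forbidden beta with negligible discrete yield, `"lu177_like"`
#' an intermediate beta emitter with a modest line component.
#'
#' @param kind fixture family.
#' @param seed integer seed.
#' @param path optional file path; when given the fixture is written in the
#'   decay dialect.
#' @return a [radionuclide()].
#' @export
generate_decay_fixture <- function(kind = c("beta_only", "discrete_only",
                                            "tb161_like", "lu177_like",
                                            "y90_like"),
                                   seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  jit <- function(x, rel = 0.1) signif(x * runif(length(x), 1 - rel, 1 + rel), 8)
  nuc <- switch(kind,
    beta_only = {
      n <- sample(1:3, 1)
      eps <- sort(signif(runif(n, 200, 2000), 8), decreasing = TRUE)
      fr <- signif(as.vector(prop.table(runif(n, 0.2, 1))), 8)
      z <- sample(30:80, 1)
      radionuclide(sprintf("beta_only_%d", seed), signif(runif(1, 0.5, 10), 8),
                   lapply(seq_len(n), function(i)
                     beta_branch(eps[i], fr[i], z)))
    },
    discrete_only = {
      n <- sample(2:5, 1)
      e <- signif(sort(runif(n, 5, 300)), 8)
      y <- signif(runif(n, 0.05, 2), 8)
      radionuclide(sprintf("discrete_only_%d", seed),
                   signif(runif(1, 0.5, 10), 8), list(),
                   lapply(seq_len(n), function(i)
                     discrete_emission(e[i], y[i],
                                       if (e[i] < 10) "auger" else "conversion")))
    },
    tb161_like = {
      base <- bundled_nuclide("tb161")
      fr <- vapply(base$beta_branches, `[[`, numeric(1), "fraction")
      fr <- signif(fr * runif(length(fr), 0.95, 1.05), 8)
      fr <- signif(fr / sum(fr), 8)
      betas <- lapply(seq_along(base$beta_branches), function(i) {
        b <- base$beta_branches[[i]]
        beta_branch(b$endpoint_keV, fr[i], b$daughter_Z, b$kind)
      })
      discs <- lapply(base$discrete, function(d)
        discrete_emission(d$energy_keV, jit(d$yield), d$kind))
      radionuclide(sprintf("tb161_like_%d", seed), base$half_life_days,
                   betas, discs)
    },
    lu177_like = {
      base <- bundled_nuclide("lu177")
      fr <- vapply(base$beta_branches, `[[`, numeric(1), "fraction")
      fr <- signif(fr * runif(length(fr), 0.95, 1.05), 8)
      fr <- signif(fr / sum(fr), 8)
      betas <- lapply(seq_along(base$beta_branches), function(i) {
        b <- base$beta_branches[[i]]
        beta_branch(b$endpoint_keV, fr[i], b$daughter_Z, b$kind)
      })
      discs <- lapply(base$discrete, function(d)
        discrete_emission(d$energy_keV, jit(d$yield), d$kind))
      radionuclide(sprintf("lu177_like_%d", seed), base$half_life_days,
                   betas, discs)
    },
    y90_like = {
      ep <- signif(runif(1, 2000, 2500), 8)
      discs <- list(
        discrete_emission(signif(runif(1, 1, 3), 8),
                          signif(runif(1, 5e-4, 2e-3), 8), "auger"),
        discrete_emission(signif(runif(1, 1500, 1900), 8),
                          signif(runif(1, 5e-5, 2e-4), 8), "conversion"))
      radionuclide(sprintf("y90_like_%d", seed), signif(runif(1, 1, 5), 8),
                   list(beta_branch(ep, 1, 40, "first_forbidden_unique")),
                   discs)
    })
  if (!is.null(path)) write_decay_table(nuc, path)
  nuc
}

#' Materialise the default synthetic test corpus
#'
#' Writes a male and a female synthetic skeleton plus one decay fixture per
#' family under `dir`. This is the `make-fixtures` entry point of the
#' command-line interface.
#'
#' @param dir destination directory.
#' @param seed integer seed.
#' @return `dir`, invisibly.
#' @export
make_fixture_corpus <- function(dir, seed = 1L) {
  cfg <- synthetic_config(seed = seed)
  generate_skeleton(cfg, dir = file.path(dir, "skeleton_male"), sex = "male")
  generate_skeleton(cfg, dir = file.path(dir, "skeleton_female"),
                    sex = "female")
  dir.create(file.path(dir, "decay"), recursive = TRUE, showWarnings = FALSE)
  for (kind in c("beta_only", "discrete_only", "tb161_like", "lu177_like",
                 "y90_like")) {
    generate_decay_fixture(kind, seed = seed,
                           path = file.path(dir, "decay",
                                            paste0(kind, ".tsv")))
  }
  invisible(dir)
}
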