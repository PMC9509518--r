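# Reporting front end: validated run configuration, the two pipeline
# commands (S-value tables and the voxel deposition study) and their run
# manifests. The command-line wrapper in inst/cli/marrowdose-cli.R is a thin
# shell over these functions.

#' Validated pipeline run configuration
#'
#' @param decay_files paths to decay tables (dialect of
#'   [read_decay_table()]); defaults to the three bundled nuclides.
#' @param skeleton_dir directory holding a skeleton model
#'   ([read_skeleton()] layout); `NULL` lets commands that need one fail
#'   early.
#' @param sources source compartments to evaluate.
#' @param cellularities cellularity fractions for cellularity curves.
#' @param voxel_sides_um voxel sides for the deposition study.
#' @param n_decays decays per simulated nuclide and voxel size.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest and applied to every
#'   stochastic stage.
#' @param n_sites expected number of skeletal sites.
#' @return a `run_config` list, echoed verbatim into run manifests.
#' @export
run_config <- function(decay_files = NULL, skeleton_dir = NULL,
                       sources = SAF_SOURCES, cellularities = NULL,
                       voxel_sides_um = c(50, 8.2), n_decays = 1e5,
                       out_dir = "marrowdose-out", seed = 1L,
                       n_sites = 13L) {
  if (is.null(decay_files)) {
    decay_files <- vapply(c("lu177", "tb161", "y90"), function(n)
      system.file("extdata", "decay", paste0(n, ".tsv"),
                  package = "marrowdose", mustWork = TRUE), character(1))
  }
  missing <- decay_files[!file.exists(decay_files)]
  if (length(missing) > 0L) {
    stop("decay file not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(skeleton_dir) && !dir.exists(skeleton_dir)) {
    stop("skeleton directory not found: ", skeleton_dir, call. = FALSE)
  }
  structure(list(decay_files = decay_files, skeleton_dir = skeleton_dir,
                 sources = sources, cellularities = cellularities,
                 voxel_sides_um = voxel_sides_um,
                 n_decays = as.integer(n_decays), out_dir = out_dir,
                 seed = as.integer(seed), n_sites = as.integer(n_sites)),
            class = "run_config")
}

write_manifest <- function(config, path, extra = list()) {
  manifest <- c(unclass(config), extra,
                list(package_version =
                       as.character(utils::packageVersion("marrowdose"))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Compute and write the S-value tables
#'
#' For every nuclide in the configuration: per-site S-values for all
#' configured sources, the skeletal-averaged values, the spongiosa value and
#' (when cellularities are configured) the cellularity curve for each site.
#' Outputs: `svalues_per_site.tsv` (tidy), `svalues_summary.tsv` (one row
#' per nuclide) and `manifest.json`. Deterministic: identical inputs give
#' byte-identical outputs.
#'
#' @param config a [run_config()] with `skeleton_dir` set.
#' @return list with the per-site sets and the summary data frame,
#'   invisibly.
#' @export
run_svalues <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$skeleton_dir)) {
    stop("run_svalues needs `skeleton_dir`", call. = FALSE)
  }
  model <- read_skeleton(config$skeleton_dir, n_sites = config$n_sites)
  nuclides <- lapply(config$decay_files, read_decay_table)
  sets <- lapply(nuclides, svalue_set, model = model,
                 sources = config$sources)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_svalue_table(sets, model,
                     file.path(config$out_dir, "svalues_per_site.tsv"))
  summary_df <- svalue_summary(sets, model)
  write.table(summary_df, file.path(config$out_dir, "svalues_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  curves <- NULL
  if (!is.null(config$cellularities)) {
    rows <- list()
    for (i in seq_along(nuclides)) {
      for (site in names(model$sites)) {
        cv <- cellularity_curve(nuclides[[i]], model, site,
                                config$cellularities)
        rows[[length(rows) + 1L]] <- data.frame(
          nuclide = nuclides[[i]]$name, site = site,
          cellularity = config$cellularities, relative_s = unname(cv))
      }
    }
    curves <- do.call(rbind, rows)
    write.table(curves, file.path(config$out_dir, "cellularity_curves.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(config, file.path(config$out_dir, "manifest.json"),
                 list(command = "svalues", sex = model$sex))
  invisible(list(sets = sets, summary = summary_df, curves = curves,
                 model = model))
}

#' Run the voxel-resolution deposition study
#'
#' For every nuclide and configured voxel size: a uniform-activity
#' single-voxel simulation (self-absorbed fraction with standard error) and a
#' point-source tally with its radial profile and 30/50/90% energy radii.
#' Writes `voxel_fractions.tsv`, per-run radial profiles/tallies and
#' `manifest.json` (recording the seed; rerunning with the same
#' configuration is bit-identical).
#'
#' @param config a [run_config()].
#' @return data frame of voxel fractions and percentile radii, invisibly.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  nuclides <- lapply(config$decay_files, read_decay_table)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (nuc in nuclides) {
    for (side in config$voxel_sides_um) {
      tc <- transport_config(n_decays = config$n_decays,
                             voxel_side_um = side,
                             tally_extent_um = max(200, 4 * side),
                             seed = config$seed)
      cv <- central_voxel_fraction(nuc, voxel_side_um = side, config = tc)
      pt <- simulate_point_source(nuc, tc)
      radii <- energy_percentile_radii(pt)
      write_tally(pt, config$out_dir)
      rows[[length(rows) + 1L]] <- data.frame(
        nuclide = nuc$name, voxel_side_um = side,
        central_fraction = cv$fraction, central_fraction_se = cv$se,
        r30_um = radii[["r30"]], r50_um = radii[["r50"]],
        r90_um = radii[["r90"]], n_decays = config$n_decays)
    }
  }
  out <- do.call(rbind, rows)
  write.table(out, file.path(config$out_dir, "voxel_fractions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, file.path(config$out_dir, "manifest.json"),
                 list(command = "simulate"))
  invisible(out)
}
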