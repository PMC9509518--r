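# On-disk layout of a skeleton model:
#   <dir>/masses.tsv                site, mass_AM_kg, mass_IM_kg, mass_TB_kg,
#                                   cellularity (tab-separated, one header row)
#   <dir>/saf/<site>_<source>_c<cell>.tsv
#                                   '# site=', '# source=', '# cellularity=',
#                                   '# sex=' header lines, then rows
#                                   energy_keV<TAB>saf_per_kg

#' Write a skeleton model to a directory
#'
#' @param model a [skeleton_model()].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_skeleton <- function(model, dir) {
  stopifnot(inherits(model, "skeleton_model"))
  dir.create(file.path(dir, "saf"), recursive = TRUE, showWarnings = FALSE)
  rows <- vapply(model$sites, function(s) {
    paste(s$name, fmt_num(s$mass_AM), fmt_num(s$mass_IM), fmt_num(s$mass_TB),
          fmt_num(s$cellularity), sep = "\t")
  }, character(1))
  writeLines(c(paste0("# sex=", model$sex),
               "site\tmass_AM_kg\tmass_IM_kg\tmass_TB_kg\tcellularity",
               rows),
             file.path(dir, "masses.tsv"))
  for (tb in model$tables) {
    fn <- sprintf("%s_%s_c%03.0f.tsv", tb$site, tb$source,
                  round(100 * tb$cellularity))
    writeLines(c(paste0("# site=", tb$site),
                 paste0("# source=", tb$source),
                 paste0("# cellularity=", fmt_num(tb$cellularity)),
                 paste0("# sex=", model$sex),
                 paste(fmt_num(tb$energy_keV), fmt_num(tb$saf), sep = "\t")),
               file.path(dir, "saf", fn))
  }
  invisible(dir)
}

read_saf_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(field) {
    m <- sub(paste0("^#\\s*", field, "="), "", grep(paste0("^#\\s*", field, "="),
                                                    hdr, value = TRUE))
    if (length(m) != 1L) {
      stop(path, ": missing or repeated '# ", field, "=' header", call. = FALSE)
    }
    trimws(m)
  }
  site <- meta("site"); source <- meta("source")
  cellularity <- as.numeric(meta("cellularity"))
  sex <- tryCatch(meta("sex"), error = function(e) NA_character_)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop(path, ": SAF table body too short", call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("%s: row %d does not have two tab-separated fields",
                 path, bad[1]), call. = FALSE)
  }
  e <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  v <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (any(is.na(e)) || any(is.na(v))) {
    stop(path, ": non-numeric SAF rows", call. = FALSE)
  }
  if (any(diff(e) <= 0)) {
    stop(path, ": energy grid not strictly increasing", call. = FALSE)
  }
  if (any(v < 0)) stop(path, ": negative SAF value", call. = FALSE)
  saf_table(site, source, e, v, cellularity, sex)
}

#' Read a skeleton model from a directory
#'
#' Reads the mass table and every SAF file under `<dir>/saf/`, then validates
#' the assembled model: all sites present, every (site, source) pair covered
#' at reference cellularity, monotone grids, non-negative SAFs, and
#' self-irradiation absorbed fractions not exceeding 1 + 5%.
#'
#' @param dir directory written by [write_skeleton()] (or assembled by hand
#'   in the same layout).
#' @param n_sites expected number of sites.
#' @return a [skeleton_model()].
#' @export
read_skeleton <- function(dir, n_sites = 13L) {
  mass_path <- file.path(dir, "masses.tsv")
  if (!file.exists(mass_path)) {
    stop("no mass table at ", mass_path, call. = FALSE)
  }
  lines <- readLines(mass_path, warn = FALSE)
  sex_line <- grep("^#\\s*sex=", lines, value = TRUE)
  sex <- if (length(sex_line) == 1L) sub("^#\\s*sex=", "", sex_line) else "male"
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  body <- body[-1L]  # column header
  sites <- lapply(body, function(row) {
    f <- strsplit(row, "\t", fixed = TRUE)[[1]]
    if (length(f) != 5L) {
      stop(mass_path, ": mass rows need 5 fields, got '", row, "'",
           call. = FALSE)
    }
    skeletal_site(f[1], as.numeric(f[2]), as.numeric(f[3]), as.numeric(f[4]),
                  as.numeric(f[5]))
  })
  saf_files <- list.files(file.path(dir, "saf"), pattern = "\\.tsv$",
                          full.names = TRUE)
  tables <- lapply(saf_files, read_saf_file)
  skeleton_model(sex, sites, tables, n_sites = n_sites)
}

#' Convert a published SAF supplement worksheet into the package dialect
#'
#' The SAF supplements published with voxel-based skeletal dosimetry models
#' ship as spreadsheets with one row per electron energy and one column per
#' skeletal site (or per cellularity). This converter takes such a worksheet
#' already loaded as a data frame and a user-supplied column mapping, and
#' returns validated [saf_table()] objects. The mapping itself depends on the
#' exact worksheet edition and is deliberately left to the user.
#'
#' @param df data frame with an energy column and one or more SAF columns.
#' @param energy_col name of the energy column. If the worksheet tabulates
#'   energy in MeV set `energy_unit = "MeV"`.
#' @param columns named list mapping each SAF column name to a
#'   `list(site =, source =, cellularity =)` descriptor.
#' @param sex `"male"` or `"female"` tag stored on the tables.
#' @param energy_unit `"keV"` or `"MeV"`.
#' @return list of [saf_table()] objects, one per mapped column.
#' @export
ingest_saf_worksheet <- function(df, energy_col, columns, sex = "male",
                                 energy_unit = c("keV", "MeV")) {
  energy_unit <- match.arg(energy_unit)
  stopifnot(is.data.frame(df), energy_col %in% names(df))
  e <- as.numeric(df[[energy_col]])
  if (energy_unit == "MeV") e <- e * 1000
  lapply(names(columns), function(col) {
    if (!col %in% names(df)) {
      stop("worksheet has no column '", col, "'", call. = FALSE)
    }
    m <- columns[[col]]
    saf_table(m$site, m$source, e, as.numeric(df[[col]]), m$cellularity, sex)
  })
}
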