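# Reader/writer for the decay-table dialect and access to the bundled
# decay-scheme constants.
#
# Dialect (tab-separated, '#' starts a comment line):
#   name<TAB><identifier>
#   half_life_d<TAB><days>
#   [beta]
#   <endpoint_keV><TAB><fraction><TAB><daughter_Z><TAB><kind>
#   [discrete]
#   <energy_keV><TAB><yield><TAB><kind>

#' Read a radionuclide decay table
#'
#' Parses the package's decay-table dialect (see Details) into a
#' [radionuclide()]. Malformed rows raise an error naming the line number.
#'
#' @details The file holds a header block (`name`, `half_life_d`), a `[beta]`
#' section with rows `endpoint_keV  fraction  daughter_Z  kind` and a
#' `[discrete]` section with rows `energy_keV  yield  kind`. Fields are
#' tab-separated; lines beginning with `#` are ignored. An import path for
#' users holding the licensed ICRP-107 electronic dataset is to export its
#' beta branch and electron emission records into this layout.
#'
#' @param path file to read.
#' @return a [radionuclide()].
#' @export
read_decay_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  perr <- function(i, msg) {
    stop(sprintf("%s:%d: %s", path, i, msg), call. = FALSE)
  }
  name <- NULL; half_life <- NULL
  betas <- list(); discs <- list()
  section <- "header"
  saw_any <- FALSE
  num <- function(x, i, what) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) perr(i, sprintf("cannot parse %s: '%s'", what, x))
    v
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    saw_any <- TRUE
    if (trimws(line) == "[beta]") { section <- "beta"; next }
    if (trimws(line) == "[discrete]") { section <- "discrete"; next }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (section == "header") {
      if (length(f) != 2L) perr(i, "header rows need exactly two fields")
      if (f[1] == "name") name <- f[2]
      else if (f[1] == "half_life_d") half_life <- num(f[2], i, "half-life")
      else perr(i, sprintf("unknown header field '%s'", f[1]))
    } else if (section == "beta") {
      if (length(f) != 4L) perr(i, "[beta] rows need 4 fields")
      kind <- f[4]
      if (!kind %in% c("allowed", "first_forbidden_unique")) {
        perr(i, sprintf("unknown transition kind '%s'", kind))
      }
      ep <- num(f[1], i, "endpoint"); fr <- num(f[2], i, "fraction")
      z <- num(f[3], i, "daughter_Z")
      if (ep <= 0) perr(i, "endpoint must be > 0")
      if (fr < 0 || fr > 1) perr(i, "fraction must lie in [0, 1]")
      betas[[length(betas) + 1L]] <- beta_branch(ep, fr, z, kind)
    } else {
      if (length(f) != 3L) perr(i, "[discrete] rows need 3 fields")
      kind <- f[3]
      if (!kind %in% c("conversion", "auger")) {
        perr(i, sprintf("unknown emission kind '%s'", kind))
      }
      e <- num(f[1], i, "energy"); y <- num(f[2], i, "yield")
      if (e <= 0) perr(i, "energy must be > 0")
      if (y < 0) perr(i, "yield must be >= 0")
      discs[[length(discs) + 1L]] <- discrete_emission(e, y, kind)
    }
  }
  if (!saw_any) stop(path, ": empty decay table", call. = FALSE)
  if (is.null(name) || is.null(half_life)) {
    stop(path, ": missing 'name' or 'half_life_d' header row", call. = FALSE)
  }
  radionuclide(name, half_life, betas, discs)
}

#' Write a radionuclide decay table
#'
#' Canonical writer for the decay dialect; `write_decay_table(read_decay_table(f), f)`
#' reproduces `f` byte for byte for files in canonical form (such as the
#' bundled constants and all generator output).
#'
#' @param nuclide a [radionuclide()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_decay_table <- function(nuclide, path) {
  stopifnot(inherits(nuclide, "radionuclide"))
  out <- c(
    paste0("name\t", nuclide$name),
    paste0("half_life_d\t", fmt_num(nuclide$half_life_days)),
    "[beta]",
    vapply(nuclide$beta_branches, function(b) {
      paste(fmt_num(b$endpoint_keV), fmt_num(b$fraction),
            fmt_num(b$daughter_Z), b$kind, sep = "\t")
    }, character(1)),
    "[discrete]",
    vapply(nuclide$discrete, function(d) {
      paste(fmt_num(d$energy_keV), fmt_num(d$yield), d$kind, sep = "\t")
    }, character(1))
  )
  writeLines(out, path)
  invisible(path)
}

#' Load one of the bundled radionuclides
#'
#' Decay-scheme constants for terbium-161, lutetium-177 and yttrium-90
#' (endpoints, branching fractions, principal conversion/Auger electron
#' lines, half-lives) shipped with the package and treated as physical
#' constants. Line yields are calibrated so that the per-decay electron
#' summaries (mean beta energy, conversion/Auger energy and counts below
#' 50 keV) match the ICRP-107 reference values for these nuclides.
#'
#' @param name one of `"lu177"`, `"tb161"`, `"y90"`.
#' @return a [radionuclide()].
#' @export
bundled_nuclide <- function(name = c("lu177", "tb161", "y90")) {
  name <- match.arg(name)
  path <- system.file("extdata", "decay", paste0(name, ".tsv"),
                      package = "marrowdose", mustWork = TRUE)
  read_decay_table(path)
}
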