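# Table schemas: required columns, their types, enum domains and unique keys.
# Optional columns are read when present and otherwise filled with NA.
hemp_schemas <- function() {
  list(
    samples = list(
      cols = c(sample_id = "character", accession = "character",
               tissue = "enum", replicate = "integer", batch = "character",
               air_mass_mg = "numeric", hydrolysate_volume_ml = "numeric",
               dm_fraction = "numeric"),
      optional = "batch",
      enums = list(tissue = HEMP_TISSUES),
      key = "sample_id",
      checks = function(df) {
        bad <- which(df$air_mass_mg <= 0)
        if (length(bad)) return(sprintf("air_mass_mg must be > 0 (row %d)", bad[1]))
        bad <- which(df$hydrolysate_volume_ml <= 0)
        if (length(bad)) return(sprintf("hydrolysate_volume_ml must be > 0 (row %d)", bad[1]))
        bad <- which(df$dm_fraction <= 0 | df$dm_fraction > 1)
        if (length(bad)) return(sprintf("dm_fraction must lie in (0, 1] (row %d)", bad[1]))
        NULL
      }
    ),
    quant = list(
      cols = c(sample_id = "character", analyte = "enum",
               concentration = "numeric", dilution_factor = "numeric"),
      enums = list(analyte = HEMP_ANALYTES),
      key = c("sample_id", "analyte", "dilution_factor"),
      checks = function(df) {
        bad <- which(df$concentration < 0)
        if (length(bad)) return(sprintf("concentration must be >= 0 (row %d)", bad[1]))
        bad <- which(df$dilution_factor < 1)
        if (length(bad)) return(sprintf("dilution_factor must be >= 1 (row %d)", bad[1]))
        NULL
      }
    ),
    srs = list(
      cols = c(analyte = "enum", replicate = "integer", batch = "character",
               control_conc = "numeric", hydrolyzed_conc = "numeric"),
      optional = "batch",
      enums = list(analyte = HEMP_ANALYTES),
      key = c("analyte", "replicate", "batch"),
      checks = function(df) {
        bad <- which(df$control_conc <= 0)
        if (length(bad)) return(sprintf("control_conc must be > 0 (row %d)", bad[1]))
        bad <- which(df$hydrolyzed_conc < 0)
        if (length(bad)) return(sprintf("hydrolyzed_conc must be >= 0 (row %d)", bad[1]))
        NULL
      }
    ),
    residues = list(
      cols = c(sample_id = "character", residue_role = "enum",
               tare_mg = "numeric", gross_mg = "numeric",
               initial_biomass_mg = "numeric"),
      optional = "initial_biomass_mg",
      enums = list(residue_role = c("klason", "air_residue")),
      key = c("sample_id", "residue_role"),
      checks = function(df) {
        bad <- which(df$tare_mg < 0 | df$gross_mg < 0)
        if (length(bad)) return(sprintf("masses must be >= 0 (row %d)", bad[1]))
        bad <- which(df$gross_mg < df$tare_mg)
        if (length(bad)) return(sprintf("gross_mg below tare_mg (row %d): filter lost mass", bad[1]))
        NULL
      }
    ),
    hydrolysis = list(
      cols = c(sample_id = "character", analyte = "enum",
               tfa_pct = "numeric", h2so4_pct = "numeric"),
      enums = list(analyte = HEMP_ANALYTES),
      key = c("sample_id", "analyte"),
      checks = function(df) {
        bad <- which(df$tfa_pct < 0 | df$h2so4_pct < 0)
        if (length(bad)) return(sprintf("hydrolysis fractions must be >= 0 (row %d)", bad[1]))
        NULL
      }
    ),
    radii = list(
      cols = c(accession = "character", cross_section = "integer",
               replicate = "integer", structure = "enum",
               radius_um = "numeric"),
      enums = list(structure = HEMP_STRUCTURES),
      key = c("accession", "cross_section", "replicate", "structure"),
      checks = function(df) {
        bad <- which(df$radius_um < 0)
        if (length(bad)) return(sprintf("radius_um must be >= 0 (row %d)", bad[1]))
        NULL
      }
    ),
    diameters = list(
      cols = c(accession = "character", diameter_cm = "numeric"),
      enums = list(),
      key = "accession",
      checks = function(df) {
        bad <- which(df$diameter_cm <= 0)
        if (length(bad)) return(sprintf("diameter_cm must be > 0 (row %d)", bad[1]))
        NULL
      }
    ),
    traits = list(
      cols = c(accession = "character", tissue = "character",
               replicate = "integer", trait_name = "character",
               value = "numeric"),
      enums = list(),
      key = c("accession", "tissue", "replicate", "trait_name"),
      checks = function(df) {
        bad <- which(!is.finite(df$value) & !is.na(df$value))
        if (length(bad)) return(sprintf("trait values must be finite (row %d)", bad[1]))
        NULL
      }
    )
  )
}

#' Read and validate a delimited phenotyping table
#'
#' Reads a UTF-8 delimited text file with one header row and validates it
#' against one of the pipeline schemas. Validation reports the offending
#' column, row (1-based, excluding the header) and value, so a transcription
#' error in a 216-row radius table can be located directly.
#'
#' @param path Path to the file.
#' @param schema One of `"samples"`, `"quant"`, `"srs"`, `"residues"`,
#'   `"hydrolysis"`, `"radii"`, `"diameters"`, `"traits"`.
#' @param delim Field delimiter (default comma).
#' @return A validated tibble with typed columns, carrying the schema name
#'   in attribute `"hemp_schema"`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' readr::write_csv(hemp_fixture()$diameters, tf)
#' read_table(tf, "diameters")
read_table <- function(path, schema, delim = ",") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  validate_table(raw, schema, source = path)
}

#' Validate an in-memory table against a pipeline schema
#'
#' @param df A data frame (columns may still be character, as read from text).
#' @param schema Schema name as in [read_table()].
#' @param source Label used in error messages.
#' @return A validated, typed tibble.
#' @export
validate_table <- function(df, schema, source = "table") {
  schemas <- hemp_schemas()
  if (!schema %in% names(schemas)) {
    abort(paste0("Unknown schema '", schema, "'. Known: ",
                 paste(names(schemas), collapse = ", ")))
  }
  sc <- schemas[[schema]]
  required <- setdiff(names(sc$cols), sc$optional %||% character())
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0(source, ": missing required column(s) for schema '", schema,
                 "': ", paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(df)[, intersect(names(sc$cols), names(df)), drop = FALSE]
  for (opt in setdiff(sc$optional %||% character(), names(out))) {
    out[[opt]] <- if (sc$cols[[opt]] == "numeric") NA_real_ else NA_character_
  }
  for (col in names(sc$cols)) {
    type <- sc$cols[[col]]
    v <- out[[col]]
    if (type %in% c("numeric", "integer")) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & trimws(as.character(v)) != "")
      if (length(bad)) {
        abort(sprintf("%s: column '%s' row %d: cannot parse '%s' as a number",
                      source, col, bad[1], v[bad[1]]))
      }
      if (type == "integer") {
        if (any(conv[!is.na(conv)] %% 1 != 0)) {
          bad <- which(!is.na(conv) & conv %% 1 != 0)
          abort(sprintf("%s: column '%s' row %d: '%s' is not an integer",
                        source, col, bad[1], v[bad[1]]))
        }
        conv <- as.integer(conv)
      }
      out[[col]] <- conv
    } else {
      out[[col]] <- as.character(v)
      if (type == "enum") {
        domain <- sc$enums[[col]]
        bad <- which(!is.na(out[[col]]) & !out[[col]] %in% domain)
        if (length(bad)) {
          abort(sprintf("%s: column '%s' row %d: unknown value '%s' (expected one of %s)",
                        source, col, bad[1], out[[col]][bad[1]],
                        paste(domain, collapse = ", ")))
        }
      }
    }
  }
  key <- out[, intersect(sc$key, names(out)), drop = FALSE]
  if (ncol(key) && anyDuplicated(key)) {
    d <- anyDuplicated(key)
    abort(sprintf("%s: duplicate key (%s) at row %d",
                  source, paste(sc$key, collapse = ", "), d))
  }
  msg <- sc$checks(out)
  if (!is.null(msg)) abort(paste0(source, ": ", msg))
  out <- out[, names(sc$cols), drop = FALSE]
  attr(out, "hemp_schema") <- schema
  out
}

#' Write a pipeline table as delimited text
#'
#' Numbers are written in their shortest round-trippable decimal form, so
#' `read_table(write_table(x))` reproduces values to full stored precision.
#'
#' @param df Tibble to write.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, delim = ",") {
  readr::write_delim(df, path, delim = delim, na = "")
  invisible(path)
}
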