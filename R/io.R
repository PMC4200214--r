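# Table schemas: required columns and their types ("n" numeric, "c" character).
.table_schemas <- list(
  deposition = c(generation = "n", region = "c", deposition_fraction = "n",
                 surface_area_cm2 = "n", n_alveoli = "n"),
  retention = c(time_h = "n", mass_ug = "n"),
  cellular_dose = c(time_h = "n", nominal_ug_per_ml = "n",
                    measured_mass_ug = "n", n_cells = "n",
                    well_area_cm2 = "n"),
  delivered = c(time_h = "n", fraction_delivered = "n", mass_ug = "n",
                dose_ug_cm2 = "n"),
  regional_dose = c(generation = "n", region = "c", deposition_fraction = "n",
                    surface_area_cm2 = "n", n_alveoli = "n", mass_ug = "n"),
  bands = c(system = "c", metric = "c", lower = "n", upper = "n",
            cell_context = "c", effect = "c")
)

#' Validate a data frame against a packaged table schema
#'
#' Checks that all required columns are present and of the right type.
#' Extra columns raise a warning and are preserved; missing or non-numeric
#' required columns are errors that name the offending column.
#'
#' @param df a data frame
#' @param schema one of `r paste0('\x60', names(.table_schemas), '\x60', collapse = ", ")`
#' @return the validated tibble
#' @export
validate_table <- function(df, schema) {
  if (!schema %in% names(.table_schemas)) {
    abort(paste0("unknown schema: ", schema))
  }
  stopifnot(is.data.frame(df))
  spec <- .table_schemas[[schema]]
  miss <- setdiff(names(spec), names(df))
  if (length(miss)) {
    abort(sprintf("table does not match schema '%s': missing column(s) %s",
                  schema, paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    abort(sprintf("table for schema '%s' has no rows", schema))
  }
  for (col in names(spec)) {
    if (spec[[col]] == "n" && !is.numeric(df[[col]])) {
      abort(sprintf("column `%s` must be numeric (schema '%s')", col, schema))
    }
  }
  extra <- setdiff(names(df), names(spec))
  if (length(extra)) {
    warn(sprintf("table has extra column(s) beyond schema '%s': %s (preserved)",
                 schema, paste(extra, collapse = ", ")))
  }
  as_tibble(df)
}

#' Read and write schema-validated CSV tables
#'
#' Plain one-header-line CSV in, validated tibble out (and the reverse).
#' Numbers are serialised at full precision. An empty file is an explicit
#' error, not an empty table.
#'
#' @param path file path
#' @param schema schema name, see [validate_table()]
#' @return `read_dose_table()`: the validated tibble; `write_dose_table()`:
#'   `path`, invisibly
#' @export
read_dose_table <- function(path, schema) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0) abort(paste0("file is empty: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_table(df, schema)
}

#' @rdname read_dose_table
#' @param df the table to write (validated against the schema first)
#' @export
write_dose_table <- function(df, path, schema) {
  df <- suppressWarnings(validate_table(df, schema))
  readr::write_csv(df, path)
  invisible(path)
}

#' Packaged default pipeline configuration
#'
#' Reads the packaged YAML configuration carrying the SPIO study parameters:
#' particle/agglomerate/medium/well geometry, mouse and human respiratory
#' physiology, the exposure scenarios, in vitro fixture settings, regional
#' dosimetry constants, clearance fixture settings, the effective dose
#' bands, and solver settings.
#'
#' @param path optional path to a YAML file with the same structure; unknown
#'   keys are rejected with their location
#' @return a named list of class `pipeline_config`
#' @examples
#' cfg <- default_config()
#' names(cfg)
#' @export
default_config <- function(path = NULL) {
  default_path <- system.file("extdata", "config-default.yaml",
                              package = "particledose", mustWork = TRUE)
  template <- yaml::read_yaml(default_path)
  cfg <- if (is.null(path)) template else yaml::read_yaml(path)
  .check_config_keys(cfg, template, "config")
  structure(cfg, class = "pipeline_config")
}

# Recursively reject keys not present in the packaged template, reporting
# the dotted location of the offender.
.check_config_keys <- function(cfg, template, where) {
  if (!is.list(cfg) || !is.list(template)) return(invisible(TRUE))
  if (is.null(names(template))) return(invisible(TRUE))  # unnamed list: free-form
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s) at %s: %s",
                  where, paste(unknown, collapse = ", ")))
  }
  for (nm in names(cfg)) {
    .check_config_keys(cfg[[nm]], template[[nm]], paste0(where, "$", nm))
  }
  invisible(TRUE)
}
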