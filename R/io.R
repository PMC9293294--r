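## CSV schema shared by the reader, the writers and the synthetic generator.
## Decimal point, UTF-8, empty string = missing. Fluxes in kg N2O-N ha^-1
## period^-1, N input in kg N ha^-1, lengths in days.
.ef_numeric_cols <- c("latitude", "longitude", "annual_precip", "pet_ratio",
                      "n2o_treatment", "n2o_control", "n_input", "ef",
                      "soil_c_pct", "soil_ph", "length_days")
.ef_logical_cols <- c("fertilizer_synthetic", "fertilizer_organic", "irrigated",
                      "flooded_rice", "grazed_excreta", "enhanced_efficiency",
                      "organic_soil", "lab_or_model", "peer_reviewed")
.ef_character_cols <- c("record_id", "reference_id", "climate_zone",
                        "fertilizer_description", "organic_state",
                        "land_cover_raw", "usda_texture")
.ef_required_cols <- c("record_id", "reference_id", "climate_zone",
                       "n2o_treatment", "n2o_control", "n_input",
                       "land_cover_raw", "length_days")

#' Read an EF observation table
#'
#' Reads the documented CSV schema: one row per fertilization experiment with
#' treatment/control N2O-N fluxes (kg N2O-N ha^-1 period^-1), applied N
#' (kg N ha^-1), climate descriptors, fertilizer form flags, land cover, USDA
#' texture, soil C (% mass), pH, experiment length (days), irrigation and
#' provenance flags. Empty strings are missing values. Columns outside the
#' schema are carried through untouched.
#'
#' @param path Path to a CSV file.
#' @return Data frame with schema columns coerced to their documented types.
#' @export
read_ef_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                       fileEncoding = "UTF-8")
  missing_cols <- setdiff(.ef_required_cols, names(d))
  if (length(missing_cols)) {
    stop("EF table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cc in intersect(.ef_numeric_cols, names(d))) d[[cc]] <- as.numeric(d[[cc]])
  for (cc in intersect(.ef_logical_cols, names(d))) d[[cc]] <- as.logical(d[[cc]])
  for (cc in intersect(.ef_character_cols, names(d))) d[[cc]] <- as.character(d[[cc]])
  if (anyDuplicated(d$record_id)) {
    stop("duplicated record_id in ", path, call. = FALSE)
  }
  d
}

#' Write an EF observation table (or any derived table) as CSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ef_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gridded fertilizer-N cell list
#'
#' Tabular equivalent of a raster stack on a shared grid: one row per
#' cropland cell with columns `cell_id`, `country_code` (ISO-3166 alpha-3),
#' `climate` (`wet`/`dry`), `n_synthetic` and `n_manure` (Gg N per cell), and
#' optionally `rice_excluded` (whether flooded-rice N was already removed).
#'
#' @param path Path to a CSV file.
#' @return Validated data frame of grid cells.
#' @export
read_grid_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                       fileEncoding = "UTF-8")
  validate_grid(d)
}

validate_grid <- function(d) {
  needed <- c("cell_id", "country_code", "climate", "n_synthetic", "n_manure")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    stop("grid is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d$n_synthetic <- as.numeric(d$n_synthetic)
  d$n_manure <- as.numeric(d$n_manure)
  if (any(is.na(d$n_synthetic)) || any(is.na(d$n_manure)) ||
      any(d$n_synthetic < 0) || any(d$n_manure < 0)) {
    stop("grid N masses must be present and non-negative (Gg N)", call. = FALSE)
  }
  bad <- !d$climate %in% c("wet", "dry")
  if (any(bad)) {
    stop("grid climate must be 'wet' or 'dry'; offending cell(s): ",
         paste(utils::head(d$cell_id[bad], 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(d$rice_excluded)) d$rice_excluded <- TRUE
  d
}

#' Convert an N2O-N mass to N2O mass
#'
#' Emissions are reported as Gg N2O-N throughout; multiply by 44/28 to express
#' them as mass of the N2O molecule. Never applied by default.
#'
#' @param x Emission in Gg N2O-N (or any N2O-N mass unit).
#' @return The same mass as N2O.
#' @export
as_n2o_mass <- function(x) x * 44 / 28
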