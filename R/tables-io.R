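#' Read a per-tank census table
#'
#' Validates and loads tank census records. The victim count is the number
#' of missing (cannibalized) larvae, `n_victims = n_initial - n_survivors`;
#' if a `n_victims` column is present it must agree with that identity.
#'
#' @param path CSV path with required columns `tank_id`, `n_initial`,
#'   `n_survivors`, `n_cannibals`.
#' @return A tibble with columns `tank_id`, `n_initial`, `n_survivors`,
#'   `n_cannibals`, `n_victims`.
#' @export
read_census_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_census(df)
}

#' @rdname read_census_csv
#' @param census A census data frame (same columns as the CSV).
#' @export
validate_census <- function(census) {
  required <- c("tank_id", "n_initial", "n_survivors", "n_cannibals")
  missing <- setdiff(required, names(census))
  if (length(missing)) {
    abort(sprintf("census table is missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(census)
  counts <- c("n_initial", "n_survivors", "n_cannibals")
  for (cl in counts) {
    if (!is.numeric(df[[cl]]) || any(is.na(df[[cl]])) || any(df[[cl]] < 0) ||
      any(df[[cl]] != round(df[[cl]]))) {
      abort(sprintf("census column %s must hold non-negative integer counts", cl))
    }
  }
  victims <- df$n_initial - df$n_survivors
  if (any(victims < 0)) abort("n_survivors exceeds n_initial")
  if ("n_victims" %in% names(df) && !all(df$n_victims == victims)) {
    abort("n_victims must equal n_initial - n_survivors")
  }
  df$n_victims <- as.integer(victims)
  if (any(df$n_cannibals > df$n_survivors)) {
    abort("n_cannibals cannot exceed n_survivors")
  }
  df[c("tank_id", "n_initial", "n_survivors", "n_cannibals", "n_victims")]
}

#' Read a specimen body-dimension measurement table
#'
#' Loads the seven head dimensions (HW, JW1, JW2, EW, HL1, HL2, HL3), the
#' snout-vent length SVL (all mm), and the visual cannibal-evidence flags.
#' Missing flag columns default to `FALSE`.
#'
#' @param path CSV path with required columns `specimen_id`, `HW`, `JW1`,
#'   `JW2`, `EW`, `HL1`, `HL2`, `HL3`, `SVL`; optional logical columns
#'   `stomach_conspecific`, `visual_cannibal`, and `tank_id`.
#' @return A validated tibble.
#' @export
read_measurements_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_measurements(df)
}

measurement_dims <- c("HW", "JW1", "JW2", "EW", "HL1", "HL2", "HL3", "SVL")

#' @rdname read_measurements_csv
#' @param measurements A measurement data frame (same columns as the CSV).
#' @export
validate_measurements <- function(measurements) {
  required <- c("specimen_id", measurement_dims)
  missing <- setdiff(required, names(measurements))
  if (length(missing)) {
    abort(sprintf(
      "measurement table is missing required column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  df <- tibble::as_tibble(measurements)
  for (cl in measurement_dims) {
    if (!is.numeric(df[[cl]]) || any(is.na(df[[cl]])) || any(df[[cl]] <= 0)) {
      abort(sprintf("measurement column %s must be positive lengths (mm)", cl))
    }
  }
  if (any(df$SVL <= df$HW)) abort("SVL must exceed HW for every specimen")
  for (fl in c("stomach_conspecific", "visual_cannibal")) {
    if (!fl %in% names(df)) df[[fl]] <- FALSE
    df[[fl]] <- as.logical(df[[fl]])
    if (any(is.na(df[[fl]]))) abort(sprintf("flag column %s must be logical", fl))
  }
  df
}

#' Write census / measurement tables
#'
#' Thin [readr::write_csv()] wrappers that validate before writing, so a
#' written table always round-trips through the matching reader.
#'
#' @param census,measurements Validated tables.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(census, path) {
  readr::write_csv(validate_census(census), path)
  invisible(path)
}

#' @rdname write_census_csv
#' @export
write_measurements_csv <- function(measurements, path) {
  readr::write_csv(validate_measurements(measurements), path)
  invisible(path)
}

#' Published per-population census and distribution statistics
#'
#' The worked-example dataset shipped with the package: one row per
#' population (ten high-density tanks `g1`-`g10` plus the pooled solitary
#' pseudo-population `sol`), with the census counts of cannibals (`x1`) and
#' victims (`x2`) and the three distribution statistics of the within-tank
#' size/shape scores: `y1 = r(PC1_size, PC1_shape)`, `y2 = sk(PC1_size)`,
#' `y3 = sk(PC1_shape)`. This table drives [census_correlation_suite()] and
#' the census allometry line.
#'
#' @return An 11-row tibble with columns `population`, `x1`, `x2`, `y1`,
#'   `y2`, `y3`.
#' @export
#' @examples
#' hynobius_populations()
hynobius_populations <- function() {
  path <- system.file("extdata", "hynobius_population_stats.csv", package = "cannorm")
  if (path == "") {
    # during development (package not installed)
    path <- file.path("inst", "extdata", "hynobius_population_stats.csv")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  tibble::as_tibble(df)
}
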