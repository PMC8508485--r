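#' Read a stratified panel from CSV
#'
#' Expects columns `area_id`, `year`, `stratum_id`, `events`, `population`;
#' validates types, non-negativity, key uniqueness and stratum coverage.
#'
#' @param path Path to a CSV file.
#' @return A validated panel tibble.
#' @export
read_panel <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      area_id = readr::col_character(),
      year = readr::col_integer(),
      stratum_id = readr::col_character(),
      events = readr::col_integer(),
      population = readr::col_double()
    )
  )
  stop_on_parse_problems(x, path)
  validate_panel(x)
}

#' Read a standard-population weight table from CSV
#'
#' @param path Path to a CSV with columns `stratum_id`, `weight`.
#' @return Tibble `stratum_id`, `weight`.
#' @export
read_standard_population <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      stratum_id = readr::col_character(),
      weight = readr::col_double()
    )
  )
  stop_on_parse_problems(x, path)
  if (any(x$weight <= 0)) abort("weights must be strictly positive")
  if (anyDuplicated(x$stratum_id)) abort("duplicate stratum_id in standard population")
  x
}

#' Read an area-level covariate table from CSV
#'
#' @param path Path to a CSV with columns `area_id`, `year` and one column
#'   per raw covariate.
#' @return Covariate tibble.
#' @export
read_covariates <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    area_id = readr::col_character(),
    year = readr::col_integer(),
    .default = readr::col_double()
  ))
  stop_on_parse_problems(x, path)
  if (!all(c("area_id", "year") %in% names(x))) {
    abort("covariate table needs area_id and year columns")
  }
  dup <- x |>
    dplyr::count(.data$area_id, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate (area, year) rows, e.g. ", dup$area_id[1], "/", dup$year[1]))
  }
  x
}

stop_on_parse_problems <- function(x, path) {
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    abort(paste0(
      "malformed rows in ", path, ": line ",
      paste(head(pr$row, 5), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Write hotspot classifications to CSV
#'
#' One row per (area, year): the standardised rate, its confidence limits,
#' the all-area rate and the 0/1 hotspot flag.
#'
#' @param hotspots Output of [classify_hotspots()].
#' @param path Output CSV path.
#' @return The input, invisibly.
#' @export
write_hotspots <- function(hotspots, path) {
  hotspots |>
    dplyr::mutate(hotspot = as.integer(.data$hotspot)) |>
    dplyr::select(
      "area_id", "year", "assr", "lower", "upper",
      "all_area_assr", "hotspot"
    ) |>
    readr::write_csv(path)
  invisible(hotspots)
}

#' Write a synthetic dataset to a directory of CSV files
#'
#' Emits `panel.csv`, `covariates.csv` and `standard_population.csv` in the
#' formats the readers consume.
#'
#' @param sim A `synthetic_panel` from [generate_panel()].
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("panel.csv", "covariates.csv", "standard_population.csv"))
  readr::write_csv(sim$panel, paths[1])
  readr::write_csv(sim$covariates, paths[2])
  readr::write_csv(sim$standard_population, paths[3])
  invisible(paths)
}
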