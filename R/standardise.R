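#' Validate a stratified event/population panel
#'
#' A panel is a long tibble with one row per (area, year, age-sex stratum)
#' holding the event count and the person-count denominator for that cell.
#' Validation checks the column set, key uniqueness, non-negativity, and that
#' every (area, year) combination carries the same stratum set.
#'
#' @param panel A data frame with columns `area_id`, `year`, `stratum_id`,
#'   `events`, `population`.
#' @return The panel as a tibble, invisibly validated.
#' @export
validate_panel <- function(panel) {
  required <- c("area_id", "year", "stratum_id", "events", "population")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  panel <- tibble::as_tibble(panel)
  if (any(panel$events < 0, na.rm = TRUE)) abort("panel has negative event counts")
  if (any(panel$population < 0, na.rm = TRUE)) abort("panel has negative populations")
  if (anyNA(panel[required])) abort("panel contains missing values")
  dup <- panel |>
    dplyr::count(.data$area_id, .data$year, .data$stratum_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "duplicate (area, year, stratum) keys, e.g. ",
      dup$area_id[1], "/", dup$year[1], "/", dup$stratum_id[1]
    ))
  }
  strata <- sort(unique(panel$stratum_id))
  cover <- panel |>
    dplyr::count(.data$area_id, .data$year, name = "n_strata") |>
    dplyr::filter(.data$n_strata != length(strata))
  if (nrow(cover) > 0) {
    abort(paste0(
      "incomplete stratum coverage: area ", cover$area_id[1],
      ", year ", cover$year[1], " has ", cover$n_strata[1],
      " of ", length(strata), " strata"
    ))
  }
  panel
}

check_weights <- function(weights, panel) {
  if (!all(c("stratum_id", "weight") %in% names(weights))) {
    abort("weights must have columns stratum_id, weight")
  }
  if (any(weights$weight <= 0)) abort("standard-population weights must be strictly positive")
  missing_strata <- setdiff(unique(panel$stratum_id), weights$stratum_id)
  if (length(missing_strata) > 0) {
    abort(paste0(
      "standard population is missing strata: ",
      paste(head(missing_strata, 5), collapse = ", ")
    ))
  }
  tibble::as_tibble(weights)
}

#' Substitute all-area counts into small strata
#'
#' Stratum cells whose population falls below `threshold` are unstable for
#' direct standardisation. Rather than collapsing age groups, each small cell
#' is replaced by the all-area totals for the same stratum and year (events
#' and population alike), computed from the original, unsubstituted panel.
#'
#' @param panel A stratified panel (see [validate_panel()]).
#' @param threshold Population size below which a cell is substituted
#'   (default 30).
#' @return A panel tibble of the same shape with small cells replaced.
#' @export
substitute_small_strata <- function(panel, threshold = 30) {
  panel <- validate_panel(panel)
  if (threshold < 0) abort("threshold must be >= 0")
  totals <- panel |>
    dplyr::summarise(
      events_total = sum(.data$events),
      population_total = sum(.data$population),
      .by = c("stratum_id", "year")
    )
  panel |>
    dplyr::left_join(totals, by = c("stratum_id", "year")) |>
    dplyr::mutate(
      small = .data$population < threshold,
      events = ifelse(.data$small, .data$events_total, .data$events),
      population = ifelse(.data$small, .data$population_total, .data$population)
    ) |>
    dplyr::select(-"events_total", -"population_total", -"small")
}

#' Directly age-sex standardised rates per area and year
#'
#' Computes, for each (area, year), the weighted average of stratum-specific
#' rates using the standard-population weights: the directly standardised rate
#' `sum(w * O/n) / sum(w)` and its variance `sum(w^2 * O/n^2) / sum(w)^2`.
#'
#' @param panel A stratified panel, typically after [substitute_small_strata()].
#' @param weights Standard population: tibble with `stratum_id`, `weight`.
#' @param area,year Optional filters restricting the result.
#' @return Tibble with `area_id`, `year`, `assr`, `variance`.
#' @export
compute_assr <- function(panel, weights, area = NULL, year = NULL) {
  panel <- validate_panel(panel)
  weights <- check_weights(weights, panel)
  if (!is.null(area)) panel <- dplyr::filter(panel, .data$area_id %in% .env$area)
  if (!is.null(year)) panel <- dplyr::filter(panel, .data$year %in% .env$year)
  if (nrow(panel) == 0) abort("no panel rows match the requested area/year")
  zero_pop <- dplyr::filter(panel, .data$population == 0)
  if (nrow(zero_pop) > 0) {
    abort(paste0(
      "zero population in stratum ", zero_pop$stratum_id[1],
      " (area ", zero_pop$area_id[1], ", year ", zero_pop$year[1],
      "); substitute small strata first"
    ))
  }
  panel |>
    dplyr::left_join(weights, by = "stratum_id") |>
    dplyr::summarise(
      assr = sum(.data$weight * .data$events / .data$population) / sum(.data$weight),
      variance = sum(.data$weight^2 * .data$events / .data$population^2) /
        sum(.data$weight)^2,
      .by = c("area_id", "year")
    )
}

#' Byar's approximation to Poisson confidence limits for a count
#'
#' Closed-form approximation to the exact Poisson interval for an observed
#' count `O`. The lower limit is defined as 0 when `O = 0` (the formula is
#' singular there) and is clamped at 0.
#'
#' @param o Vector of non-negative counts.
#' @param z Normal quantile for the desired two-sided confidence level
#'   (default 1.959964, i.e. 95%).
#' @return Tibble with columns `lower`, `upper`.
#' @export
byar_limits <- function(o, z = Z_DEFAULT) {
  if (any(o < 0)) abort("counts must be non-negative")
  if (z <= 0) abort("z must be positive")
  lower <- ifelse(
    o == 0, 0,
    pmax(0, o * (1 - 1 / (9 * o) - z / (3 * sqrt(o)))^3)
  )
  upper <- (o + 1) * (1 - 1 / (9 * (o + 1)) + z / (3 * sqrt(o + 1)))^3
  tibble::tibble(lower = lower, upper = upper)
}

#' All-area summary per year
#'
#' Pools the panel across areas within each year: the total event count (whose
#' Poisson variance equals itself), its Byar confidence limits, and the
#' all-area standardised rate computed from the pooled stratum totals.
#'
#' @inheritParams compute_assr
#' @param z Normal quantile for the Byar limits.
#' @return Tibble with `year`, `events`, `variance`, `lower`, `upper`,
#'   `all_area_assr`.
#' @export
all_area_summary <- function(panel, weights, year = NULL, z = Z_DEFAULT) {
  panel <- validate_panel(panel)
  weights <- check_weights(weights, panel)
  if (!is.null(year)) {
    panel <- dplyr::filter(panel, .data$year %in% .env$year)
    if (nrow(panel) == 0) abort("panel has no rows for the requested year")
  }
  pooled <- panel |>
    dplyr::summarise(
      events = sum(.data$events),
      population = sum(.data$population),
      .by = c("year", "stratum_id")
    ) |>
    dplyr::mutate(area_id = "all")
  rates <- compute_assr(pooled, weights)
  totals <- pooled |>
    dplyr::summarise(events = sum(.data$events), .by = "year")
  lims <- byar_limits(totals$events, z)
  totals |>
    dplyr::mutate(
      variance = .data$events,
      lower = lims$lower,
      upper = lims$upper
    ) |>
    dplyr::left_join(
      dplyr::select(rates, "year", all_area_assr = "assr"),
      by = "year"
    )
}

#' Confidence limits for area-level standardised rates
#'
#' Carries the Byar limits of the all-area count over to each area rate by
#' the variance-ratio construction:
#' `lower = assr + sqrt(Var(assr)/Var(O_l)) * (O_l_lower - O_l)`, and
#' analogously for the upper limit. Lower limits are clamped at 0.
#'
#' @param rates Output of [compute_assr()].
#' @param summary Output of [all_area_summary()] covering the same years.
#' @return `rates` with columns `lower`, `upper`, `all_area_assr` added.
#' @export
assr_confidence_limits <- function(rates, summary) {
  if (any(summary$variance <= 0)) {
    abort("all-area count variance is zero; confidence limits are undefined")
  }
  rates |>
    dplyr::left_join(
      dplyr::select(summary, "year",
        ol = "events", ol_var = "variance",
        ol_lower = "lower", ol_upper = "upper", "all_area_assr"
      ),
      by = "year"
    ) |>
    dplyr::mutate(
      lower = pmax(0, .data$assr +
        sqrt(.data$variance / .data$ol_var) * (.data$ol_lower - .data$ol)),
      upper = .data$assr +
        sqrt(.data$variance / .data$ol_var) * (.data$ol_upper - .data$ol)
    ) |>
    dplyr::select(-"ol", -"ol_var", -"ol_lower", -"ol_upper")
}

#' Classify hotspot areas per year
#'
#' An area is a hotspot in a given year when the lower confidence limit of its
#' directly standardised rate exceeds the all-area standardised rate for that
#' year, i.e. its rate is statistically significantly above the overall rate.
#'
#' @inheritParams compute_assr
#' @param z Normal quantile setting the confidence level (default two-sided
#'   95%).
#' @param small_stratum_threshold If non-`NULL`, small-stratum substitution is
#'   applied first with this population threshold; pass `NULL` when the panel
#'   has already been substituted.
#' @param per Display multiplier for rates (1 = per person-year; 1e5 = per
#'   100,000).
#' @return Tibble of class `hotspot_rates` with one row per (area, year):
#'   `area_id`, `year`, `assr`, `variance`, `lower`, `upper`, `all_area_assr`,
#'   `hotspot`.
#' @export
classify_hotspots <- function(panel, weights, z = Z_DEFAULT,
                              small_stratum_threshold = NULL, per = 1) {
  if (!is.null(small_stratum_threshold)) {
    panel <- substitute_small_strata(panel, small_stratum_threshold)
  }
  rates <- compute_assr(panel, weights)
  summ <- all_area_summary(panel, weights, z = z)
  out <- assr_confidence_limits(rates, summ) |>
    dplyr::mutate(
      hotspot = .data$lower > .data$all_area_assr,
      dplyr::across(c("assr", "lower", "upper", "all_area_assr"), ~ .x * per),
      variance = .data$variance * per^2
    ) |>
    dplyr::arrange(.data$year, .data$area_id)
  class(out) <- c("hotspot_rates", class(out))
  attr(out, "z") <- z
  out
}

#' Hotspot indicators as an area-by-year logical matrix
#'
#' @param hotspots A tibble with columns `area_id`, `year`, `hotspot` (e.g.
#'   from [classify_hotspots()]).
#' @return Logical matrix with one row per area and one column per year.
#' @export
hotspot_matrix <- function(hotspots) {
  wide <- hotspots |>
    dplyr::select("area_id", "year", "hotspot") |>
    dplyr::arrange(.data$year) |>
    tidyr::pivot_wider(names_from = "year", values_from = "hotspot")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$area_id
  m
}
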