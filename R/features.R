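#' Signed log transform with a linear core
#'
#' Approximate log transform for variables that may contain zeros or small
#' values: the identity inside `[-c, c]`, and `sign(x) * c * (1 + log(|x|/c))`
#' outside. Continuous, odd, and strictly increasing; with `c = 1` it agrees
#' with `log(x) + 1` for `x >= 1`.
#'
#' @param x Numeric vector.
#' @param c Positive scale at which the log branch takes over (default 1).
#' @return Transformed numeric vector.
#' @export
signed_log_transform <- function(x, c = 1) {
  if (c <= 0) abort("c must be positive")
  ifelse(abs(x) <= c, x, sign(x) * c * (1 + log(abs(x) / c)))
}

#' Percentile ranks
#'
#' Maps each value to `100 * (rank - 0.5) / n` with mean ranks for ties, so
#' ranks lie strictly inside (0, 100) and a fully tied vector maps to 50.
#'
#' @param x Numeric vector of length at least 2.
#' @return Numeric vector of percentile ranks in (0, 100).
#' @export
percentile_rank <- function(x) {
  if (length(x) < 2) abort("percentile_rank needs at least 2 values")
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Centre values around their within-year mean
#'
#' @param x Numeric vector.
#' @param year Grouping vector of the same length.
#' @return `x` with the group mean subtracted within each year.
#' @export
center_within_year <- function(x, year) {
  if (length(x) == 0) abort("cannot centre an empty group")
  if (length(x) != length(year)) abort("x and year must have the same length")
  stats::ave(x, year, FUN = function(v) v - mean(v))
}

#' Consecutive years classified as a hotspot
#'
#' For each (area, year), the length of the maximal run of hotspot years
#' ending at that year (inclusive by default). An area that is not a hotspot
#' in the query year scores 0. With `include_current = FALSE` the run is taken
#' to end at the previous year instead, so the current year's status is not
#' used.
#'
#' @param hotspots Tibble with `area_id`, `year`, `hotspot`.
#' @param area,year Optional filters; with both given a single integer is
#'   returned.
#' @param include_current Count the query year itself in the run (default
#'   `TRUE`).
#' @return Tibble `area_id`, `year`, `past_hot_years`, or a single integer
#'   when both `area` and `year` are scalars.
#' @export
consecutive_hot_years <- function(hotspots, area = NULL, year = NULL,
                                  include_current = TRUE) {
  runs <- hotspots |>
    dplyr::select("area_id", "year", "hotspot") |>
    dplyr::arrange(.data$area_id, .data$year) |>
    dplyr::mutate(
      past_hot_years = Reduce(
        function(acc, h) if (h) acc + 1L else 0L,
        .data$hotspot, accumulate = TRUE, init = 0L
      )[-1],
      .by = "area_id"
    )
  if (!include_current) {
    runs <- runs |>
      dplyr::mutate(
        past_hot_years = dplyr::lag(.data$past_hot_years, default = 0L),
        .by = "area_id"
      )
  }
  runs <- dplyr::select(runs, -"hotspot")
  if (!is.null(area)) runs <- dplyr::filter(runs, .data$area_id %in% .env$area)
  if (!is.null(year)) runs <- dplyr::filter(runs, .data$year %in% .env$year)
  if (length(area) == 1 && length(year) == 1) {
    if (nrow(runs) != 1) abort("area/year not found in hotspot matrix")
    return(runs$past_hot_years)
  }
  runs
}

#' Persistent-hotspot outcome for a prediction horizon
#'
#' The dichotomous outcome used throughout model selection: an area is a
#' positive case at covariate year `l` and horizon `m` when it is a hotspot in
#' every one of the years `l+1, ..., l+m`.
#'
#' @param hotspots Tibble with `area_id`, `year`, `hotspot`.
#' @param l Covariate-definition year.
#' @param m Horizon in years (positive integer).
#' @return Tibble `area_id`, `outcome` (logical).
#' @export
build_outcome <- function(hotspots, l, m) {
  if (m < 1) abort("horizon m must be >= 1")
  needed <- l + seq_len(m)
  have <- unique(hotspots$year)
  if (!all(needed %in% have)) {
    abort(paste0(
      "outcome undefined: years ", paste(setdiff(needed, have), collapse = ", "),
      " not present in the hotspot matrix"
    ))
  }
  hotspots |>
    dplyr::filter(.data$year %in% needed) |>
    dplyr::summarise(outcome = all(.data$hotspot), .by = "area_id")
}

#' Define a covariate-catalogue term
#'
#' @param name Term name (also the output column name in a model frame).
#' @param kind One of `"main"`, `"quadratic"`, `"interaction"`.
#' @param parents Names of parent terms (the linear parent of a quadratic; the
#'   two main effects of an interaction).
#' @param source Raw covariate column the term is built from (mains only);
#'   the special source `"past_hot_years"` is derived from the hotspot matrix.
#' @param transform One of `"none"`, `"signed_log"`, `"log"`,
#'   `"percentile_rank"`, `"center_within_year"`.
#' @param group Exclusivity-group tag (`NA` for unconstrained terms); at most
#'   one term per group may enter a model.
#' @param applicability `"both"`, `"statewide"`, or `"metropolitan"`.
#' @return One-row tibble describing the term.
#' @export
catalogue_term <- function(name, kind = "main", parents = character(),
                           source = name, transform = "none",
                           group = NA_character_, applicability = "both") {
  kind <- match.arg(kind, c("main", "quadratic", "interaction"))
  transform <- match.arg(
    transform,
    c("none", "signed_log", "log", "percentile_rank", "center_within_year")
  )
  tibble::tibble(
    name = name, kind = kind, parents = list(parents), source = source,
    transform = transform, group = group, applicability = applicability
  )
}

validate_catalogue <- function(catalogue) {
  if (anyDuplicated(catalogue$name)) abort("catalogue term names must be unique")
  for (i in seq_len(nrow(catalogue))) {
    pr <- catalogue$parents[[i]]
    if (catalogue$kind[i] == "main" && length(pr) != 0) {
      abort(paste0("main term ", catalogue$name[i], " cannot have parents"))
    }
    if (catalogue$kind[i] == "quadratic" && length(pr) != 1) {
      abort(paste0("quadratic term ", catalogue$name[i], " needs exactly one parent"))
    }
    if (catalogue$kind[i] == "interaction" && length(pr) != 2) {
      abort(paste0("interaction term ", catalogue$name[i], " needs exactly two parents"))
    }
    if (!all(pr %in% catalogue$name)) {
      abort(paste0("term ", catalogue$name[i], " names unknown parents"))
    }
  }
  catalogue
}

#' The packaged area-level predictor catalogues
#'
#' The candidate-predictor set used for hotspot prediction: percentage of
#' Aboriginal residents (signed-log transformed), percentage aged 75+ with a
#' quadratic term, within-year-centred percentage male, rurality (state-wide
#' only), distance to the nearest emergency department (signed-log), two
#' mutually exclusive general-practice accessibility measures (weighted
#' distance, signed-log; and a gravity-model accessibility index as a
#' percentile rank), four mutually exclusive SEIFA index percentiles, the
#' number of past consecutive hotspot years, and interactions of the latter
#' and of ED distance with each SEIFA percentile.
#'
#' @param region `"statewide"` (includes rurality) or `"metropolitan"`.
#' @param distance_transform `"signed_log"` (default) or `"log"` for the
#'   strictly positive distance covariates.
#' @return A catalogue tibble (one row per term).
#' @export
default_catalogue <- function(region = c("statewide", "metropolitan"),
                              distance_transform = c("signed_log", "log")) {
  region <- match.arg(region)
  distance_transform <- match.arg(distance_transform)
  seifa <- c("seifa_irsd", "seifa_irsad", "seifa_ieo", "seifa_ier")
  terms <- dplyr::bind_rows(
    catalogue_term("pct_aboriginal", transform = "signed_log"),
    catalogue_term("pct_75plus"),
    catalogue_term("pct_75plus_sq", kind = "quadratic", parents = "pct_75plus"),
    catalogue_term("pct_male", transform = "center_within_year"),
    catalogue_term("rurality", applicability = "statewide"),
    catalogue_term("ed_distance", transform = distance_transform),
    catalogue_term("gp_distance", transform = distance_transform, group = "gp_access"),
    catalogue_term("gp_access_pct",
      source = "gp_access_index",
      transform = "percentile_rank", group = "gp_access"
    ),
    catalogue_term("past_hot_years", source = "past_hot_years"),
    dplyr::bind_rows(lapply(seifa, function(s) {
      catalogue_term(paste0(s, "_pct"),
        source = s, transform = "percentile_rank",
        group = "seifa"
      )
    })),
    dplyr::bind_rows(lapply(seifa, function(s) {
      catalogue_term(paste0("past_hot_years:", s, "_pct"),
        kind = "interaction",
        parents = c("past_hot_years", paste0(s, "_pct"))
      )
    })),
    dplyr::bind_rows(lapply(seifa, function(s) {
      catalogue_term(paste0("ed_distance:", s, "_pct"),
        kind = "interaction",
        parents = c("ed_distance", paste0(s, "_pct"))
      )
    }))
  )
  if (region == "metropolitan") {
    terms <- dplyr::filter(terms, .data$applicability != "statewide")
  }
  validate_catalogue(terms)
}

apply_transform <- function(x, transform, year, c = 1) {
  switch(transform,
    none = x,
    signed_log = signed_log_transform(x, c),
    log = log(x),
    percentile_rank = percentile_rank(x),
    center_within_year = center_within_year(x, year),
    abort(paste0("unknown transform: ", transform))
  )
}

#' Assemble the area-level model frame for one covariate year
#'
#' Builds one row per area: the raw covariates of year `l` pushed through
#' their declared transforms (signed-log, percentile ranking across areas,
#' within-year centring), the derived past-consecutive-hot-years predictor,
#' quadratic and interaction columns formed from the transformed parents, and
#' the persistent-hotspot outcome over years `l+1, ..., l+m`.
#'
#' @param hotspots Tibble with `area_id`, `year`, `hotspot`.
#' @param covariates Tibble with `area_id`, `year`, and one column per raw
#'   covariate named in the catalogue's `source` field.
#' @param catalogue A catalogue tibble (see [default_catalogue()]).
#' @param l Covariate-definition year.
#' @param m Prediction horizon in years.
#' @param include_current Whether the past-hot-years run includes year `l`.
#' @param signed_log_c Scale constant for the signed-log transform.
#' @return Tibble of class `model_frame`: `area_id`, `outcome`, one column per
#'   catalogue term; attributes `l`, `m`, `terms`.
#' @export
assemble_model_frame <- function(hotspots, covariates, catalogue, l, m,
                                 include_current = TRUE, signed_log_c = 1) {
  catalogue <- validate_catalogue(catalogue)
  outcome <- build_outcome(hotspots, l, m)
  areas <- sort(unique(hotspots$area_id))
  cov_l <- covariates |>
    dplyr::filter(.data$year == l) |>
    dplyr::arrange(.data$area_id)
  frame <- tibble::tibble(area_id = areas) |>
    dplyr::left_join(outcome, by = "area_id")

  mains <- dplyr::filter(catalogue, .data$kind == "main")
  for (i in seq_len(nrow(mains))) {
    src <- mains$source[i]
    if (src == "past_hot_years") {
      phy <- consecutive_hot_years(hotspots,
        year = l,
        include_current = include_current
      )
      frame[[mains$name[i]]] <-
        phy$past_hot_years[match(frame$area_id, phy$area_id)]
    } else {
      if (!src %in% names(cov_l)) {
        abort(paste0("covariate column missing: ", src))
      }
      vals <- cov_l[[src]][match(frame$area_id, cov_l$area_id)]
      if (anyNA(vals)) {
        missing_areas <- frame$area_id[is.na(vals)]
        abort(paste0(
          "missing covariate ", src, " for areas: ",
          paste(head(missing_areas, 5), collapse = ", ")
        ))
      }
      frame[[mains$name[i]]] <-
        apply_transform(vals, mains$transform[i], rep(l, length(vals)),
          c = signed_log_c
        )
    }
  }
  quads <- dplyr::filter(catalogue, .data$kind == "quadratic")
  for (i in seq_len(nrow(quads))) {
    frame[[quads$name[i]]] <- frame[[quads$parents[[i]]]]^2
  }
  inters <- dplyr::filter(catalogue, .data$kind == "interaction")
  for (i in seq_len(nrow(inters))) {
    pr <- inters$parents[[i]]
    frame[[inters$name[i]]] <- frame[[pr[1]]] * frame[[pr[2]]]
  }
  attr(frame, "l") <- l
  attr(frame, "m") <- m
  attr(frame, "terms") <- catalogue$name
  class(frame) <- c("model_frame", class(frame))
  frame
}

#' Model frames for a span of covariate years
#'
#' Convenience wrapper producing one model frame per covariate year, keyed by
#' year, as consumed by the rolling-forecast comparison engine.
#'
#' @inheritParams assemble_model_frame
#' @param years Covariate years to build frames for.
#' @return Named list of model frames (names are the years).
#' @export
model_frames_by_year <- function(hotspots, covariates, catalogue, years, m,
                                 include_current = TRUE) {
  frames <- lapply(years, function(l) {
    assemble_model_frame(hotspots, covariates, catalogue, l, m,
      include_current = include_current
    )
  })
  names(frames) <- as.character(years)
  frames
}
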