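#' Current-hotspots prediction rule
#'
#' Predicts as future hotspots exactly the areas classified as hotspots in
#' the prediction year `l`.
#'
#' @param hotspots Tibble with `area_id`, `year`, `hotspot`.
#' @param l Prediction year.
#' @return Character vector of predicted area ids.
#' @export
current_hotspots_rule <- function(hotspots, l) {
  if (!l %in% hotspots$year) abort(paste0("year ", l, " not in hotspot matrix"))
  sort(hotspots$area_id[hotspots$year == l & hotspots$hotspot])
}

#' Past-persistent-hotspots prediction rule
#'
#' Predicts as future hotspots the areas classified as hotspots in every one
#' of the `run_length` consecutive years up to and including `l`. The default
#' run of 6 years reflects common practice with relatively scarce persistent
#' hotspots; 10 years has also been used for national analyses.
#'
#' @inheritParams current_hotspots_rule
#' @param run_length Required number of consecutive hotspot years (>= 1).
#' @return Character vector of predicted area ids.
#' @export
past_persistent_hotspots_rule <- function(hotspots, l, run_length = 6) {
  if (run_length < 1) abort("run_length must be >= 1")
  needed <- (l - run_length + 1):l
  have <- unique(hotspots$year)
  if (!all(needed %in% have)) {
    abort(paste0(
      "insufficient history: years ",
      paste(setdiff(needed, have), collapse = ", "), " missing"
    ))
  }
  persistent <- hotspots |>
    dplyr::filter(.data$year %in% needed) |>
    dplyr::summarise(all_hot = all(.data$hotspot), .by = "area_id") |>
    dplyr::filter(.data$all_hot)
  sort(persistent$area_id)
}

#' Evaluate a prediction rule against observed future hotspots
#'
#' Tallies the confusion counts of a predicted area set against the set of
#' positive-outcome areas within a universe of areas, and reports sensitivity
#' and PPV. PPV is explicitly `NA` when the predicted set is empty (no
#' predictions to be correct about), while sensitivity is 0 when positives
#' exist but none are predicted.
#'
#' @param predicted Character vector of predicted hotspot areas.
#' @param positives Character vector of areas observed to be positive.
#' @param universe Character vector of all areas under consideration.
#' @param rule Label recorded in the output (default `"rule"`).
#' @return One-row tibble: `rule`, `n_predicted`, `TP`, `FP`, `FN`, `TN`,
#'   `sensitivity`, `ppv`.
#' @export
evaluate_rule <- function(predicted, positives, universe, rule = "rule") {
  if (!all(predicted %in% universe)) abort("predicted areas outside universe")
  if (!all(positives %in% universe)) abort("positive areas outside universe")
  tp <- length(intersect(predicted, positives))
  fp <- length(setdiff(predicted, positives))
  fn <- length(setdiff(positives, predicted))
  tn <- length(universe) - tp - fp - fn
  counts <- tibble::tibble(TP = tp, FP = fp, FN = fn, TN = tn)
  tibble::tibble(
    rule = rule,
    n_predicted = tp + fp,
    counts,
    sensitivity = pooled_metric(counts, "sensitivity"),
    ppv = pooled_metric(counts, "ppv")
  )
}

#' Evaluate both baseline rules on a hotspot matrix
#'
#' Applies the current-hotspots and past-persistent-hotspots rules at
#' prediction year `l` and scores them against the future outcome. The
#' outcome target is configurable: `"persistent"` scores against areas hot in
#' all of years `l+1, ..., l+m` (the same outcome the model pipeline
#' predicts); `"single_year"` scores against areas hot in year `l+m` only.
#'
#' @inheritParams past_persistent_hotspots_rule
#' @param m Prediction horizon in years.
#' @param outcome Outcome target, `"persistent"` (default) or
#'   `"single_year"`.
#' @return Tibble with one row per rule (see [evaluate_rule()]).
#' @export
evaluate_baselines <- function(hotspots, l, m, run_length = 6,
                               outcome = c("persistent", "single_year")) {
  outcome <- match.arg(outcome)
  universe <- sort(unique(hotspots$area_id))
  positives <- if (outcome == "persistent") {
    oc <- build_outcome(hotspots, l, m)
    sort(oc$area_id[oc$outcome])
  } else {
    current_hotspots_rule(hotspots, l + m)
  }
  dplyr::bind_rows(
    evaluate_rule(
      current_hotspots_rule(hotspots, l),
      positives, universe,
      rule = "current_hotspots"
    ),
    evaluate_rule(
      past_persistent_hotspots_rule(hotspots, l, run_length),
      positives, universe,
      rule = "past_persistent_hotspots"
    )
  )
}
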