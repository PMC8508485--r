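#' Calibration step: attainable PPV across a grid of sensitivity thresholds
#'
#' Runs a small number of CV repeats once, then re-tallies the cached fits at
#' each minimum-sensitivity threshold of the grid, recording the pooled
#' sensitivity and PPV of every candidate model at every threshold. The
#' resulting table shows what PPV is attainable while holding sensitivity
#' above each threshold, from which a minimum sensitivity `t*` can be chosen.
#'
#' @inheritParams repeated_cv
#' @param Q_cal Number of calibration repeats (default 5).
#' @param grid Sensitivity thresholds (default `seq(0, 0.9, by = 0.1)`).
#' @return Object of class `hotspot_calibration`: `grid` (per threshold and
#'   model: pooled sensitivity and PPV), `best` (per threshold: the optimal
#'   model and its PPV), plus the layout parameters.
#' @export
calibration_step <- function(models, train_frame, test_frame, K = 5,
                             Q_cal = 5, grid = seq(0, 0.9, by = 0.1),
                             seed = 1, stratify = TRUE) {
  if (Q_cal < 1) abort("Q_cal must be >= 1")
  cache <- cv_fit_cache(models, train_frame, test_frame, K, Q_cal, seed, stratify)
  per_t <- lapply(grid, function(t) {
    counts <- tally_cache(cache, "ppv", "sensitivity", t)
    add_count_metrics(pool_counts(counts, by = "model_id")) |>
      dplyr::mutate(threshold = t, .before = 1)
  })
  grid_tbl <- dplyr::bind_rows(per_t) |>
    dplyr::select(
      "threshold", "model_id", "TP", "FP", "FN", "TN",
      "sensitivity", "ppv"
    )
  best <- grid_tbl |>
    dplyr::filter(!is.na(.data$sensitivity) &
      .data$sensitivity >= .data$threshold) |>
    dplyr::filter(!is.na(.data$ppv)) |>
    dplyr::slice_max(.data$ppv, n = 1, with_ties = FALSE, by = "threshold") |>
    dplyr::select("threshold", "model_id", "sensitivity", "ppv")
  structure(
    list(
      grid = grid_tbl, best = best, models = models,
      K = cache$K, Q_cal = Q_cal, seed = seed
    ),
    class = "hotspot_calibration"
  )
}

#' Choose the minimum sensitivity threshold
#'
#' The intended mode is a user-supplied `t_star` reflecting the requirements
#' of the planned intervention. Alternatively, given a PPV floor, the largest
#' grid threshold whose best attainable pooled PPV still meets the floor is
#' returned (0, with a warning, when none does).
#'
#' @param calibration A `hotspot_calibration`.
#' @param ppv_floor Minimum acceptable PPV for the automatic rule.
#' @param t_star Explicit user override; returned unchanged when supplied.
#' @return The chosen minimum sensitivity threshold.
#' @export
choose_sensitivity_threshold <- function(calibration, ppv_floor = NULL,
                                         t_star = NULL) {
  if (!is.null(t_star)) return(t_star)
  if (is.null(ppv_floor)) abort("supply either t_star or ppv_floor")
  ok <- calibration$best |>
    dplyr::filter(!is.na(.data$ppv) & .data$ppv >= ppv_floor)
  if (nrow(ok) == 0) {
    warn("no threshold attains the requested PPV floor; returning 0")
    return(0)
  }
  max(ok$threshold)
}

#' Empirical quantile interval of a per-repeat metric series
#'
#' Undefined (NA) repeats are excluded; their count is reported as an
#' attribute. With fewer than two defined values the interval itself is
#' flagged undefined.
#'
#' @param x Numeric vector of within-repeat pooled metric values.
#' @param probs Two probabilities (default 2.5% and 97.5%).
#' @return Named numeric vector `lo`, `hi`; attribute `n_undefined`.
#' @export
quantile_interval <- function(x, probs = c(0.025, 0.975)) {
  n_undef <- sum(is.na(x))
  x <- x[!is.na(x)]
  out <- if (length(x) < 2) {
    c(lo = NA_real_, hi = NA_real_)
  } else {
    stats::setNames(quantile(x, probs = probs, names = FALSE), c("lo", "hi"))
  }
  attr(out, "n_undefined") <- n_undef
  out
}

#' Implementation step: select the optimal model at a sensitivity threshold
#'
#' Runs the full complement of CV repeats at the chosen minimum sensitivity
#' `t_star` and selects the model maximising pooled PPV among those whose
#' pooled sensitivity meets `t_star`. Ties prefer higher pooled sensitivity,
#' then fewer terms, then the lowest model id; an undefined pooled PPV ranks
#' below any defined value. Also reports the ten best models with their mean
#' odds ratios, per-repeat metric series for stability assessment, and 95%
#' quantile intervals across repeats for the optimal model.
#'
#' @inheritParams repeated_cv
#' @param Q_impl Number of implementation repeats (default 250).
#' @param t_star Minimum sensitivity threshold from the calibration step.
#' @return Object of class `hotspot_selection`.
#' @export
implementation_step <- function(models, train_frame, test_frame, K = 5,
                                Q_impl = 250, t_star = 0, seed = 1,
                                stratify = TRUE) {
  cv <- repeated_cv(
    models, train_frame, test_frame,
    K = K, Q = Q_impl, seed = seed,
    objective = "ppv", constraint = "sensitivity", min_constraint = t_star,
    stratify = stratify
  )
  ranked <- cv$pooled |>
    dplyr::left_join(
      dplyr::select(models, "model_id", "n_terms", "terms"),
      by = "model_id"
    ) |>
    dplyr::mutate(ppv_rank = ifelse(is.na(.data$ppv), -Inf, .data$ppv)) |>
    dplyr::arrange(
      dplyr::desc(.data$ppv_rank), dplyr::desc(.data$sensitivity),
      .data$n_terms, .data$model_id
    ) |>
    dplyr::select(-"ppv_rank")
  eligible <- ranked |>
    dplyr::filter(!is.na(.data$sensitivity) & .data$sensitivity >= t_star)
  optimal <- if (nrow(eligible) == 0) NULL else eligible[1, ]
  if (is.null(optimal)) {
    warn(paste0(
      "no model attains pooled sensitivity >= ", t_star,
      "; returning an empty selection"
    ))
  }
  best10 <- head(eligible, 10) |>
    dplyr::left_join(cv$mean_or, by = "model_id") |>
    tidyr::nest(odds_ratios = c("term", "mean_or"))
  quantiles <- NULL
  per_repeat_opt <- NULL
  if (!is.null(optimal)) {
    per_repeat_opt <- dplyr::filter(cv$per_repeat, .data$model_id == optimal$model_id)
    quantiles <- purrr::map_dfr(
      c("sensitivity", "specificity", "ppv", "npv"),
      function(mname) {
        qi <- quantile_interval(per_repeat_opt[[mname]])
        tibble::tibble(
          metric = mname,
          pooled = optimal[[mname]],
          lo = qi[["lo"]], hi = qi[["hi"]],
          median_repeat = stats::median(per_repeat_opt[[mname]], na.rm = TRUE),
          n_undefined = attr(qi, "n_undefined")
        )
      }
    )
  }
  structure(
    list(
      t_star = t_star,
      optimal = optimal,
      ranked = ranked,
      best10 = best10,
      quantiles = quantiles,
      per_repeat = cv$per_repeat,
      per_repeat_optimal = per_repeat_opt,
      counts = cv$counts,
      mean_or = cv$mean_or,
      n_predicted = if (!is.null(optimal)) {
        (optimal$TP + optimal$FP) / Q_impl
      } else {
        NA_real_
      },
      K = cv$K, Q_impl = Q_impl, seed = seed
    ),
    class = "hotspot_selection"
  )
}

#' @export
print.hotspot_selection <- function(x, ...) {
  cat("Model selection at minimum sensitivity t* = ", x$t_star,
    " (K = ", x$K, ", Q = ", x$Q_impl, ")\n",
    sep = ""
  )
  if (is.null(x$optimal)) {
    cat("No model attained the sensitivity threshold.\n")
  } else {
    cat(
      "Optimal model ", x$optimal$model_id, ": ",
      paste(x$optimal$terms[[1]], collapse = " + "), "\n",
      sep = ""
    )
    print(x$quantiles)
  }
  invisible(x)
}

#' Refit the optimal model structure and forecast future hotspots
#'
#' Applies a selected model structure to the most recent frame available:
#' refits on all areas, selects a classification threshold on that same
#' frame, and returns each area's predicted probability of being a persistent
#' future hotspot together with the thresholded prediction.
#'
#' @param terms Character vector of term columns (the optimal structure).
#' @param frame The most recent model frame with a defined outcome.
#' @inheritParams run_area_fold_cv
#' @return Tibble of class `hotspot_forecast`: `area_id`, `prob`,
#'   `predicted`; attributes `threshold`, `fit`, `n_predicted`.
#' @export
refit_and_forecast <- function(terms, frame, objective = "ppv",
                               constraint = "sensitivity",
                               min_constraint = 0) {
  frame <- check_model_frame(frame)
  x <- design_matrix(frame, terms)
  fit <- fit_firth(x, frame$outcome)
  prob <- predict_prob(fit, x)
  thr <- select_threshold(prob, frame$outcome, objective, constraint, min_constraint)
  out <- tibble::tibble(
    area_id = frame$area_id,
    prob = prob,
    predicted = prob >= thr
  )
  attr(out, "threshold") <- thr
  attr(out, "fit") <- fit
  attr(out, "n_predicted") <- sum(out$predicted)
  class(out) <- c("hotspot_forecast", class(out))
  out
}
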