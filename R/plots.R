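#' Plot hotspot classifications as an area-by-year tile map
#'
#' @param object A `hotspot_rates` tibble from [classify_hotspots()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hotspot_rates <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = factor(.data$year), y = .data$area_id,
      fill = .data$hotspot
    )
  ) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.1) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey90", `TRUE` = "firebrick"),
      name = "Hotspot"
    ) +
    ggplot2::labs(x = "Year", y = "Area") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot attainable PPV against the minimum sensitivity threshold
#'
#' Shows, for each grid threshold, the pooled PPV of every candidate model
#' meeting that sensitivity (points) and the optimal model's PPV (line) —
#' the view used to choose a minimum sensitivity threshold.
#'
#' @param object A `hotspot_calibration` from [calibration_step()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hotspot_calibration <- function(object, ...) {
  eligible <- object$grid |>
    dplyr::filter(!is.na(.data$sensitivity) &
      .data$sensitivity >= .data$threshold & !is.na(.data$ppv))
  ggplot2::ggplot(eligible, ggplot2::aes(x = .data$threshold, y = .data$ppv)) +
    ggplot2::geom_point(alpha = 0.25, position = ggplot2::position_jitter(width = 0.01, height = 0)) +
    ggplot2::geom_line(
      data = object$best,
      colour = "firebrick", linewidth = 1
    ) +
    ggplot2::labs(
      x = "Minimum sensitivity threshold",
      y = "Pooled PPV (eligible models)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-repeat stability of the best models
#'
#' Cumulative pooled sensitivity and PPV against the number of CV repeats
#' used, for the ten best models; the heavier line is the optimal model.
#'
#' @param object A `hotspot_selection` from [implementation_step()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hotspot_selection <- function(object, ...) {
  best_ids <- object$best10$model_id
  cum <- object$counts |>
    dplyr::filter(.data$model_id %in% best_ids) |>
    dplyr::summarise(
      TP = sum(.data$TP), FP = sum(.data$FP),
      FN = sum(.data$FN), TN = sum(.data$TN),
      .by = c("model_id", "q")
    ) |>
    dplyr::arrange(.data$model_id, .data$q) |>
    dplyr::mutate(
      dplyr::across(c("TP", "FP", "FN", "TN"), cumsum),
      .by = "model_id"
    ) |>
    dplyr::mutate(
      sensitivity = metric_from_counts(.data$TP, .data$FP, .data$FN, .data$TN, "sensitivity"),
      ppv = metric_from_counts(.data$TP, .data$FP, .data$FN, .data$TN, "ppv")
    ) |>
    tidyr::pivot_longer(c("sensitivity", "ppv"),
      names_to = "metric", values_to = "value"
    )
  optimal_id <- if (!is.null(object$optimal)) object$optimal$model_id else NA
  ggplot2::ggplot(
    cum,
    ggplot2::aes(
      x = .data$q, y = .data$value,
      group = .data$model_id,
      linewidth = .data$model_id == optimal_id
    )
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.3, `TRUE` = 1.1), guide = "none") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::geom_hline(
      yintercept = object$t_star, linetype = "dashed",
      colour = "grey50"
    ) +
    ggplot2::labs(x = "CV repeats pooled", y = "Cumulative pooled metric") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
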