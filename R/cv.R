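#' Maximum training-window width for the rolling-forecast-window layout
#'
#' In the rolling layout, iteration `r` trains on covariates defined in year
#' `l_r = w + r - 1` (the training window spans the `w` years ending there)
#' with the outcome over years `l_r + 1, ..., l_r + m`; the test set is the
#' same frame shifted `m` years forward, so its outcome ends at `l_r + 2m`.
#' With `C` one-year rolls inside a `T`-year series the width is found by
#' scanning widths from `T` downward for the largest `w` whose full layout of
#' year indices fits in `1..T`.
#'
#' @param T Series length in years.
#' @param m Prediction horizon in years.
#' @param C Number of train/test comparisons required.
#' @return The maximum feasible window width (integer, years).
#' @export
max_rolling_window_width <- function(T, m, C) {
  if (T < 1 || m < 1 || C < 1) abort("T, m and C must be >= 1")
  for (w in seq(T, 1)) {
    last_test_outcome <- (w + C - 1) + 2 * m
    if (last_test_outcome <= T) return(as.integer(w))
  }
  abort(paste0(
    "no feasible rolling layout: T = ", T, " is too short for m = ", m,
    " and C = ", C
  ))
}

#' Maximum training-window width for the area-fold time-shifted layout
#'
#' Under the area-partitioned K-fold scheme all folds share a single layout:
#' training covariates in year `l = w` with the outcome over `l+1, ..., l+m`,
#' and the held-out fold tested on covariates from year `l + m` with the
#' outcome ending at `l + 2m`. The number of comparisons equals K and does
#' not consume calendar years, so only `l + 2m <= T` constrains the width.
#'
#' @inheritParams max_rolling_window_width
#' @return The maximum feasible window width (integer, years).
#' @export
max_areafold_window_width <- function(T, m) {
  if (T < 1 || m < 1) abort("T and m must be >= 1")
  for (w in seq(T, 1)) {
    if (w + 2 * m <= T) return(as.integer(w))
  }
  abort(paste0("no feasible layout: need T >= ", 2 * m + 1, ", got T = ", T))
}

#' Partition areas into K cross-validation folds
#'
#' Areas are assigned whole to folds (the partition is over areas, never over
#' years), with fold sizes differing by at most one. With `stratify_on`, the
#' flagged areas (typically the rare positive outcome cases) are spread across
#' folds as evenly as possible before the remaining areas are dealt out.
#'
#' @param areas Character vector of area identifiers.
#' @param K Number of folds (>= 2).
#' @param seed Integer seed making the assignment reproducible.
#' @param stratify_on Optional logical vector aligned with `areas`.
#' @return Tibble `area_id`, `fold`; attribute `seed`.
#' @export
partition_areas <- function(areas, K, seed, stratify_on = NULL) {
  n <- length(areas)
  if (K < 2) abort("K must be >= 2")
  if (K > n) abort(paste0("K = ", K, " exceeds the number of areas (", n, ")"))
  if (!is.null(stratify_on) && length(stratify_on) != n) {
    abort("stratify_on must align with areas")
  }
  with_seed(seed, {
    base <- n %/% K
    extra <- sample(K, n %% K)
    remaining <- base + as.integer(seq_len(K) %in% extra)
    fold_of <- integer(n)
    deal <- function(idx) {
      for (i in sample(idx)) {
        j <- which.max(remaining + runif(K) * 0.5)
        fold_of[i] <<- j
        remaining[j] <<- remaining[j] - 1L
      }
    }
    if (is.null(stratify_on)) {
      deal(seq_len(n))
    } else {
      deal(which(stratify_on))
      deal(which(!stratify_on))
    }
    out <- tibble::tibble(area_id = areas, fold = fold_of)
    attr(out, "seed") <- seed
    out
  })
}

metric_from_counts <- function(TP, FP, FN, TN, metric) {
  num <- switch(metric,
    sensitivity = TP, ppv = TP, specificity = TN, npv = TN,
    accuracy = TP + TN,
    abort(paste0("unknown metric: ", metric))
  )
  den <- switch(metric,
    sensitivity = TP + FN, ppv = TP + FP, specificity = TN + FP,
    npv = TN + FN, accuracy = TP + FP + FN + TN
  )
  ifelse(den == 0, NA_real_, num / den)
}

#' Metric from pooled confusion counts
#'
#' Computes sensitivity, PPV, specificity, NPV or accuracy from (possibly
#' pooled) confusion counts. A zero denominator yields `NA`, never a silent 0.
#'
#' @param counts Data frame (or one-row tibble) with columns `TP`, `FP`,
#'   `FN`, `TN`.
#' @param metric One of `"sensitivity"`, `"ppv"`, `"specificity"`, `"npv"`,
#'   `"accuracy"`.
#' @return Numeric vector, `NA` where the denominator is zero.
#' @export
pooled_metric <- function(counts, metric) {
  metric_from_counts(counts$TP, counts$FP, counts$FN, counts$TN, metric)
}

#' Pool confusion counts across folds and repeats
#'
#' Cell-wise sums of TP/FP/FN/TN, optionally within groups (e.g. per model).
#' Pooling before computing ratio metrics avoids the undefined per-fold
#' estimates that arise with rare outcomes.
#'
#' @param counts Tibble with columns `TP`, `FP`, `FN`, `TN`.
#' @param by Optional character vector of grouping columns.
#' @return Tibble of summed counts (one row per group, or one row).
#' @export
pool_counts <- function(counts, by = NULL) {
  if (is.null(by)) {
    dplyr::summarise(
      counts,
      TP = sum(.data$TP), FP = sum(.data$FP),
      FN = sum(.data$FN), TN = sum(.data$TN)
    )
  } else {
    dplyr::summarise(
      counts,
      TP = sum(.data$TP), FP = sum(.data$FP),
      FN = sum(.data$FN), TN = sum(.data$TN),
      .by = dplyr::all_of(by)
    )
  }
}

#' Select a classification threshold on training predictions
#'
#' Scans every candidate cut-point — midpoints of adjacent sorted unique
#' predicted probabilities plus sentinels below the minimum (predict all
#' positive) and above the maximum (predict none) — classifying
#' `probability >= threshold` as positive. Among cut-points whose constraint
#' metric meets `min_constraint`, the one maximising the objective is chosen;
#' ties prefer the higher secondary metric (sensitivity when the objective is
#' PPV, PPV otherwise), then the largest cut-point (fewest predicted
#' positives). If no cut-point satisfies the constraint, the cut-point
#' maximising the constraint metric is returned instead.
#'
#' @param prob Predicted probabilities on the training data.
#' @param outcome Logical (or 0/1) observed outcomes.
#' @param objective Metric to maximise (default `"ppv"`).
#' @param constraint Metric to bound from below (default `"sensitivity"`).
#' @param min_constraint Minimum required value of the constraint metric.
#' @return The selected threshold (numeric scalar).
#' @export
select_threshold <- function(prob, outcome, objective = "ppv",
                             constraint = "sensitivity", min_constraint = 0) {
  y <- as.numeric(outcome)
  if (length(prob) != length(y)) abort("prob and outcome sizes differ")
  P <- sum(y)
  if (P == 0) warn("no positive outcomes; threshold selection is degenerate")
  v <- sort(unique(prob), decreasing = TRUE)
  r <- length(v)
  lvl <- match(prob, v)
  n_lvl <- tabulate(lvl, nbins = r)
  pos_lvl <- as.numeric(rowsum(y, lvl, reorder = TRUE))
  # k = number of top probability levels classified positive (0 = none)
  TPk <- c(0, cumsum(pos_lvl))
  PPk <- c(0, cumsum(n_lvl))
  thr <- c(v[1] + 1, if (r > 1) (v[-r] + v[-1]) / 2, v[r] - 1)
  FPk <- PPk - TPk
  FNk <- P - TPk
  TNk <- (length(y) - P) - FPk
  obj <- metric_from_counts(TPk, FPk, FNk, TNk, objective)
  con <- metric_from_counts(TPk, FPk, FNk, TNk, constraint)
  secondary_name <- if (objective == "ppv") "sensitivity" else "ppv"
  sec <- metric_from_counts(TPk, FPk, FNk, TNk, secondary_name)
  pick_best <- function(idx, primary) {
    p <- primary[idx]
    p[is.na(p)] <- -Inf
    idx <- idx[p == max(p)]
    s <- sec[idx]
    s[is.na(s)] <- -Inf
    idx <- idx[s == max(s)]
    idx[which.max(thr[idx])]
  }
  feasible <- which(!is.na(con) & con >= min_constraint)
  best <- if (length(feasible) > 0) {
    pick_best(feasible, obj)
  } else {
    pick_best(seq_along(thr), con)
  }
  thr[best]
}

tally_counts <- function(prob, outcome, threshold) {
  pred <- prob >= threshold
  y <- as.logical(outcome)
  c(
    TP = sum(pred & y), FP = sum(pred & !y),
    FN = sum(!pred & y), TN = sum(!pred & !y)
  )
}

check_model_frame <- function(frame) {
  if (!all(c("area_id", "outcome") %in% names(frame))) {
    abort("model frame needs area_id and outcome columns")
  }
  if (anyNA(frame$outcome)) abort("model frame has undefined outcomes")
  frame
}

#' Area-fold cross-validation of one candidate model
#'
#' For each fold k: fit the Firth logistic model on the training-frame rows of
#' areas outside fold k, select a classification threshold on those same
#' training predictions, then apply the fit and threshold to the fold-k areas
#' of the test frame (the same layout shifted `m` years forward) and tally the
#' confusion counts against the test outcomes.
#'
#' @param terms Character vector of term columns defining the model.
#' @param train_frame,test_frame Model frames (see [assemble_model_frame()])
#'   at covariate years `l` and `l + m`, covering the same areas.
#' @param folds Fold assignment from [partition_areas()].
#' @param objective,constraint,min_constraint Passed to [select_threshold()].
#' @return Tibble with one row per fold: `fold`, `threshold`, `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
run_area_fold_cv <- function(terms, train_frame, test_frame, folds,
                             objective = "ppv", constraint = "sensitivity",
                             min_constraint = 0) {
  train_frame <- check_model_frame(train_frame)
  test_frame <- check_model_frame(test_frame)
  Ks <- sort(unique(folds$fold))
  out <- lapply(Ks, function(k) {
    train_areas <- folds$area_id[folds$fold != k]
    test_areas <- folds$area_id[folds$fold == k]
    tr <- train_frame[train_frame$area_id %in% train_areas, ]
    te <- test_frame[test_frame$area_id %in% test_areas, ]
    if (sum(tr$outcome) == 0) {
      warn(paste0("fold ", k, ": training split has no positive outcomes"))
    }
    fit <- fit_firth(design_matrix(tr, terms), tr$outcome)
    p_tr <- predict_prob(fit, design_matrix(tr, terms))
    thr <- select_threshold(p_tr, tr$outcome, objective, constraint, min_constraint)
    p_te <- predict_prob(fit, design_matrix(te, terms))
    cc <- tally_counts(p_te, te$outcome, thr)
    tibble::tibble(
      fold = k, threshold = thr,
      TP = unname(cc["TP"]), FP = unname(cc["FP"]),
      FN = unname(cc["FN"]), TN = unname(cc["TN"])
    )
  })
  dplyr::bind_rows(out)
}

#' Rolling-forecast-window cross-validation of one candidate model
#'
#' The comparison engine: iteration `r` trains on the model frame at covariate
#' year `l_r = w + r - 1` and tests on the frame at year `l_r + m`, using all
#' areas in both roles, rolling forward one year at a time for `C` iterations.
#'
#' @param terms Character vector of term columns defining the model.
#' @param frames Named list of model frames keyed by covariate year (see
#'   [model_frames_by_year()]).
#' @param m Prediction horizon in years.
#' @param C Number of rolling iterations.
#' @param T Series length; used to validate feasibility when `w` is omitted.
#' @param w Training-window width; defaults to the maximum feasible width.
#' @param reselect_threshold Re-select the classification threshold in every
#'   iteration (default) rather than reusing the first iteration's.
#' @inheritParams run_area_fold_cv
#' @return Tibble with one row per iteration: `iteration`, `train_year`,
#'   `test_year`, `threshold`, `TP`, `FP`, `FN`, `TN`.
#' @export
run_rolling_forecast_cv <- function(terms, frames, m, C, T = NULL, w = NULL,
                                    objective = "ppv",
                                    constraint = "sensitivity",
                                    min_constraint = 0,
                                    reselect_threshold = TRUE) {
  if (is.null(w)) {
    if (is.null(T)) abort("supply either w or T")
    w <- max_rolling_window_width(T, m, C)
  }
  if (!is.null(T) && (w + C - 1) + 2 * m > T) {
    abort("infeasible rolling layout: the last test outcome year exceeds T")
  }
  thr <- NULL
  out <- lapply(seq_len(C), function(r) {
    l <- w + r - 1
    tr <- frames[[as.character(l)]]
    te <- frames[[as.character(l + m)]]
    if (is.null(tr) || is.null(te)) {
      abort(paste0("missing model frame for year ", if (is.null(tr)) l else l + m))
    }
    tr <- check_model_frame(tr)
    te <- check_model_frame(te)
    fit <- fit_firth(design_matrix(tr, terms), tr$outcome)
    p_tr <- predict_prob(fit, design_matrix(tr, terms))
    if (reselect_threshold || is.null(thr)) {
      thr <<- select_threshold(p_tr, tr$outcome, objective, constraint, min_constraint)
    }
    p_te <- predict_prob(fit, design_matrix(te, terms))
    cc <- tally_counts(p_te, te$outcome, thr)
    tibble::tibble(
      iteration = r, train_year = l, test_year = l + m, threshold = thr,
      TP = unname(cc["TP"]), FP = unname(cc["FP"]),
      FN = unname(cc["FN"]), TN = unname(cc["TN"])
    )
  })
  dplyr::bind_rows(out)
}

# Effective fold count: reduced to the number of positive training areas when
# positives are scarcer than folds (so every fold's training split can see a
# positive), never below 2.
effective_K <- function(K, n_pos) {
  if (n_pos >= K || n_pos < 2) return(as.integer(K))
  warn(paste0("only ", n_pos, " positive areas; using ", n_pos, "-fold CV"))
  as.integer(n_pos)
}

# Fit every candidate model on every (repeat, fold) split once, caching the
# train/test predicted probabilities and coefficients. Threshold selection and
# tallying are deferred so one set of fits can serve a whole grid of
# sensitivity thresholds.
cv_fit_cache <- function(models, train_frame, test_frame, K, Q, seed,
                         stratify = TRUE) {
  train_frame <- check_model_frame(train_frame)
  test_frame <- check_model_frame(test_frame)
  areas <- train_frame$area_id
  if (!setequal(areas, test_frame$area_id)) {
    abort("train and test frames must cover the same areas")
  }
  test_frame <- test_frame[match(areas, test_frame$area_id), ]
  n_pos <- sum(train_frame$outcome)
  K_eff <- effective_K(K, n_pos)
  all_terms <- unique(unlist(models$terms))
  # one design matrix per frame; per-model fits slice its columns
  x_train <- design_matrix(train_frame, all_terms)
  x_test <- design_matrix(test_frame, all_terms)
  col_idx <- lapply(models$terms, function(tm) c(1L, match(tm, all_terms) + 1L))
  reps <- lapply(seq_len(Q), function(q) {
    folds <- partition_areas(
      areas, K_eff, seed + q,
      stratify_on = if (stratify) train_frame$outcome else NULL
    )
    fold_data <- lapply(sort(unique(folds$fold)), function(k) {
      in_k <- folds$fold == k
      y_tr <- train_frame$outcome[!in_k]
      per_model <- lapply(seq_len(nrow(models)), function(i) {
        x_tr <- x_train[!in_k, col_idx[[i]], drop = FALSE]
        fit <- fit_firth(x_tr, y_tr)
        list(
          train_prob = predict_prob(fit, x_tr),
          test_prob = predict_prob(fit, x_test[in_k, col_idx[[i]], drop = FALSE]),
          coef = fit$coefficients
        )
      })
      list(
        k = k, train_y = y_tr, test_y = test_frame$outcome[in_k],
        models = per_model
      )
    })
    list(q = q, folds = folds, fold_data = fold_data)
  })
  list(models = models, reps = reps, K = K_eff, Q = Q, seed = seed)
}

# Turn a fit cache into confusion counts at a given sensitivity threshold.
tally_cache <- function(cache, objective = "ppv", constraint = "sensitivity",
                        min_constraint = 0) {
  n_models <- nrow(cache$models)
  n_rows <- sum(vapply(cache$reps, function(r) length(r$fold_data), 0L)) * n_models
  out <- matrix(0, nrow = n_rows, ncol = 8)
  colnames(out) <- c("model_id", "q", "k", "threshold", "TP", "FP", "FN", "TN")
  idx <- 0L
  for (rep in cache$reps) {
    for (fd in rep$fold_data) {
      for (i in seq_len(n_models)) {
        pm <- fd$models[[i]]
        thr <- select_threshold(
          pm$train_prob, fd$train_y,
          objective, constraint, min_constraint
        )
        cc <- tally_counts(pm$test_prob, fd$test_y, thr)
        idx <- idx + 1L
        out[idx, ] <- c(cache$models$model_id[i], rep$q, fd$k, thr, cc)
      }
    }
  }
  out <- tibble::as_tibble(out)
  out$model_id <- as.integer(out$model_id)
  out
}

#' Repeated area-fold cross-validation over a set of candidate models
#'
#' Runs `Q` repeats of K-fold area-partitioned, time-shifted cross-validation
#' for every candidate model; repeat `q` partitions the areas with seed
#' `seed + q`. Confusion counts are pooled per model across all folds and
#' repeats before metrics are computed; within-repeat pooled metrics are
#' retained for quantile intervals.
#'
#' @param models A `candidate_models` tibble (or any tibble with `model_id`
#'   and a `terms` list column).
#' @param train_frame,test_frame Model frames at covariate years `l` and
#'   `l + m`.
#' @param K Number of folds (reduced automatically when positive areas are
#'   scarcer than folds).
#' @param Q Number of CV repeats.
#' @param seed Master seed; repeat `q` uses `seed + q`.
#' @param stratify Spread positive areas evenly across folds (default `TRUE`).
#' @inheritParams run_area_fold_cv
#' @return Object of class `repeated_cv`: `counts` (per model, repeat, fold),
#'   `pooled` (per model, with metrics), `per_repeat` (within-repeat pooled
#'   metrics), `mean_or` (mean odds ratio per term per model).
#' @export
repeated_cv <- function(models, train_frame, test_frame, K = 5, Q = 1,
                        seed = 1, objective = "ppv",
                        constraint = "sensitivity", min_constraint = 0,
                        stratify = TRUE) {
  cache <- cv_fit_cache(models, train_frame, test_frame, K, Q, seed, stratify)
  counts <- tally_cache(cache, objective, constraint, min_constraint)
  structure(
    c(
      summarise_counts(counts, models, cache),
      list(
        counts = counts, K = cache$K, Q = Q, seed = seed,
        min_constraint = min_constraint
      )
    ),
    class = "repeated_cv"
  )
}

add_count_metrics <- function(tbl) {
  dplyr::mutate(
    tbl,
    sensitivity = metric_from_counts(.data$TP, .data$FP, .data$FN, .data$TN, "sensitivity"),
    specificity = metric_from_counts(.data$TP, .data$FP, .data$FN, .data$TN, "specificity"),
    ppv = metric_from_counts(.data$TP, .data$FP, .data$FN, .data$TN, "ppv"),
    npv = metric_from_counts(.data$TP, .data$FP, .data$FN, .data$TN, "npv"),
    accuracy = metric_from_counts(.data$TP, .data$FP, .data$FN, .data$TN, "accuracy")
  )
}

summarise_counts <- function(counts, models, cache) {
  pooled <- add_count_metrics(pool_counts(counts, by = "model_id"))
  per_repeat <- add_count_metrics(pool_counts(counts, by = c("model_id", "q")))
  mean_or <- NULL
  if (!is.null(cache)) {
    or_rows <- list()
    for (rep in cache$reps) {
      for (fd in rep$fold_data) {
        for (i in seq_len(nrow(cache$models))) {
          or_rows[[length(or_rows) + 1L]] <- tibble::tibble(
            model_id = cache$models$model_id[i],
            term = names(fd$models[[i]]$coef),
            or = exp(unname(fd$models[[i]]$coef))
          )
        }
      }
    }
    mean_or <- dplyr::bind_rows(or_rows) |>
      dplyr::summarise(mean_or = mean(.data$or), .by = c("model_id", "term"))
  }
  list(pooled = pooled, per_repeat = per_repeat, mean_or = mean_or)
}

#' @export
print.repeated_cv <- function(x, ...) {
  cat("Repeated area-fold CV: ", nrow(x$pooled), " models, K = ", x$K,
    ", Q = ", x$Q, ", min sensitivity = ", x$min_constraint, "\n",
    sep = ""
  )
  print(dplyr::arrange(x$pooled, dplyr::desc(.data$ppv)), n = 5)
  invisible(x)
}
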