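test_that("window widths match the worked layouts", {
  expect_equal(max_rolling_window_width(10, 1, 5), 4L)
  expect_equal(max_rolling_window_width(10, 1, 1), 8L)
  expect_error(max_rolling_window_width(3, 1, 5), "too short")
  expect_equal(max_areafold_window_width(10, 1), 8L)
  expect_error(max_areafold_window_width(10, 5), "T >= 11")
})

test_that("window widths agree with brute-force layout simulation", {
  feasible_rolling <- function(T, m, C, w) {
    ls <- w + seq_len(C) - 1 # training covariate years
    all(ls - w + 1 >= 1) && all(ls + 2 * m <= T)
  }
  for (T in 6:14) {
    for (m in 1:3) {
      for (C in 1:5) {
        widths <- Filter(function(w) feasible_rolling(T, m, C, w), seq_len(T))
        if (length(widths) == 0) {
          expect_error(max_rolling_window_width(T, m, C))
        } else {
          expect_equal(max_rolling_window_width(T, m, C), max(widths))
        }
      }
      if (T >= 2 * m + 1) {
        # area-fold: single layout, test outcome ends at w + 2m
        expect_equal(max_areafold_window_width(T, m), T - 2 * m)
        # the area-fold width exceeds the rolling width by C - 1 whenever
        # both layouts are feasible
        for (C in 1:4) {
          if (T - 2 * m - C + 1 >= 1) {
            expect_equal(
              max_areafold_window_width(T, m) - max_rolling_window_width(T, m, C),
              C - 1
            )
          }
        }
      }
    }
  }
})

test_that("area partitions are reproducible, balanced and stratified", {
  areas <- sprintf("a%02d", 1:23)
  f1 <- partition_areas(areas, 5, seed = 99)
  f2 <- partition_areas(areas, 5, seed = 99)
  expect_equal(f1, f2)
  expect_equal(sort(unique(f1$fold)), 1:5)
  sizes <- table(f1$fold)
  expect_lte(max(sizes) - min(sizes), 1)

  # leave-one-area-out
  loo <- partition_areas(areas, length(areas), seed = 1)
  expect_equal(sort(table(loo$fold)), sort(table(1:23)))

  # balance holds over many random shapes
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    K <- sample(2:6, 1)
    f <- partition_areas(sprintf("x%d", 1:n), K, seed = rep)
    expect_lte(diff(range(table(factor(f$fold, levels = 1:K)))), 1)
    expect_equal(nrow(f), n)
  }

  # stratification spreads positives across folds
  pos <- rep(FALSE, 20)
  pos[c(1, 5, 9, 13, 17)] <- TRUE
  fs <- partition_areas(sprintf("a%d", 1:20), 5, seed = 2, stratify_on = pos)
  pos_per_fold <- table(fs$fold[pos[match(fs$area_id, sprintf("a%d", 1:20))]])
  expect_lte(max(pos_per_fold), 1)
  expect_error(partition_areas(areas, 30, seed = 1), "exceeds")
})

test_that("threshold selection matches an exhaustive scan oracle", {
  oracle_select <- function(prob, y, objective, constraint, t) {
    u <- sort(unique(prob))
    cand <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
    eval_at <- function(thr, metric) {
      pred <- prob >= thr
      tp <- sum(pred & y)
      fp <- sum(pred & !y)
      fn <- sum(!pred & y)
      tn <- sum(!pred & !y)
      num <- switch(metric,
        sensitivity = tp, ppv = tp, specificity = tn,
        npv = tn, accuracy = tp + tn
      )
      den <- switch(metric,
        sensitivity = tp + fn, ppv = tp + fp, specificity = tn + fp,
        npv = tn + fn, accuracy = tp + fp + fn + tn
      )
      if (den == 0) NA_real_ else num / den
    }
    con <- sapply(cand, eval_at, metric = constraint)
    obj <- sapply(cand, eval_at, metric = objective)
    sec_name <- if (objective == "ppv") "sensitivity" else "ppv"
    sec <- sapply(cand, eval_at, metric = sec_name)
    feas <- which(!is.na(con) & con >= t)
    score <- function(v) ifelse(is.na(v), -Inf, v)
    pick <- function(idx, primary) {
      idx <- idx[score(primary[idx]) == max(score(primary[idx]))]
      idx <- idx[score(sec[idx]) == max(score(sec[idx]))]
      idx[which.max(cand[idx])]
    }
    if (length(feas) > 0) cand[pick(feas, obj)] else cand[pick(seq_along(cand), con)]
  }
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    prob <- round(runif(n), 2) # ties on purpose
    y <- rbinom(n, 1, 0.4) == 1
    if (sum(y) == 0) y[1] <- TRUE
    objective <- sample(c("ppv", "sensitivity", "accuracy"), 1)
    t <- sample(c(0, 0.25, 0.5, 0.8), 1)
    got <- select_threshold(prob, y, objective, "sensitivity", t)
    expect_equal(got, oracle_select(prob, y, objective, "sensitivity", t))
  }
})

test_that("threshold selection handles separable and degenerate inputs", {
  prob <- c(0.1, 0.2, 0.8, 0.9)
  y <- c(FALSE, FALSE, TRUE, TRUE)
  thr <- select_threshold(prob, y, "ppv", "sensitivity", 1)
  expect_equal(sum(prob >= thr & y), 2)
  expect_equal(sum(prob >= thr & !y), 0)
  # returns the largest cut among perfect ones
  expect_equal(thr, 0.5)

  # constraint 0: the PPV-maximal cut keeps only positives above it
  mixed <- c(0.1, 0.4, 0.6, 0.7, 0.95)
  ym <- c(FALSE, TRUE, FALSE, TRUE, TRUE)
  thr2 <- select_threshold(mixed, ym, "ppv", "sensitivity", 0)
  expect_true(all(ym[mixed >= thr2]))

  # unattainable constraint falls back to maximising the constraint metric
  yhard <- c(TRUE, FALSE, TRUE, FALSE)
  phard <- c(0.1, 0.9, 0.2, 0.8)
  thr3 <- select_threshold(phard, yhard, "ppv", "sensitivity", 0.99)
  expect_equal(sum(phard >= thr3 & yhard), 2) # all positives captured
})

test_that("area-fold CV counts are conservative and hand-traceable", {
  fr_tr <- toy_frame(n = 24, seed = 61)
  fr_te <- toy_frame(n = 24, seed = 62)
  folds <- partition_areas(fr_tr$area_id, 2, seed = 5, stratify_on = fr_tr$outcome)
  got <- run_area_fold_cv("x", fr_tr, fr_te, folds)
  expect_equal(nrow(got), 2)
  expect_equal(sum(got$TP + got$FP + got$FN + got$TN), 24)

  # manual trace of the same protocol
  for (k in 1:2) {
    tr <- fr_tr[fr_tr$area_id %in% folds$area_id[folds$fold != k], ]
    te <- fr_te[fr_te$area_id %in% folds$area_id[folds$fold == k], ]
    fit <- fit_firth(design_matrix(tr, "x"), tr$outcome)
    thr <- select_threshold(
      predict_prob(fit, design_matrix(tr, "x")), tr$outcome,
      "ppv", "sensitivity", 0
    )
    pred <- predict_prob(fit, design_matrix(te, "x")) >= thr
    expect_equal(got$TP[got$fold == k], sum(pred & te$outcome))
    expect_equal(got$TN[got$fold == k], sum(!pred & !te$outcome))
  }

  # a deterministic outcome reproduced by the model leaves only TP and TN
  sep <- sep_frame(n = 30, seed = 63)
  folds2 <- partition_areas(sep$area_id, 3, seed = 7, stratify_on = sep$outcome)
  clean <- run_area_fold_cv("x", sep, sep, folds2)
  expect_equal(sum(clean$FP) + sum(clean$FN), 0)
})

test_that("rolling-forecast CV rolls through the published year indices", {
  frames <- lapply(1:10, function(l) toy_frame(n = 20, seed = 100 + l))
  names(frames) <- 1:10
  got <- run_rolling_forecast_cv("x", frames, m = 1, C = 5, T = 10)
  expect_equal(got$train_year, 4:8) # first training covariate year is 4
  expect_equal(got$test_year, 5:9) # first test covariate year 5, outcome 6
  expect_equal(nrow(got), 5)
  expect_true(all(got$TP + got$FP + got$FN + got$TN == 20))

  # C = 1 is a single train/test evaluation
  one <- run_rolling_forecast_cv("x", frames, m = 1, C = 1, T = 10)
  expect_equal(nrow(one), 1)
  tr <- frames[["8"]]
  te <- frames[["9"]]
  fit <- fit_firth(design_matrix(tr, "x"), tr$outcome)
  thr <- select_threshold(
    predict_prob(fit, design_matrix(tr, "x")), tr$outcome,
    "ppv", "sensitivity", 0
  )
  cc <- predict_prob(fit, design_matrix(te, "x")) >= thr
  expect_equal(one$TP, sum(cc & te$outcome))
  expect_error(
    run_rolling_forecast_cv("x", frames, m = 1, C = 5, T = 10, w = 6),
    "infeasible"
  )
})

test_that("count pooling and pooled metrics follow the formulas", {
  counts <- tibble::tibble(
    TP = c(3, 1, 0), FP = c(1, 2, 0), FN = c(2, 0, 1), TN = c(10, 12, 15)
  )
  pooled <- pool_counts(counts)
  expect_equal(pooled$TP, 4)
  expect_equal(pool_counts(counts[c(3, 1, 2), ]), pooled) # order invariance
  expect_equal(pool_counts(counts[1, ]), counts[1, ]) # identity on one row

  expect_equal(pooled_metric(tibble::tibble(TP = 6, FP = 16, FN = 0, TN = 0), "ppv"), 6 / 22)
  expect_true(is.na(pooled_metric(tibble::tibble(TP = 0, FP = 0, FN = 0, TN = 5), "sensitivity")))
  expect_true(is.na(pooled_metric(tibble::tibble(TP = 0, FP = 0, FN = 2, TN = 5), "ppv")))
  set.seed(66)
  for (rep in 1:10) {
    cc <- tibble::tibble(
      TP = rpois(1, 5), FP = rpois(1, 5), FN = rpois(1, 5), TN = rpois(1, 20)
    )
    expect_equal(pooled_metric(cc, "sensitivity"), cc$TP / (cc$TP + cc$FN))
    expect_equal(pooled_metric(cc, "specificity"), cc$TN / (cc$TN + cc$FP))
    expect_equal(pooled_metric(cc, "npv"), cc$TN / (cc$TN + cc$FN))
    expect_equal(
      pooled_metric(cc, "accuracy"),
      (cc$TP + cc$TN) / sum(cc$TP, cc$FP, cc$FN, cc$TN)
    )
  }
})

test_that("repeated CV pools counts across repeats and conserves areas", {
  fr_tr <- toy_frame(n = 30, seed = 71, noise = 0.5)
  fr_te <- toy_frame(n = 30, seed = 72, noise = 0.5)
  models <- tibble::tibble(
    model_id = 1:2, terms = list("x", c("x", "z")), n_terms = c(1L, 2L)
  )
  cv <- suppressWarnings(
    repeated_cv(models, fr_tr, fr_te, K = 3, Q = 4, seed = 10)
  )
  # every (model, repeat, fold) row covers its fold; repeats cover all areas
  per_rep <- cv$counts |>
    dplyr::summarise(
      n = sum(TP + FP + FN + TN),
      .by = c(model_id, q)
    )
  expect_true(all(per_rep$n == 30))
  expect_equal(
    cv$pooled$TP + cv$pooled$FP + cv$pooled$FN + cv$pooled$TN,
    rep(30 * 4, 2)
  )
  # pooled counts equal the sum of per-repeat pooled counts
  expect_equal(
    dplyr::arrange(pool_counts(cv$per_repeat, by = "model_id"), model_id)$TP,
    dplyr::arrange(cv$pooled, model_id)$TP
  )
  # Q = 1 reduces to a single-run area-fold CV with the same partition
  cv1 <- suppressWarnings(
    repeated_cv(models[1, ], fr_tr, fr_te, K = 3, Q = 1, seed = 10)
  )
  folds <- partition_areas(fr_tr$area_id, 3,
    seed = 11,
    stratify_on = fr_tr$outcome
  )
  direct <- run_area_fold_cv("x", fr_tr, fr_te, folds)
  expect_equal(
    dplyr::arrange(cv1$counts, k)[c("TP", "FP", "FN", "TN")],
    dplyr::arrange(direct, fold)[c("TP", "FP", "FN", "TN")]
  )
})

test_that("a deterministic classifier gives identical per-repeat metrics", {
  fr <- sep_frame(n = 30, seed = 73) # binary covariate: the rule is fixed
  models <- tibble::tibble(model_id = 1L, terms = list("x"), n_terms = 1L)
  cv <- suppressWarnings(repeated_cv(models, fr, fr, K = 3, Q = 5, seed = 4))
  expect_equal(length(unique(cv$per_repeat$accuracy)), 1)
})

test_that("training-side attainable PPV is non-increasing in the floor", {
  set.seed(77)
  prob <- runif(60)
  y <- rbinom(60, 1, plogis(3 * (prob - 0.5))) == 1
  achieved <- sapply(seq(0, 0.9, by = 0.1), function(t) {
    thr <- select_threshold(prob, y, "ppv", "sensitivity", t)
    pred <- prob >= thr
    sens <- sum(pred & y) / sum(y)
    if (sens < t) NA_real_ else sum(pred & y) / max(1, sum(pred))
  })
  achieved <- achieved[!is.na(achieved)]
  expect_true(all(diff(achieved) <= 1e-12))
})
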