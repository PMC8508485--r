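#' Enumerate the constrained all-subset candidate model space
#'
#' Generates every non-empty subset of catalogue terms with at most
#' `max_terms` members that respects the marginality principle (a quadratic
#' term requires its linear parent; an interaction requires both main-effect
#' parents) and the exclusivity groups (at most one term per group, e.g. at
#' most one SEIFA index and at most one GP-accessibility measure). Each term
#' counts as one toward the size cap; the intercept-only model is excluded.
#'
#' Enumeration proceeds by ordered backtracking: subsets are grown by
#' appending terms with a strictly increasing catalogue index, pruning on the
#' size cap and group constraints as the set grows, and checking marginality
#' on the completed set. The result is deterministic: ordered by model size,
#' then lexicographically by the term labels.
#'
#' @param catalogue A catalogue tibble (see [default_catalogue()]).
#' @param max_terms Maximum number of terms per model (default 5).
#' @return Tibble of class `candidate_models`: `model_id`, `n_terms`,
#'   `terms` (list column of character vectors), `label`.
#' @export
enumerate_candidate_models <- function(catalogue, max_terms = 5) {
  catalogue <- validate_catalogue(catalogue)
  if (max_terms < 1) abort("max_terms must be >= 1")
  nm <- catalogue$name
  n <- length(nm)
  grp <- catalogue$group
  parents <- catalogue$parents
  parent_idx <- lapply(parents, function(p) match(p, nm))

  satisfies_marginality <- function(idx) {
    for (i in idx) {
      pi <- parent_idx[[i]]
      if (length(pi) > 0 && !all(pi %in% idx)) return(FALSE)
    }
    TRUE
  }

  results <- vector("list", 2048)
  n_found <- 0L
  grow <- function(idx, used_groups) {
    if (length(idx) > 0 && satisfies_marginality(idx)) {
      n_found <<- n_found + 1L
      if (n_found > length(results)) length(results) <<- 2L * n_found
      results[[n_found]] <<- idx
    }
    if (length(idx) == max_terms) return(invisible())
    start <- if (length(idx) == 0) 1L else max(idx) + 1L
    if (start > n) return(invisible())
    for (j in start:n) {
      g <- grp[j]
      if (!is.na(g) && g %in% used_groups) next
      grow(c(idx, j), if (is.na(g)) used_groups else c(used_groups, g))
    }
  }
  grow(integer(0), character(0))
  results <- results[seq_len(n_found)]

  models <- tibble::tibble(
    terms = lapply(results, function(idx) nm[idx]),
    n_terms = lengths(results)
  ) |>
    dplyr::mutate(label = purrr::map_chr(.data$terms, paste, collapse = " + ")) |>
    dplyr::arrange(.data$n_terms, .data$label) |>
    dplyr::mutate(model_id = dplyr::row_number(), .before = 1)
  class(models) <- c("candidate_models", class(models))
  models
}

#' Check a single term set against the catalogue constraints
#'
#' @param terms Character vector of term names.
#' @param catalogue A catalogue tibble.
#' @param max_terms Size cap.
#' @return `TRUE` when the set is a valid candidate model.
#' @export
is_valid_model <- function(terms, catalogue, max_terms = 5) {
  if (length(terms) == 0 || length(terms) > max_terms) return(FALSE)
  if (anyDuplicated(terms) > 0) return(FALSE)
  if (!all(terms %in% catalogue$name)) return(FALSE)
  rows <- match(terms, catalogue$name)
  for (i in rows) {
    pr <- catalogue$parents[[i]]
    if (length(pr) > 0 && !all(pr %in% terms)) return(FALSE)
  }
  grp <- catalogue$group[rows]
  grp <- grp[!is.na(grp)]
  !anyDuplicated(grp)
}
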