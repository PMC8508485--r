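# Small in-code fixtures and independent oracles shared across test files.

# A tiny fully-crossed panel: `events` and `population` are functions of
# (area index, stratum index) so fixtures are deterministic and transparent.
make_panel <- function(n_areas, strata, events_fn, pop_fn, years = 1L) {
  grid <- expand.grid(
    area_id = sprintf("a%d", seq_len(n_areas)),
    year = years,
    stratum_id = strata,
    stringsAsFactors = FALSE
  )
  grid$events <- mapply(
    events_fn,
    match(grid$area_id, sprintf("a%d", seq_len(n_areas))),
    match(grid$stratum_id, strata)
  )
  grid$population <- mapply(
    pop_fn,
    match(grid$area_id, sprintf("a%d", seq_len(n_areas))),
    match(grid$stratum_id, strata)
  )
  tibble::as_tibble(grid)
}

equal_weights <- function(strata, w = 1) {
  tibble::tibble(stratum_id = strata, weight = rep(w, length(strata)))
}

# Loop-based substitution oracle: cell-by-cell replacement from original totals.
oracle_substitute <- function(panel, threshold) {
  out <- panel
  for (r in seq_len(nrow(out))) {
    if (panel$population[r] < threshold) {
      sel <- panel$stratum_id == panel$stratum_id[r] & panel$year == panel$year[r]
      out$events[r] <- sum(panel$events[sel])
      out$population[r] <- sum(panel$population[sel])
    }
  }
  out
}

# Direct spreadsheet-style evaluation of the standardised rate and variance.
oracle_assr <- function(events, pops, w) {
  list(
    assr = sum(w * events / pops) / sum(w),
    variance = sum(w^2 * events / pops^2) / sum(w)^2
  )
}

# Exact Poisson limits from gamma quantiles.
oracle_poisson_ci <- function(o, level = 0.95) {
  a <- (1 - level) / 2
  c(
    lower = if (o == 0) 0 else stats::qgamma(a, o),
    upper = stats::qgamma(1 - a, o + 1)
  )
}

# Power-set enumeration oracle: flat generation + an independent constraint
# check written against the catalogue directly.
oracle_enumerate <- function(catalogue, max_terms = 5) {
  nm <- catalogue$name
  ok <- list()
  for (size in seq_len(min(max_terms, length(nm)))) {
    sets <- utils::combn(nm, size, simplify = FALSE)
    for (s in sets) {
      valid <- TRUE
      for (t in s) {
        i <- match(t, nm)
        pr <- catalogue$parents[[i]]
        if (length(pr) > 0 && !all(pr %in% s)) valid <- FALSE
      }
      grp <- catalogue$group[match(s, nm)]
      grp <- grp[!is.na(grp)]
      if (anyDuplicated(grp) > 0) valid <- FALSE
      if (valid) ok[[length(ok) + 1]] <- sort(s)
    }
  }
  ok
}

# Independent penalized-likelihood objective and gradient for the Firth
# oracle: BFGS maximisation from zero, no scoring iterations involved.
oracle_firth_obj <- function(beta, x, y) {
  eta <- drop(x %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  info <- t(x) %*% (x * w)
  sum(y * eta - log1p(exp(eta))) +
    0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
}

oracle_firth_grad <- function(beta, x, y) {
  eta <- drop(x %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  info <- t(x) %*% (x * w)
  hat <- rowSums((x %*% solve(info)) * x) * w
  drop(t(x) %*% (y - p + hat * (0.5 - p)))
}

oracle_firth_fit <- function(x, y) {
  opt <- stats::optim(
    rep(0, ncol(x)),
    fn = function(b) -oracle_firth_obj(b, x, y),
    gr = function(b) -oracle_firth_grad(b, x, y),
    method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-15)
  )
  opt$par
}

# Random boolean hotspot matrix in long form.
random_hotspots <- function(n_areas, n_years, p = 0.3) {
  tidyr::expand_grid(
    area_id = sprintf("a%d", seq_len(n_areas)),
    year = seq_len(n_years)
  ) |>
    dplyr::mutate(hotspot = stats::runif(dplyr::n()) < p)
}

# A small linearly-separable model frame for CV plumbing tests.
toy_frame <- function(n = 40, seed = 1, noise = 0) {
  set.seed(seed)
  x <- stats::rnorm(n)
  outcome <- x + stats::rnorm(n, 0, max(noise, 1e-9)) > 0.8
  tibble::tibble(
    area_id = sprintf("a%02d", seq_len(n)),
    outcome = outcome,
    x = x,
    z = stats::rnorm(n)
  )
}

# A frame whose outcome is a deterministic function of a binary covariate:
# every fit separates it perfectly and the midpoint threshold is exact.
sep_frame <- function(n = 30, seed = 1) {
  set.seed(seed)
  x <- rep(0:1, length.out = n)[sample(n)]
  tibble::tibble(
    area_id = sprintf("a%02d", seq_len(n)),
    outcome = x == 1,
    x = x,
    z = stats::rnorm(n)
  )
}

# A catalogue of k unconstrained main effects named m1..mk.
plain_catalogue <- function(k) {
  dplyr::bind_rows(lapply(sprintf("m%d", seq_len(k)), catalogue_term))
}
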