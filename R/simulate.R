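#' Configuration for the synthetic panel generator
#'
#' Describes a synthetic study region shaped like the administrative panels
#' the method targets: `n_areas` small areas observed over `n_years` years in
#' age-band-by-sex strata, with Poisson admission counts whose area-level
#' log-rate carries an AR(1) random effect (persistence with regression to
#' the mean) plus fixed covariate effects.
#'
#' Defaults mirror a metropolitan-scale panel: 150 areas, 13 years, 18
#' five-year age bands by 2 sexes, mean area population 10,000, stratum
#' baseline rates rising with age to an overall admission rate of roughly 4
#' per 1,000 person-years, log-rate effect standard deviation 0.4 and AR(1)
#' persistence 0.8.
#'
#' @param n_areas Number of areas.
#' @param n_years Number of years.
#' @param n_age_bands Number of five-year age bands (18 = 0-4 through 85+).
#' @param baseline_rates Optional per-stratum baseline admission rates; the
#'   default rises exponentially with age and is slightly higher for males.
#' @param mean_population Mean area population.
#' @param population_sd_log Log-scale standard deviation of area populations.
#' @param sigma Standard deviation of the area log-rate random effect.
#' @param rho AR(1) persistence of the log-rate effect, in [0, 1).
#' @param gamma Named vector of log-rate effects per standardised covariate
#'   column (names must match [generate_covariates()] columns). Use `NULL`
#'   for no covariate signal.
#' @param zero_share Share of areas with an exact zero Aboriginal percentage.
#' @param seed Master seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_areas = 150, n_years = 13, n_age_bands = 18,
                             baseline_rates = NULL, mean_population = 10000,
                             population_sd_log = 0.35, sigma = 0.4, rho = 0.8,
                             gamma = c(
                               seifa_irsd = -0.3, pct_aboriginal = 0.25,
                               ed_distance = 0.15
                             ),
                             zero_share = 0.1, seed = 1) {
  if (n_areas < 2 || n_years < 1 || n_age_bands < 1) {
    abort("n_areas, n_years and n_age_bands must be positive (n_areas >= 2)")
  }
  if (sigma < 0) abort("sigma must be >= 0")
  if (rho < 0 || rho >= 1) abort("rho must be in [0, 1)")
  if (mean_population <= 0) abort("mean_population must be positive")
  ages <- seq(0, by = 5, length.out = n_age_bands)
  age_labels <- ifelse(
    seq_along(ages) == n_age_bands,
    paste0(ages, "+"),
    paste0(ages, "-", ages + 4)
  )
  strata <- tidyr::expand_grid(age = age_labels, sex = c("F", "M")) |>
    dplyr::mutate(
      stratum_id = paste(.data$age, .data$sex, sep = "_"),
      band = match(.data$age, age_labels)
    )
  # population share decays with age; rates rise with age, higher for males
  share <- exp(-0.15 * (strata$band - 1))
  strata$pop_share <- 0.5 * share / sum(share)
  if (is.null(baseline_rates)) {
    baseline_rates <- 5e-4 * exp(0.25 * (strata$band - 1)) *
      ifelse(strata$sex == "M", 1.1, 0.9)
  }
  if (length(baseline_rates) != nrow(strata)) {
    abort("baseline_rates must have one value per stratum")
  }
  if (any(baseline_rates < 0)) abort("baseline rates must be >= 0")
  strata$rate <- baseline_rates
  structure(
    list(
      n_areas = n_areas, n_years = n_years, strata = strata,
      mean_population = mean_population,
      population_sd_log = population_sd_log,
      sigma = sigma, rho = rho, gamma = gamma,
      zero_share = zero_share, seed = seed
    ),
    class = "synthetic_config"
  )
}

#' Synthetic area-level covariate table
#'
#' Generates covariates shaped like the real candidate predictors: four
#' correlated socio-economic index scores (sharing a common factor),
#' a zero-inflated right-skewed Aboriginal percentage, percentages aged 75+
#' and male (the latter jittered per year), a rurality indicator, strictly
#' positive right-skewed distances to the nearest emergency department and
#' general practice, a gravity-style GP accessibility index, and two
#' pure-noise columns. All covariates except the per-year jitter are constant
#' over time.
#'
#' @param config A `synthetic_config`.
#' @return Tibble with `area_id`, `year` and one column per raw covariate.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  J <- config$n_areas
  with_seed(config$seed + 1000L, {
    area_id <- sprintf("A%03d", seq_len(J))
    ses <- rnorm(J)
    mix <- function(loading) {
      loading * ses + sqrt(1 - loading^2) * rnorm(J)
    }
    rurality <- rbinom(J, 1, 0.3)
    ed_distance <- exp(rnorm(J, log(4), 0.8) + 1.2 * rurality)
    gp_distance <- exp(0.8 * log(ed_distance) + rnorm(J, 0, 0.4))
    base <- tibble::tibble(
      area_id = area_id,
      seifa_irsd = 1000 + 80 * mix(0.85),
      seifa_irsad = 1000 + 85 * mix(0.80),
      seifa_ieo = 1000 + 90 * mix(0.75),
      seifa_ier = 1000 + 80 * mix(0.70),
      pct_aboriginal = ifelse(
        runif(J) < config$zero_share, 0,
        pmin(60, exp(rnorm(J, log(1.5), 0.9) - 0.4 * ses))
      ),
      pct_75plus = pmax(0.5, 7 + 2.5 * rnorm(J)),
      rurality = rurality,
      ed_distance = ed_distance,
      gp_distance = gp_distance,
      gp_access_index = exp(-0.5 * log(gp_distance) + rnorm(J, 0, 0.5)),
      noise1 = rnorm(J),
      noise2 = rnorm(J)
    )
    pct_male_base <- 50 + 1.2 * rnorm(J)
    tidyr::expand_grid(year = seq_len(config$n_years), base) |>
      dplyr::mutate(
        pct_male = rep(pct_male_base, config$n_years) +
          rnorm(J * config$n_years, 0, 0.2)
      ) |>
      dplyr::relocate("area_id", "year")
  })
}

#' Standard population implied by a synthetic configuration
#'
#' @param config A `synthetic_config`.
#' @return Tibble `stratum_id`, `weight` (the generator's age-sex structure
#'   scaled to one million persons).
#' @export
generate_standard_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tibble::tibble(
    stratum_id = config$strata$stratum_id,
    weight = config$strata$pop_share * 1e6
  )
}

#' Generate a synthetic stratified panel with known latent structure
#'
#' Event counts are drawn as
#' `O ~ Poisson(n * baseline_rate * exp(u_jl + x_j' gamma))`, where `u` is a
#' stationary area-level AR(1) process (`u_{j,l+1} = rho u_jl + eps`,
#' marginal standard deviation `sigma`) and the covariate signal applies
#' `gamma` to z-scored covariate columns. The latent effects and `gamma` are
#' returned so recovery can be tested.
#'
#' @param config A `synthetic_config`.
#' @return List of class `synthetic_panel`: `panel` (stratified long tibble),
#'   `covariates`, `standard_population`, `latent` (tibble `area_id`, `year`,
#'   `u`), `gamma`, `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  covariates <- generate_covariates(config)
  J <- config$n_areas
  L <- config$n_years
  strata <- config$strata
  with_seed(config$seed + 2000L, {
    area_id <- sprintf("A%03d", seq_len(J))
    total_pop <- rlnorm(
      J,
      log(config$mean_population) - config$population_sd_log^2 / 2,
      config$population_sd_log
    )
    # covariate signal on the log-rate scale
    eta_cov <- rep(0, J)
    if (!is.null(config$gamma) && length(config$gamma) > 0) {
      cov1 <- covariates[covariates$year == 1, ]
      cov1 <- cov1[match(area_id, cov1$area_id), ]
      for (nm in names(config$gamma)) {
        if (!nm %in% names(cov1)) abort(paste0("gamma names unknown covariate: ", nm))
        v <- cov1[[nm]]
        z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
        eta_cov <- eta_cov + config$gamma[[nm]] * z
      }
    }
    u <- matrix(0, nrow = J, ncol = L)
    if (config$sigma > 0) {
      u[, 1] <- rnorm(J, 0, config$sigma)
      if (L > 1) {
        innov_sd <- config$sigma * sqrt(1 - config$rho^2)
        for (l in 2:L) {
          u[, l] <- config$rho * u[, l - 1] + rnorm(J, 0, innov_sd)
        }
      }
    }
    cells <- tidyr::expand_grid(
      area_idx = seq_len(J),
      year = seq_len(L),
      stratum_idx = seq_len(nrow(strata))
    ) |>
      dplyr::mutate(
        area_id = area_id[.data$area_idx],
        stratum_id = strata$stratum_id[.data$stratum_idx],
        population = round(
          total_pop[.data$area_idx] * strata$pop_share[.data$stratum_idx]
        ),
        mu = .data$population * strata$rate[.data$stratum_idx] *
          exp(u[cbind(.data$area_idx, .data$year)] + eta_cov[.data$area_idx]),
        events = rpois(dplyr::n(), .data$mu)
      )
    panel <- cells |>
      dplyr::select("area_id", "year", "stratum_id", "events", "population")
    latent <- tidyr::expand_grid(area_idx = seq_len(J), year = seq_len(L)) |>
      dplyr::mutate(
        area_id = area_id[.data$area_idx],
        u = u[cbind(.data$area_idx, .data$year)]
      ) |>
      dplyr::select("area_id", "year", "u")
    structure(
      list(
        panel = panel,
        covariates = covariates,
        standard_population = generate_standard_population(config),
        latent = latent,
        gamma = config$gamma,
        config = config
      ),
      class = "synthetic_panel"
    )
  })
}
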