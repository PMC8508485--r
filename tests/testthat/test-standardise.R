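test_that("small-stratum substitution replaces cells with all-area totals", {
  strata <- "s1"
  panel <- make_panel(2, strata,
    events_fn = function(a, s) c(3L, 40L)[a],
    pop_fn = function(a, s) c(10, 500)[a]
  )
  # threshold 0: nothing is below 0
  expect_equal(substitute_small_strata(panel, 0), validate_panel(panel))
  out <- substitute_small_strata(panel, 30)
  small <- out[out$area_id == "a1", ]
  expect_equal(small$events, 43L)
  expect_equal(small$population, 510)
  expect_equal(out[out$area_id == "a2", ], validate_panel(panel)[panel$area_id == "a2", ])
})

test_that("substitution matches the cell-by-cell oracle and is idempotent", {
  set.seed(42)
  strata <- c("s1", "s2")
  panel <- make_panel(3, strata,
    events_fn = function(a, s) rpois(1, 5),
    pop_fn = function(a, s) sample(c(5, 20, 100), 1)
  )
  out <- substitute_small_strata(panel, 30)
  oracle <- oracle_substitute(panel, 30)
  expect_equal(out$events, oracle$events)
  expect_equal(out$population, oracle$population)
  # all-area totals exceed the threshold here, so a second pass changes nothing
  expect_equal(substitute_small_strata(out, 30), out)
})

test_that("panel validation rejects structural errors", {
  strata <- c("s1", "s2")
  panel <- make_panel(2, strata, function(a, s) 1L, function(a, s) 100)
  expect_error(validate_panel(panel[-1, ]), "coverage")
  expect_error(validate_panel(rbind(panel, panel[1, ])), "duplicate")
  bad <- panel
  bad$events[1] <- -1L
  expect_error(validate_panel(bad), "negative")
})

test_that("standardised rate and variance follow the direct formulas", {
  # single stratum: weights cancel
  p1 <- make_panel(1, "s1", function(a, s) 50L, function(a, s) 1000)
  r1 <- compute_assr(p1, equal_weights("s1", 7))
  expect_equal(r1$assr, 0.05)
  expect_equal(r1$variance, 50 / 1000^2)

  # zero events everywhere
  p0 <- make_panel(1, c("s1", "s2"), function(a, s) 0L, function(a, s) 100)
  r0 <- compute_assr(p0, equal_weights(c("s1", "s2")))
  expect_equal(r0$assr, 0)
  expect_equal(r0$variance, 0)

  # three strata, unequal weights, vs spreadsheet-style oracle
  ev <- c(12L, 30L, 7L)
  pop <- c(400, 900, 150)
  w <- c(0.2, 0.5, 0.3)
  p3 <- make_panel(1, c("s1", "s2", "s3"),
    function(a, s) ev[s], function(a, s) pop[s]
  )
  r3 <- compute_assr(p3, tibble::tibble(stratum_id = c("s1", "s2", "s3"), weight = w))
  expect_equal(r3$assr, oracle_assr(ev, pop, w)$assr)
  expect_equal(r3$variance, oracle_assr(ev, pop, w)$variance)

  # zero population names the stratum
  pz <- make_panel(1, c("s1", "s2"), function(a, s) 0L, function(a, s) c(100, 0)[s])
  expect_error(compute_assr(pz, equal_weights(c("s1", "s2"))), "s2")
})

test_that("Byar limits are accurate against exact Poisson limits", {
  expect_equal(byar_limits(0)$lower, 0)
  for (o in c(10, 25, 100, 400, 1000)) {
    b <- byar_limits(o, z = 1.959964)
    exact <- oracle_poisson_ci(o)
    expect_lt(abs(b$lower - exact["lower"]) / exact["lower"], 0.01)
    expect_lt(abs(b$upper - exact["upper"]) / exact["upper"], 0.01)
  }
})

test_that("Byar limits straddle the count as z tends to zero", {
  for (o in c(5, 10, 50)) {
    b <- byar_limits(o, z = 1e-9)
    expect_equal(b$lower, o * (1 - 1 / (9 * o))^3, tolerance = 1e-6)
    expect_equal(b$upper, (o + 1) * (1 - 1 / (9 * (o + 1)))^3, tolerance = 1e-6)
    expect_lt(b$lower, o)
    expect_gt(b$upper, o)
  }
})

test_that("all-area summary pools counts and reproduces single-area rates", {
  strata <- c("s1", "s2")
  w <- equal_weights(strata)
  one <- make_panel(1, strata, function(a, s) c(5L, 9L)[s], function(a, s) 100)
  s1 <- all_area_summary(one, w)
  expect_equal(s1$all_area_assr, compute_assr(one, w)$assr)
  expect_equal(s1$variance, s1$events)

  # two identical areas: pooling leaves the rate unchanged
  two <- make_panel(2, strata, function(a, s) c(5L, 9L)[s], function(a, s) 100)
  expect_equal(
    all_area_summary(two, w)$all_area_assr,
    compute_assr(two, w, area = "a1")$assr
  )

  set.seed(7)
  rnd <- make_panel(5, strata,
    function(a, s) rpois(1, 20), function(a, s) 50 + runif(1, 0, 100)
  )
  expect_equal(all_area_summary(rnd, w)$events, sum(rnd$events))
  expect_error(all_area_summary(rnd, w, year = 99), "no rows")
})

test_that("area confidence limits follow the variance-ratio construction", {
  # 3 areas, 1 stratum, events (100, 10, 10), populations 1000
  ev <- c(100L, 10L, 10L)
  panel <- make_panel(3, "s1", function(a, s) ev[a], function(a, s) 1000)
  w <- equal_weights("s1")
  hs <- classify_hotspots(panel, w)
  a1 <- hs[hs$area_id == "a1", ]
  expected_lower <- 0.1 +
    sqrt((100 / 1000^2) / 120) * (byar_limits(120)$lower - 120)
  expect_equal(a1$lower, expected_lower)
  expect_equal(a1$all_area_assr, 0.04)
  expect_gt(a1$lower, a1$all_area_assr)
  # exactly area 1 is flagged
  expect_equal(hs$area_id[hs$hotspot], "a1")

  # degenerate rate: zero variance collapses the interval onto the estimate
  rates <- compute_assr(panel, w)
  rates$variance[2] <- 0
  lims <- assr_confidence_limits(rates, all_area_summary(panel, w))
  expect_equal(lims$lower[2], lims$assr[2])
  expect_equal(lims$upper[2], lims$assr[2])
})

test_that("rescaling all weights changes nothing", {
  set.seed(11)
  strata <- c("s1", "s2", "s3")
  panel <- make_panel(4, strata,
    function(a, s) rpois(1, 30), function(a, s) 200 + runif(1, 0, 400)
  )
  w1 <- tibble::tibble(stratum_id = strata, weight = c(0.3, 1.2, 2.5))
  w2 <- dplyr::mutate(w1, weight = weight * 1234.5)
  h1 <- classify_hotspots(panel, w1)
  h2 <- classify_hotspots(panel, w2)
  expect_equal(h1$assr, h2$assr)
  expect_equal(h1$variance, h2$variance)
  expect_equal(h1$lower, h2$lower)
  expect_equal(h1$hotspot, h2$hotspot)
})

test_that("hotspot flags shrink as the confidence level rises", {
  set.seed(3)
  strata <- c("s1", "s2")
  panel <- make_panel(20, strata,
    function(a, s) rpois(1, 15 + 4 * (a %% 5)),
    function(a, s) 500
  )
  w <- equal_weights(strata)
  zs <- c(1.2815516, 1.644854, 1.959964, 2.575829)
  flags <- sapply(zs, function(z) sum(classify_hotspots(panel, w, z = z)$hotspot))
  expect_true(all(diff(flags) <= 0))
  h95 <- classify_hotspots(panel, w, z = 1.959964)
  h99 <- classify_hotspots(panel, w, z = 2.575829)
  expect_true(all(h99$area_id[h99$hotspot] %in% h95$area_id[h95$hotspot]))
})

test_that("identical areas with large counts yield no hotspots", {
  panel <- make_panel(6, "s1", function(a, s) 500L, function(a, s) 10000)
  hs <- classify_hotspots(panel, equal_weights("s1"))
  expect_false(any(hs$hotspot))
})

test_that("hotspot_matrix reshapes the long classification", {
  hs <- random_hotspots(4, 3)
  m <- hotspot_matrix(hs)
  expect_equal(dim(m), c(4, 3))
  expect_equal(
    m["a2", "3"],
    hs$hotspot[hs$area_id == "a2" & hs$year == 3]
  )
})
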