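test_that("age-specific estimator reproduces the Namibia J-shape row 30-34", {
  b <- load_fixture("namibia2019")
  ltr <- ltr_age_specific(b$morbidity, b$fertility, b$life_table)
  row <- dplyr::filter(tidy(ltr), age_start == 30)
  expect_equal(round(row$contribution, 4), 0.0075)
  # against hand recomputation of the printed inputs
  expect_equal(row$contribution, 11.19 / 1000 * 140.9 / 1000 * 455466.6 / 95283,
               tolerance = 1e-12)
  expect_identical(ltr$route, "age_specific")
  expect_identical(ltr$event, "mnm")
  # value is the exact sum of contributions
  expect_identical(ltr$value, sum(tidy(ltr)$contribution))
})

test_that("zero morbidity gives zero lifetime risk", {
  b <- load_fixture("namibia2019")
  zero <- morbidity_schedule(
    dplyr::mutate(reproductive_grid(), ratio = 0), "per_birth")
  ltr <- ltr_age_specific(zero, b$fertility, b$life_table)
  expect_identical(ltr$value, 0)
  expect_identical(tidy(ltr)$contribution, rep(0, 7))
  expect_identical(ltr_summary(0, b$fertility, b$life_table)$value, 0)
})

test_that("constant per-age ratio collapses the age-specific route to the summary route", {
  b <- load_fixture("namibia2019")
  for (r in c(0.001, 0.00803, 0.05)) {
    const <- morbidity_schedule(
      dplyr::mutate(reproductive_grid(), ratio = r), "per_birth")
    expect_equal(ltr_age_specific(const, b$fertility, b$life_table)$value,
                 ltr_summary(r, b$fertility, b$life_table)$value,
                 tolerance = 1e-12)
  }
})

test_that("rate-based and ratio-based forms agree under rate = ratio * fertility", {
  b <- load_fixture("namibia2019")
  rates <- tibble::tibble(age_start = b$morbidity$age_start,
                          age_interval = 5,
                          rate = b$morbidity$ratio * b$fertility$asfr)
  expect_equal(ltr_from_rate(rates, b$life_table)$value,
               ltr_age_specific(b$morbidity, b$fertility, b$life_table)$value,
               tolerance = 1e-12)

  # property: equality across random draws on a no-mortality toy table
  lt <- toy_life_table(step = 10)
  grid <- reproductive_grid()
  for (i in 1:100) {
    draws <- withr::with_seed(i, list(ratio = runif(7, 0, 0.05),
                                      f = runif(7, 0, 0.3)))
    morb <- morbidity_schedule(dplyr::mutate(grid, ratio = draws$ratio))
    fert <- fertility_schedule(dplyr::mutate(grid, asfr = draws$f))
    rates <- dplyr::mutate(grid, rate = draws$ratio * draws$f)
    expect_equal(ltr_from_rate(rates, lt)$value,
                 ltr_age_specific(morb, fert, lt)$value,
                 tolerance = 1e-12)
  }
})

test_that("rate-based form: one-group closed form", {
  lt <- toy_life_table(step = 0)  # weight exactly 5
  rates <- tibble::tibble(age_start = 15, age_interval = 5, rate = 0.001)
  expect_equal(ltr_from_rate(rates, lt)$value, 0.005, tolerance = 1e-15)
})

test_that("summary estimator: worked-example value, rendering and linearity", {
  b <- load_fixture("namibia2019")
  ltr <- ltr_summary(8.03, b$fertility, b$life_table, units = "per_1000")
  expect_equal(ltr$value, 0.0264, tolerance = 2e-3)
  expect_identical(one_in_n(ltr$value)$label, "1 in 38")
  expect_identical(ltr$route, "summary")
  # linear in the aggregate ratio
  ltr2 <- ltr_summary(16.06, b$fertility, b$life_table, units = "per_1000")
  expect_equal(ltr2$value, 2 * ltr$value, tolerance = 1e-12)
})

test_that("sex-ratio scaling factor matches its definition", {
  expect_equal(srb_scaling_factor(101), 2.01)
  expect_equal(srb_scaling_factor(105), 2.05)
  expect_equal(srb_scaling_factor(100), 2.00)
  expect_error(srb_scaling_factor(0), class = "ltrmnm_error_input")
  expect_error(srb_scaling_factor(-5), class = "ltrmnm_error_input")
})

test_that("NRR shortcut reproduces the published summary calculation", {
  s <- summary_inputs(8.03, nrr = 1.554, srb = 101, l0 = 1e5, l15 = 95283,
                      units = "per_1000")
  ltr <- ltr_summary_nrr(s)
  expect_equal(round(ltr$value, 4), 0.0263)
  expect_identical(one_in_n(ltr$value)$label, "1 in 38")
  expect_identical(ltr$route, "summary_nrr")

  expect_identical(
    ltr_summary_nrr(summary_inputs(0, 1.554, 101, l15 = 95283))$value, 0)
  expect_equal(
    ltr_summary_nrr(summary_inputs(0.001, nrr = 1, srb = 105,
                                   l0 = 1e5, l15 = 1e5))$value,
    0.00205, tolerance = 1e-12)
})

test_that("summary route and NRR shortcut are algebraically equivalent", {
  for (i in 1:25) {
    expect_lt(summary_route_gap(random_bundle(i)), 1e-9)
  }
})

test_that("severe-outcome risk is the sum of its components", {
  b <- load_fixture("namibia2019")
  lt <- b$life_table
  mnm <- ltr_summary_nrr(summary_inputs(
    8.03, nrr = b$nrr, srb = b$srb, l0 = lt_radix(lt),
    l15 = survivors_at(lt, 15), units = "per_1000"))
  md <- structure(list(value = b$ltr_md_published, route = "published",
                       event = "maternal_death",
                       contributions = tibble::tibble()),
                  class = "lifetime_risk")
  smo <- ltr_smo(md, mnm)
  expect_equal(round(smo$value, 4), 0.0333)
  expect_identical(one_in_n(smo$value)$label, "1 in 30")
  expect_identical(smo$event, "smo")
  expect_equal(smo$value, md$value + mnm$value)
  # share of the severe outcome attributable to morbidity
  expect_equal(round(morbidity_share(mnm, smo)), 79)
})

test_that("severe-outcome combination enforces event kinds", {
  b <- load_fixture("namibia2019")
  mnm <- ltr_summary(8.03, b$fertility, b$life_table, units = "per_1000")
  expect_error(ltr_smo(mnm, mnm), class = "ltrmnm_error_usage")
})

test_that("morbidity share spans its range", {
  mk <- function(v, e) structure(
    list(value = v, route = "summary", event = e,
         contributions = tibble::tibble()), class = "lifetime_risk")
  expect_equal(morbidity_share(mk(0.02, "mnm"), mk(0.02, "smo")), 100)
  expect_equal(morbidity_share(mk(0, "mnm"), mk(0.02, "smo")), 0)
  expect_error(morbidity_share(mk(0, "mnm"), mk(0, "smo")),
               class = "ltrmnm_error_input")
})

test_that("'1 in n' rendering matches every published example", {
  expect_identical(one_in_n(0.0263)$label, "1 in 38")
  expect_identical(one_in_n(0.0282)$label, "1 in 35")
  expect_identical(one_in_n(0.0333)$label, "1 in 30")
  expect_identical(one_in_n(0.00702)$label, "1 in 142")
  expect_identical(one_in_n(0.5)$label, "1 in 2")
  expect_identical(one_in_n(c(0.0263, 0.5))$n, c(38L, 2L))
  expect_error(one_in_n(0), class = "ltrmnm_error_input")
  expect_error(one_in_n(1), class = "ltrmnm_error_input")
})

test_that("estimators are linear and monotone in ratios, fertility and survival", {
  b <- random_bundle(11)
  base <- ltr_age_specific(b$morbidity, b$fertility, b$life_table)$value
  scaled <- morbidity_schedule(
    dplyr::mutate(as.data.frame(b$morbidity), ratio = 3 * ratio,
                  cases = NULL, live_births = NULL))
  expect_equal(ltr_age_specific(scaled, b$fertility, b$life_table)$value,
               3 * base, tolerance = 1e-12)

  bump_one <- function(col_df) ltr_age_specific(col_df$m, col_df$f, col_df$l)$value
  # raise a single ratio / rate / Lx entry: value must not decrease
  m2 <- b$morbidity; m2$ratio[4] <- m2$ratio[4] * 1.5
  f2 <- b$fertility; f2$asfr[2] <- f2$asfr[2] * 1.2
  l2 <- b$life_table
  i <- which(l2$age_start == 25)
  l2$Lx[i] <- min(l2$Lx[i] * 1.01, 5 * l2$lx[i])
  expect_gt(bump_one(list(m = m2, f = b$fertility, l = b$life_table)), base)
  expect_gt(bump_one(list(m = b$morbidity, f = f2, l = b$life_table)), base)
  expect_gte(bump_one(list(m = b$morbidity, f = b$fertility, l = l2)), base)
})

test_that("severe-outcome addition matches the summed count schedule", {
  # additivity: summing MNM and death cases over the same births equals
  # adding the two age-specific risks
  b <- load_fixture("namibia2019")
  deaths <- withr::with_seed(5, {
    dplyr::mutate(as.data.frame(b$morbidity), ratio = NULL,
                  cases = rpois(7, 0.02 * cases))
  })
  md_sched <- morbidity_schedule(deaths, event = "maternal_death")
  counts <- dplyr::select(as.data.frame(b$morbidity), -"ratio")
  mnm_sched <- morbidity_schedule(counts, event = "mnm")
  both <- morbidity_schedule(
    dplyr::mutate(counts, cases = cases + deaths$cases), event = "smo")
  smo <- ltr_smo(ltr_age_specific(md_sched, b$fertility, b$life_table),
                 ltr_age_specific(mnm_sched, b$fertility, b$life_table))
  expect_equal(smo$value,
               ltr_age_specific(both, b$fertility, b$life_table)$value,
               tolerance = 1e-12)
})

test_that("implausible unit errors are rejected rather than silently returned", {
  b <- load_fixture("namibia2019")
  # an aggregate "ratio" of 8.03 per birth (units mistake) exceeds 1
  expect_error(ltr_summary(8.03, b$fertility, b$life_table, units = "per_birth"),
               class = "ltrmnm_error_domain")
})
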