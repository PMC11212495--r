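# In-code fixtures shared across the suite.

# Toy life table on the reproductive grid: linear survivorship decline of
# `step` persons per 5-year group from l15; step = 0 gives no mortality.
toy_life_table <- function(l15 = 1000, step = 0) {
  pins <- l15 - step * 0:7           # survivors at 15, 20, ..., 50
  tibble::tibble(
    age_start = seq(15, 45, 5),
    age_interval = 5,
    lx = pins[1:7],
    Lx = 5 * (pins[1:7] + pins[2:8]) / 2
  ) |> life_table(radix = l15)
}

flat_fertility <- function(rate = 0.1) {
  dplyr::mutate(reproductive_grid(), asfr = rate) |> fertility_schedule()
}

# Reproducible bundle with knobs drawn from the index.
random_bundle <- function(i, family = "j_shape") {
  knobs <- withr::with_seed(i, {
    list(m = runif(1, 0.3, 3), f = runif(1, 1.5, 6.5),
         t = runif(1, 2, 20), srb = runif(1, 95, 112))
  })
  make_synthetic_bundle(seed = i + 1000L, mortality_level = knobs$m,
                        fertility_level = knobs$f, target_aggregate = knobs$t,
                        family = family, srb = knobs$srb)
}

# Route-equivalence gap between the summary estimator and its NRR shortcut
# on one bundle (should vanish when the NRR comes from the same schedules).
summary_route_gap <- function(b) {
  lt <- b$life_table
  s1 <- ltr_summary(b$aggregate_ratio, b$fertility, lt)
  s2 <- ltr_summary_nrr(summary_inputs(
    b$aggregate_ratio, nrr = b$nrr, srb = b$srb,
    l0 = lt_radix(lt), l15 = survivors_at(lt, 15)))
  abs(s1$value - s2$value) / s1$value
}
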