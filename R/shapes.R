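# Age-pattern simulation: plausible age distributions of the near miss
# ratio constrained to a fixed aggregate level, stillbirth adjustment of
# birth counts, and the synthetic input-bundle generator.

# Default relative-risk profiles on the 7-group reproductive grid.  The
# literature gives qualitative shapes only; these multipliers are fixed,
# documented defaults (configurable via shape_family(profile = ...)).
default_shape_profiles <- list(
  j_shape    = c(1.5, 0.8, 1.0, 1.9, 2.1, 2.6, 3.1),
  u_shape    = c(2.2, 1.3, 0.9, 0.8, 1.0, 1.5, 2.3),
  n_shape    = c(0.6, 1.1, 1.6, 1.9, 1.5, 1.0, 0.5),
  constant   = rep(1, 7),
  increasing = c(0.5, 0.8, 1.1, 1.5, 2.0, 2.6, 3.3),
  decreasing = c(3.3, 2.6, 2.0, 1.5, 1.1, 0.8, 0.5)
)

#' Names of the supported age-pattern families
#'
#' @return Character vector of family names.
#' @export
shape_families <- function() names(default_shape_profiles)

#' An age-pattern family for the near miss ratio
#'
#' A family is a vector of seven positive relative-risk multipliers on the
#' reproductive grid, later calibrated by a single scalar so that the
#' births-weighted mean ratio hits a requested aggregate level.  Each named
#' family enforces its qualitative shape: `j_shape` is elevated at 15-19,
#' has its minimum at 20-24 and increases strictly thereafter; `u_shape`
#' has a single interior minimum with elevated extremes; `n_shape` a single
#' interior maximum; `increasing`/`decreasing` are strictly monotone;
#' `constant` is flat.
#'
#' @param name One of [shape_families()].
#' @param profile Optional replacement multipliers (7 positive numbers,
#'   validated against the family's shape invariant).
#' @return A list of class `ltr_shape` with fields `name` and `profile`.
#' @export
#' @examples
#' shape_family("j_shape")
shape_family <- function(name = shape_families(), profile = NULL) {
  name <- rlang::arg_match(name)
  profile <- profile %||% default_shape_profiles[[name]]
  if (length(profile) != 7 || any(!is.finite(profile)) || any(profile <= 0)) {
    abort_input("A shape profile must be 7 positive finite multipliers.")
  }
  check_shape_profile(name, profile)
  structure(list(name = name, profile = profile), class = "ltr_shape")
}

check_shape_profile <- function(name, p) {
  d <- diff(p)
  ok <- switch(
    name,
    constant = all(p == p[1]),
    increasing = all(d > 0),
    decreasing = all(d < 0),
    j_shape = p[1] > p[2] && all(diff(p[2:7]) > 0),
    u_shape = {
      k <- which.min(p)
      k > 1 && k < 7 && all(diff(p[1:k]) < 0) && all(diff(p[k:7]) > 0)
    },
    n_shape = {
      k <- which.max(p)
      k > 1 && k < 7 && all(diff(p[1:k]) > 0) && all(diff(p[k:7]) < 0)
    }
  )
  if (!ok) {
    abort_input(sprintf("Profile violates the '%s' shape invariant.", name))
  }
  invisible(TRUE)
}

#' Convert total births to live births using a stillbirth rate
#'
#' Stillbirth rates are expressed per 1000 total births, so live births are
#' `births * (1 - sbr/1000)`, rounded half-up to whole births per group.
#'
#' @param births Total (live + still) birth counts by age group.
#' @param sbr Stillbirth rate per 1000 total births, in `[0, 1000)`.
#' @return Live-birth counts, integers.
#' @export
#' @examples
#' stillbirth_adjust(69225, 17.68)  # 68001
stillbirth_adjust <- function(births, sbr) {
  if (!is.numeric(sbr) || length(sbr) != 1 || sbr < 0 || sbr >= 1000) {
    abort_input("`sbr` must be a stillbirth rate per 1000 total births in [0, 1000).")
  }
  if (any(births < 0)) abort_input("Birth counts must be non-negative.")
  round_half_up(births * (1 - sbr / 1000))
}

#' Generate an age-specific morbidity schedule from a shape family
#'
#' Scales the family's relative-risk profile by a single constant `c` so
#' that the births-weighted mean ratio equals `target_aggregate` exactly
#' (before integer rounding): `ratio_g = c * profile_g` with
#' `sum(ratio_g * births_g) / sum(births_g) = target_aggregate / 1000`.
#' Integer case counts summing to `round(target/1000 * total births)` are
#' then allocated by largest-remainder apportionment (ties broken toward
#' the youngest group), so the schedule is deterministic and conserves the
#' total.
#'
#' @param live_births Data frame with `age_start`, `age_interval`,
#'   `live_births` (all positive), or a bare vector of 7 counts on the
#'   default reproductive grid.
#' @param family A [shape_family()] or family name.
#' @param target_aggregate Aggregate ratio for ages 15-49 combined, events
#'   per 1000 live births.
#' @param event Event kind label for the resulting schedule.
#' @return A [morbidity_schedule()] carrying the calibrated exact ratios
#'   and the apportioned integer cases.
#' @export
#' @examples
#' b <- load_fixture("namibia2019")
#' ratios_from_shape(b$morbidity, "constant", target_aggregate = 8.03)
ratios_from_shape <- function(live_births, family, target_aggregate,
                              event = "mnm") {
  if (is.character(family)) family <- shape_family(family)
  if (!inherits(family, "ltr_shape")) {
    abort_usage("`family` must be a shape_family() or a family name.")
  }
  if (is.numeric(live_births) && is.null(dim(live_births))) {
    live_births <- dplyr::mutate(reproductive_grid(), live_births = live_births)
  }
  b <- live_births$live_births
  if (length(b) != 7 || any(b <= 0)) {
    abort_input("`live_births` must hold 7 positive counts on the reproductive grid.")
  }
  if (!is.numeric(target_aggregate) || target_aggregate <= 0) {
    abort_input("`target_aggregate` must be positive (events per 1000 live births).")
  }
  p <- family$profile
  target <- target_aggregate / 1000
  cal <- target * sum(b) / sum(p * b)
  ratio <- cal * p
  quotas <- ratio * b                       # expected cases; sum = target * sum(b)
  total_cases <- round_half_up(target * sum(b))
  base <- floor(quotas)
  short <- total_cases - sum(base)
  frac <- quotas - base
  # largest remainder, ties to the youngest age group
  extra <- order(-frac, live_births$age_start)[seq_len(short)]
  cases <- base
  cases[extra] <- cases[extra] + 1
  morbidity_schedule(
    tibble::tibble(
      age_start = live_births$age_start,
      age_interval = live_births$age_interval,
      cases = cases,
      live_births = b,
      ratio = ratio
    ),
    units = "per_birth", event = event, count_tol = Inf
  )
}

#' Sensitivity of the lifetime risk to the assumed age pattern
#'
#' Generates one morbidity schedule per family (all constrained to the same
#' aggregate ratio), runs the age-specific estimator on each, and tabulates
#' the resulting lifetime risks and their "1 in n" renderings.
#'
#' @inheritParams ratios_from_shape
#' @param fert A [fertility_schedule()].
#' @param lt A [life_table()].
#' @param families Character vector of family names or list of
#'   [shape_family()] objects (default: all six).
#' @return A tibble of class `ltr_sweep` with columns `family`, `ltr`, `n`,
#'   `label`, plus a `band` attribute summarising the min/max rendering
#'   ("between 1 in max and 1 in min").
#' @export
#' @examples
#' b <- load_fixture("namibia2019")
#' sensitivity_sweep(b$morbidity, b$fertility, b$life_table,
#'                   target_aggregate = 8.03)
sensitivity_sweep <- function(live_births, fert, lt,
                              families = shape_families(),
                              target_aggregate) {
  rows <- purrr::map(families, function(fam) {
    morb <- ratios_from_shape(live_births, fam, target_aggregate)
    ltr <- ltr_age_specific(morb, fert, lt)
    r <- one_in_n(ltr$value)
    name <- if (inherits(fam, "ltr_shape")) fam$name else fam
    tibble::tibble(family = name, ltr = ltr$value, n = r$n, label = r$label)
  })
  out <- dplyr::bind_rows(rows)
  band <- sprintf("between 1 in %d and 1 in %d", max(out$n), min(out$n))
  structure(out, class = c("ltr_sweep", class(out)), band = band)
}

#' Plot a sensitivity sweep
#'
#' @param object A `ltr_sweep` from [sensitivity_sweep()].
#' @param ... Unused.
#' @return A ggplot of the lifetime risk per age-pattern family.
#' @method autoplot ltr_sweep
#' @export
autoplot.ltr_sweep <- function(object, ...) {
  df <- dplyr::mutate(object,
                      family = factor(.data$family, levels = .data$family))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$ltr)) +
    ggplot2::geom_point(size = 3, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -1, size = 3) +
    ggplot2::labs(x = "Age pattern of the near miss ratio",
                  y = "Lifetime risk",
                  title = "Sensitivity of the lifetime risk to the age pattern") +
    ggplot2::theme_minimal()
}

# Baseline shapes for the synthetic generator: a broad mid-peaked fertility
# pattern and a mildly increasing adult mortality hazard.
synthetic_fertility_shape <- c(0.09, 0.21, 0.22, 0.19, 0.15, 0.1, 0.04)
synthetic_hazard <- function(age, mortality_level) {
  mortality_level * 0.002 * exp(0.04 * (age - 15))
}

#' Generate an internally consistent synthetic input bundle
#'
#' Builds a life table, fertility schedule and morbidity schedule that
#' satisfy all container invariants and are mutually consistent: the
#' morbidity schedule's aggregate ratio hits `target_aggregate` (to within
#' integer-allocation error) and `nrr` matches [nrr_from_schedules()] on
#' the generated schedules.  Intended as the package's test-fixture engine:
#' the defaults emulate a middle-income setting (moderate fertility,
#' low-to-moderate adult female mortality, near miss ratios of a few per
#' 1000 births).
#'
#' Generation is fully reproducible: all randomness (log-normal jitter on
#' the fertility shape and on age-specific hazards) flows from `seed`.
#'
#' @param seed Integer seed.
#' @param mortality_level Positive scale on the adult female mortality
#'   hazard; 1 gives roughly 5% mortality over ages 15-50.
#' @param fertility_level Total fertility rate, births per woman.
#' @param target_aggregate Aggregate event ratio per 1000 live births.
#' @param family Age-pattern family for the morbidity schedule.
#' @param srb Sex ratio at birth, boys per 100 girls.
#' @param women Women per five-year age group in the synthetic population
#'   (drives birth-count denominators).
#' @param preset `"namibia2019"` short-circuits to [load_fixture()].
#' @return A list of class `ltr_bundle` with elements `life_table`,
#'   `fertility`, `morbidity`, `srb`, `nrr`, `aggregate_ratio`, `seed`.
#' @export
#' @examples
#' b <- make_synthetic_bundle(seed = 1)
#' nrr_from_schedules(b$life_table, b$fertility, b$srb) == b$nrr
make_synthetic_bundle <- function(seed = 1L,
                                  mortality_level = 1,
                                  fertility_level = 3.3,
                                  target_aggregate = 8,
                                  family = "j_shape",
                                  srb = 103,
                                  women = 10000,
                                  preset = NULL) {
  if (!is.null(preset)) return(load_fixture(preset))
  if (mortality_level <= 0 || mortality_level > 50) {
    abort_input("`mortality_level` must be in (0, 50].")
  }
  if (fertility_level <= 0 || fertility_level > 12) {
    abort_input("`fertility_level` must be a plausible TFR in (0, 12].")
  }
  withr::with_seed(seed, {
    grid <- reproductive_grid()
    ages <- c(grid$age_start, 50)
    # survivorship: ~3% loss before 15, then jittered Gompertz-like hazard
    l0 <- 1e5
    l15 <- l0 * exp(-0.03 * min(mortality_level, 2))
    haz <- synthetic_hazard(grid$age_start + 2.5, mortality_level) *
      exp(runif(7, -0.2, 0.2))
    lx <- l15 * exp(-cumsum(c(0, haz * 5)))   # survivors at 15, 20, ..., 50
    Lx <- 5 * (lx[-8] + lx[-1]) / 2           # trapezoid within 5-year groups
    lx_col <- c(l0, lx)
    Lx_col <- c(15 * (l0 + l15) / 2, Lx, 5 * lx[8] * 0.98)
    lt <- life_table(
      tibble::tibble(age_start = c(0, ages),
                     age_interval = c(15L, rep(5L, 8)),
                     lx = lx_col, Lx = Lx_col),
      radix = l0
    )
    shape <- synthetic_fertility_shape * exp(runif(7, -0.15, 0.15))
    shape <- shape / sum(shape)
    fert <- fertility_schedule(
      dplyr::mutate(grid, asfr = fertility_level * shape / 5),
      units = "per_woman"
    )
    births <- pmax(1, round_half_up(fert$asfr * women * 5))
    morb <- ratios_from_shape(
      dplyr::mutate(grid, live_births = births), family, target_aggregate
    )
    structure(
      list(life_table = lt, fertility = fert, morbidity = morb,
           srb = srb, nrr = nrr_from_schedules(lt, fert, srb),
           aggregate_ratio = target_aggregate / 1000,
           seed = seed, source = "synthetic"),
      class = "ltr_bundle"
    )
  })
}

#' @export
print.ltr_bundle <- function(x, ...) {
  cat(sprintf("Demographic input bundle ('%s')\n", x$source))
  cat(sprintf("  NRR %.3f, SRB %s; aggregate ratio %.2f per 1000 live births\n",
              x$nrr, format(x$srb), 1000 * x$aggregate_ratio))
  cat(sprintf("  morbidity: %s cases / %s live births over 7 groups\n",
              format(sum(x$morbidity$cases)),
              format(sum(x$morbidity$live_births))))
  invisible(x)
}
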