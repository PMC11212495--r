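# Facility-to-population adjustment and uncertainty propagation.
# Event counts per age group can be small (single digits at 45-49), so the
# frequentist interval is the exact Poisson (Garwood) interval rather than
# a normal approximation; the 80% "uncertainty interval" convention is
# percentile reporting over a Jeffreys Gamma posterior on each count.

new_interval_estimate <- function(point, lower, upper, level, method) {
  if (!(lower <= point + 1e-12 && point <= upper + 1e-12)) {
    abort_domain("Interval must satisfy lower <= point <= upper.")
  }
  if (level <= 0 || level >= 1) abort_input("`level` must lie in (0, 1).")
  structure(list(point = point, lower = lower, upper = upper,
                 level = level, method = method),
            class = "ltr_interval")
}

#' @export
print.ltr_interval <- function(x, ...) {
  cat(sprintf("%.0f%% interval (%s): %.6g [%.6g, %.6g]\n",
              100 * x$level, x$method, x$point, x$lower, x$upper))
  invisible(x)
}

#' Tidy an interval estimate
#'
#' @param x A `ltr_interval`.
#' @param ... Unused.
#' @return One-row tibble with `point`, `lower`, `upper`, `level`, `method`.
#' @method tidy ltr_interval
#' @export
tidy.ltr_interval <- function(x, ...) {
  tibble::tibble(point = x$point, lower = x$lower, upper = x$upper,
                 level = x$level, method = x$method)
}

#' Adjust a facility-based ratio to the population level
#'
#' Facility surveillance captures (nearly) all events — women with a
#' life-threatening complication would not survive without facility care —
#' but its live-birth denominator misses home births.  Inflating the
#' denominator by the institutional delivery rate is equivalent to
#' multiplying the ratio by that rate:
#' `adjusted = facility_ratio * institutional_delivery_rate`.
#'
#' A warning (class `ltrmnm_warning_low_idr`) is emitted when the
#' institutional delivery rate is below 0.5: with mostly home births, and
#' especially when facility data derive from tertiary hospitals only, the
#' completeness assumptions behind this adjustment become doubtful.
#'
#' @param facility_ratio Facility-based events per live birth (any scale;
#'   returned on the same scale).
#' @param institutional_delivery_rate Proportion of births occurring in
#'   health facilities, in (0, 1].
#' @return The adjusted ratio, same scale as the input.
#' @export
#' @examples
#' facility_adjust(10, 0.8)  # 8, on whatever per-birth scale 10 was
facility_adjust <- function(facility_ratio, institutional_delivery_rate) {
  idr <- institutional_delivery_rate
  if (!is.numeric(idr) || length(idr) != 1 || idr <= 0 || idr > 1) {
    abort_input("`institutional_delivery_rate` must be a proportion in (0, 1].")
  }
  if (any(facility_ratio < 0)) abort_input("`facility_ratio` must be non-negative.")
  if (idr < 0.5) {
    warn(paste("Institutional delivery rate below 0.5: facility-based ratios",
               "may remain overestimated even after adjustment (denominator",
               "completeness is doubtful when most births occur at home)."),
         class = "ltrmnm_warning_low_idr")
  }
  facility_ratio * idr
}

#' Exact Poisson interval for an event ratio
#'
#' Garwood's exact interval for a Poisson count, divided by the live-birth
#' denominator: lower `qgamma(a/2, cases)/births` (0 when `cases` is 0),
#' upper `qgamma(1 - a/2, cases + 1)/births`.
#'
#' @param cases Event count (non-negative integer).
#' @param live_births Live-birth denominator (positive).
#' @param level Coverage probability, default 0.95.
#' @return A `ltr_interval` on the proportion (events per live birth) scale.
#' @export
#' @examples
#' tidy(ratio_interval(546, 68001))
ratio_interval <- function(cases, live_births, level = 0.95) {
  if (level <= 0 || level >= 1) abort_input("`level` must lie in (0, 1).")
  if (length(cases) != 1 || cases < 0) abort_input("`cases` must be a single non-negative count.")
  if (length(live_births) != 1 || live_births <= 0) {
    abort_input("`live_births` must be a single positive count.")
  }
  a <- (1 - level) / 2
  lower <- if (cases == 0) 0 else qgamma(a, cases) / live_births
  upper <- qgamma(1 - a, cases + 1) / live_births
  new_interval_estimate(cases / live_births, lower, upper, level,
                        method = "poisson_exact")
}

draw_ratio_matrix <- function(cases, births, draws, method) {
  # draws x groups matrix of ratio draws
  k <- length(cases)
  m <- switch(method,
    poisson = matrix(rpois(draws * k, lambda = rep(cases, each = draws)),
                     nrow = draws),
    gamma = matrix(rgamma(draws * k, shape = rep(cases + 0.5, each = draws),
                          rate = 1), nrow = draws)
  )
  sweep(m, 2, births, "/")
}

#' Uncertainty interval for a lifetime risk
#'
#' Propagates count-level uncertainty in the morbidity schedule through the
#' lifetime-risk estimators.
#'
#' * `route = "summary"`, `simulate = FALSE` (default): the aggregate count
#'   interval ([ratio_interval()] for `method = "poisson"`, Jeffreys
#'   Gamma-posterior percentiles for `method = "gamma"`) is pushed through
#'   [ltr_summary()].  Because every estimator is linear and increasing in
#'   the ratio, endpoint propagation is exact.
#' * `route = "age_specific"`: group counts are treated as independent
#'   Poisson observations; Monte Carlo draws (parametric bootstrap for
#'   `method = "poisson"`, Gamma posterior for `method = "gamma"`) are
#'   pushed through the age-specific estimator and the `(1 ± level)/2`
#'   percentiles extracted.  `level = 0.8` with `method = "gamma"` gives
#'   the 10th/90th-percentile 80% uncertainty-interval convention.
#'
#' Independence across age groups is assumed; clustering of repeat events
#' within women is not modelled (the result is a population average).
#'
#' @param morb A [morbidity_schedule()] with counts.
#' @param fert A [fertility_schedule()].
#' @param lt A [life_table()].
#' @param route `"summary"` or `"age_specific"`.
#' @param level Coverage probability (0.95 for a 95% CI, 0.8 for an 80% UI).
#' @param method `"poisson"` (exact/bootstrap) or `"gamma"` (Jeffreys posterior).
#' @param draws Monte Carlo draws for simulated routes.
#' @param seed Optional seed making simulated intervals reproducible.
#' @param simulate Use Monte Carlo for the summary route too (used to check
#'   the exact propagation).
#' @return A `ltr_interval` on the lifetime-risk (probability) scale.
#' @export
#' @examples
#' b <- load_fixture("namibia2019")
#' tidy(ltr_interval(b$morbidity, b$fertility, b$life_table,
#'                   route = "summary"))
ltr_interval <- function(morb, fert, lt,
                         route = c("age_specific", "summary"),
                         level = 0.95,
                         method = c("poisson", "gamma"),
                         draws = 10000,
                         seed = NULL,
                         simulate = NULL) {
  route <- rlang::arg_match(route)
  method <- rlang::arg_match(method)
  if (any(is.na(morb$cases)) || any(is.na(morb$live_births))) {
    abort_input("Count-based uncertainty needs `cases` and `live_births` in the schedule.")
  }
  simulate <- simulate %||% (route == "age_specific")
  a <- (1 - level) / 2
  run <- function() {
    if (route == "summary" && !simulate) {
      cases <- sum(morb$cases)
      births <- sum(morb$live_births)
      bounds <- if (method == "poisson") {
        ri <- ratio_interval(cases, births, level)
        c(ri$lower, ri$upper)
      } else {
        qgamma(c(a, 1 - a), shape = cases + 0.5) / births
      }
      point <- ltr_summary(cases / births, fert, lt)$value
      lims <- vapply(bounds, function(r) ltr_summary(r, fert, lt)$value, 0)
      new_interval_estimate(point, lims[1], lims[2], level,
                            method = paste0(method, "_propagated"))
    } else if (route == "summary") {
      births <- sum(morb$live_births)
      w <- survival_weights(lt, ages = fert$age_start)
      unit <- sum(fert$asfr * w$weight)   # LTR per unit aggregate ratio
      r <- draw_ratio_matrix(sum(morb$cases), births, draws, method)[, 1]
      ltrs <- r * unit
      point <- ltr_summary(sum(morb$cases) / births, fert, lt)$value
      qs <- unname(quantile(ltrs, c(a, 1 - a)))
      new_interval_estimate(point, min(qs[1], point), max(qs[2], point),
                            level, method = paste0(method, "_montecarlo"))
    } else {
      w <- survival_weights(lt, ages = morb$age_start)
      coef <- fert$asfr * w$weight
      r <- draw_ratio_matrix(morb$cases, morb$live_births, draws, method)
      ltrs <- as.vector(r %*% coef)
      point <- sum((morb$cases / morb$live_births) * coef)
      qs <- unname(quantile(ltrs, c(a, 1 - a)))
      new_interval_estimate(point, min(qs[1], point), max(qs[2], point),
                            level, method = paste0(method, "_montecarlo"))
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
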