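# Lifetime-risk estimators.  All share the synthetic-cohort logic: the
# risk that a girl surviving to exact age 15 experiences the event (near
# miss, maternal death, or either) over ages 15-49, weighting per-birth
# risk by fertility and by expected years lived in each age interval.

new_lifetime_risk <- function(value, contributions, route, event) {
  if (!is.finite(value) || value < 0) {
    abort_domain("Lifetime risk must be a finite non-negative number.")
  }
  if (value >= 1) {
    abort_domain(sprintf(
      "Computed lifetime risk %.4g is >= 1; check input units (rates and ratios must be proportions after normalisation).",
      value))
  }
  structure(
    list(value = value, contributions = contributions,
         route = route, event = event),
    class = "lifetime_risk"
  )
}

#' Lifetime risk from age-disaggregated morbidity ratios
#'
#' The age-specific estimator: for each five-year group the per-birth event
#' ratio is multiplied by the age-specific fertility rate (events per
#' woman-year) and by the survival weight \eqn{L_{x,n}/l_{15}} (expected
#' years lived in the group given survival to 15); group contributions are
#' summed over ages 15-49.  With a near miss schedule this is the LTR-MNM;
#' with a maternal-death schedule it is the classical lifetime risk of
#' maternal death.
#'
#' @param morb A [morbidity_schedule()] on the reproductive grid.
#' @param fert A [fertility_schedule()] on the same grid.
#' @param lt A [life_table()] reporting `lx` at exact age 15 and `Lx` for
#'   every reproductive group.
#' @return A `lifetime_risk` object: `value` (probability), per-age
#'   `contributions`, `route = "age_specific"` and the schedule's event kind.
#' @seealso [ltr_summary()], [ltr_summary_nrr()], [one_in_n()]
#' @export
#' @examples
#' b <- load_fixture("namibia2019")
#' ltr <- ltr_age_specific(b$morbidity, b$fertility, b$life_table)
#' glance(ltr)
ltr_age_specific <- function(morb, fert, lt) {
  assert_grid_aligned(morb, fert, "morbidity schedule", "fertility schedule")
  if (any(morb$ratio < 0)) abort_input("Morbidity ratios must be non-negative.")
  if (any(fert$asfr < 0)) abort_input("Fertility rates must be non-negative.")
  w <- survival_weights(lt, ages = morb$age_start)
  contributions <- tibble::tibble(
    age_start = morb$age_start,
    age_interval = morb$age_interval,
    ratio = morb$ratio,
    asfr = fert$asfr,
    weight = w$weight,
    contribution = morb$ratio * fert$asfr * w$weight
  )
  new_lifetime_risk(sum(contributions$contribution), contributions,
                    route = "age_specific", event = event_kind(morb))
}

#' Lifetime risk from an event rate per woman-year
#'
#' Rate-based form of the age-specific estimator: when the event rate per
#' woman-year lived (rather than per live birth) is observed, the lifetime
#' risk is \eqn{\sum_g rate_g \, L_g / l_{15}}.  Identical to
#' [ltr_age_specific()] under the substitution `rate = ratio * asfr`.
#'
#' @param rates Data frame with `age_start`, `age_interval`, `rate`
#'   (events per woman-year; `units = "per_1000"` divides by 1000).
#' @param lt A [life_table()].
#' @param units Units of `rate`.
#' @param event Event kind label.
#' @return A `lifetime_risk` object.
#' @export
ltr_from_rate <- function(rates, lt, units = c("per_woman_year", "per_1000"),
                          event = c("mnm", "maternal_death", "smo")) {
  units <- rlang::arg_match(units)
  event <- rlang::arg_match(event)
  need <- c("age_start", "age_interval", "rate")
  miss <- setdiff(need, names(rates))
  if (length(miss) > 0) {
    abort_input(sprintf("Rate schedule is missing column(s): %s.",
                        paste(miss, collapse = ", ")))
  }
  rate <- rates$rate / if (units == "per_1000") 1000 else 1
  if (any(!is.finite(rate)) || any(rate < 0)) {
    abort_input("Event rates must be finite and non-negative.")
  }
  w <- survival_weights(lt, ages = rates$age_start)
  contributions <- tibble::tibble(
    age_start = rates$age_start,
    age_interval = rates$age_interval,
    rate = rate,
    weight = w$weight,
    contribution = rate * w$weight
  )
  new_lifetime_risk(sum(contributions$contribution), contributions,
                    route = "age_specific", event = event)
}

#' Lifetime risk from a summary ratio, keeping age-specific mortality
#'
#' Summary estimator for when only an aggregate ratio for ages 15-49 is
#' available: assumes the per-birth risk is constant over age, so
#' \eqn{LTR = ratio \times \sum_g f_g L_g / l_{15}}.  Exactly equals the
#' age-specific estimator when every group's ratio is the aggregate.
#'
#' @param aggregate_ratio Events per live birth for ages 15-49 combined.
#' @param fert A [fertility_schedule()].
#' @param lt A [life_table()].
#' @param units Units of `aggregate_ratio`.
#' @param event Event kind label.
#' @return A `lifetime_risk` with `route = "summary"`.
#' @export
#' @examples
#' b <- load_fixture("namibia2019")
#' ltr_summary(8.03, b$fertility, b$life_table, units = "per_1000")
ltr_summary <- function(aggregate_ratio, fert, lt,
                        units = c("per_birth", "per_1000", "per_100000"),
                        event = c("mnm", "maternal_death", "smo")) {
  units <- rlang::arg_match(units)
  event <- rlang::arg_match(event)
  scale <- c(per_birth = 1, per_1000 = 1000, per_100000 = 1e5)[[units]]
  ratio <- aggregate_ratio / scale
  if (!is.finite(ratio) || ratio < 0) {
    abort_input("`aggregate_ratio` must be finite and non-negative.")
  }
  w <- survival_weights(lt, ages = fert$age_start)
  value <- ratio * sum(fert$asfr * w$weight)
  new_lifetime_risk(value, contributions = tibble::tibble(), route = "summary",
                    event = event)
}

#' Sex-ratio-at-birth scaling factor
#'
#' Converts daughter-only fertility (as embedded in the net reproduction
#' rate) back to all-births fertility: `srb/100 + 1`, where `srb` is boys
#' per 100 girls.  A typical SRB of 105 gives 2.05.
#'
#' @param srb Sex ratio at birth, boys per 100 girls.
#' @return Dimensionless scaling factor.
#' @export
#' @examples
#' srb_scaling_factor(101)  # 2.01
srb_scaling_factor <- function(srb) {
  if (any(!is.finite(srb)) || any(srb <= 0)) {
    abort_input("`srb` must be positive (boys per 100 girls).")
  }
  srb / 100 + 1
}

#' Lifetime risk from a summary ratio via the NRR shortcut
#'
#' The fully aggregated estimator, removing age-specific mortality:
#' \deqn{LTR = ratio \times NRR \times (SRB/100 + 1) \times l_0 / l_{15}.}
#' The NRR carries fertility-weighted survivorship for daughters only, so
#' the SRB factor restores births of both sexes and \eqn{l_0/l_{15}}
#' re-conditions on survival to age 15.  Algebraically identical to
#' [ltr_summary()] when the NRR is computed from the same schedules
#' ([nrr_from_schedules()]) with an age-constant SRB.
#'
#' @param s A [summary_inputs()] bundle.
#' @param event Event kind label.
#' @return A `lifetime_risk` with `route = "summary_nrr"`.
#' @export
#' @examples
#' s <- summary_inputs(8.03, nrr = 1.554, srb = 101, l15 = 95283,
#'                     units = "per_1000")
#' glance(ltr_summary_nrr(s))  # 0.0263, "1 in 38"
ltr_summary_nrr <- function(s, event = c("mnm", "maternal_death", "smo")) {
  event <- rlang::arg_match(event)
  if (!inherits(s, "ltr_summary_inputs")) {
    abort_usage("`s` must be built with summary_inputs().")
  }
  if (s$l15 <= 0) abort_input("l15 must be positive.")
  value <- s$aggregate_ratio * s$nrr * srb_scaling_factor(s$srb) * s$l0 / s$l15
  new_lifetime_risk(value, contributions = tibble::tibble(),
                    route = "summary_nrr", event = event)
}

#' Lifetime risk of severe maternal outcome
#'
#' A severe maternal outcome (SMO) is a maternal near miss or a maternal
#' death; its lifetime risk is the plain sum of the two component risks
#' (no competing-risk correction between the component events is applied;
#' the measure is a population average over the synthetic cohort).
#'
#' @param ltr_md A `lifetime_risk` with event kind `maternal_death`.
#' @param ltr_mnm A `lifetime_risk` with event kind `mnm`.
#' @return A `lifetime_risk` with event kind `smo`.
#' @export
ltr_smo <- function(ltr_md, ltr_mnm) {
  if (!inherits(ltr_md, "lifetime_risk") || !inherits(ltr_mnm, "lifetime_risk")) {
    abort_usage("Both inputs must be `lifetime_risk` objects.")
  }
  if (ltr_md$event != "maternal_death" || ltr_mnm$event != "mnm") {
    abort_usage(sprintf(
      "ltr_smo() needs a maternal_death risk and an mnm risk; got '%s' and '%s'.",
      ltr_md$event, ltr_mnm$event))
  }
  new_lifetime_risk(ltr_md$value + ltr_mnm$value,
                    contributions = tibble::tibble(),
                    route = "combined", event = "smo")
}

#' Share of the severe-outcome risk attributable to morbidity
#'
#' @param ltr_mnm A `lifetime_risk` for near miss.
#' @param ltr_smo A `lifetime_risk` for severe maternal outcome.
#' @return Percentage (0-100) of the SMO lifetime risk due to near miss.
#' @export
morbidity_share <- function(ltr_mnm, ltr_smo) {
  if (ltr_smo$value <= 0) abort_input("SMO lifetime risk must be positive.")
  100 * ltr_mnm$value / ltr_smo$value
}

#' Express a risk as "1 in n"
#'
#' Reciprocates a probability and rounds to the nearest integer, the
#' conventional rendering of lifetime risks.
#'
#' @param value Probability (or vector of probabilities) strictly in (0, 1).
#' @return A tibble with columns `value`, `n` (integer) and `label`
#'   (`"1 in n"`), one row per input.
#' @export
#' @examples
#' one_in_n(c(0.0263, 0.0333))
one_in_n <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0) || any(value >= 1)) {
    abort_input("`value` must lie strictly between 0 and 1.")
  }
  n <- as.integer(round_half_up(1 / value))
  tibble::tibble(value = value, n = n, label = sprintf("1 in %d", n))
}

#' @export
print.lifetime_risk <- function(x, ...) {
  kind <- c(mnm = "maternal near miss", maternal_death = "maternal death",
            smo = "severe maternal outcome")[[x$event]]
  cat(sprintf("Lifetime risk of %s (route: %s)\n", kind, x$route))
  cat(sprintf("  value: %.4f (%.2f%%), %s\n",
              x$value, 100 * x$value, one_in_n(x$value)$label))
  if (nrow(x$contributions) > 0) {
    cat(sprintf("  per-age contributions over %d groups; largest at age %d\n",
                nrow(x$contributions),
                x$contributions$age_start[which.max(x$contributions$contribution)]))
  }
  invisible(x)
}

#' Tidy the per-age contributions of a lifetime risk
#'
#' @param x A `lifetime_risk`.
#' @param ... Unused.
#' @return A tibble of per-age-group contributions (empty for summary routes).
#' @method tidy lifetime_risk
#' @export
tidy.lifetime_risk <- function(x, ...) {
  x$contributions
}

#' One-row summary of a lifetime risk
#'
#' @param x A `lifetime_risk`.
#' @param ... Unused.
#' @return A tibble with `event`, `route`, `value`, `percent`, `n`, `label`.
#' @method glance lifetime_risk
#' @export
glance.lifetime_risk <- function(x, ...) {
  r <- one_in_n(x$value)
  tibble::tibble(event = x$event, route = x$route, value = x$value,
                 percent = 100 * x$value, n = r$n, label = r$label)
}

#' Plot per-age contributions to a lifetime risk
#'
#' @param object A `lifetime_risk` computed by the age-specific route.
#' @param ... Unused.
#' @return A ggplot: contribution per five-year age group.
#' @method autoplot lifetime_risk
#' @export
autoplot.lifetime_risk <- function(object, ...) {
  if (nrow(object$contributions) == 0) {
    abort_usage("Only age-specific lifetime risks have per-age contributions to plot.")
  }
  df <- object$contributions |>
    dplyr::mutate(group = sprintf("%d–%d", .data$age_start,
                                  .data$age_start + .data$age_interval - 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$contribution)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Age group (years)", y = "Contribution to lifetime risk",
      title = sprintf("Lifetime risk %.4f (%s)", object$value,
                      one_in_n(object$value)$label)
    ) +
    ggplot2::theme_minimal()
}
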