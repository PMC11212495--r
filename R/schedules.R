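# Demographic input containers: abridged life table, fertility schedule,
# morbidity (near miss / maternal death) schedule, summary inputs.
# All are validated tibbles so they compose with dplyr verbs; rates and
# ratios are normalised to pure proportions exactly once, at construction.

#' Construct an abridged female life table
#'
#' Validates and classes a data frame holding an abridged (5-year) female
#' life table: survivors `lx` at exact age `age_start` and person-years
#' `Lx` lived in `[age_start, age_start + age_interval)`, on a radix `l0`
#' (default 100 000).  The table may extend below 15 and above 50; lifetime
#' risk computations use the reproductive rows and `lx` at exact age 15.
#'
#' `lx` may be `NA` for ages where survivorship is not reported (published
#' worked examples often print only \eqn{l_{15}}); consistency checks
#' (`lx` non-increasing, \eqn{n\,l_{x+n} \le L_x \le n\,l_x}) are applied
#' wherever the needed values are present.
#'
#' @param data Data frame with columns `age_start`, `age_interval`, `lx`, `Lx`.
#' @param radix Life-table radix `l0` in persons.
#' @return A tibble of class `ltr_life_table` with a `radix` attribute.
#' @export
#' @examples
#' lt <- life_table(data.frame(
#'   age_start = c(15, 20), age_interval = 5,
#'   lx = c(95283, NA), Lx = c(474931.6, 470667.4)
#' ))
#' survival_weights(lt)
life_table <- function(data, radix = 1e5) {
  data <- tibble::as_tibble(data)
  need <- c("age_start", "age_interval", "lx", "Lx")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort_input(sprintf("Life table is missing column(s): %s.",
                        paste(miss, collapse = ", ")))
  }
  if (!is.numeric(radix) || length(radix) != 1 || radix <= 0) {
    abort_input("`radix` must be a single positive number.")
  }
  assert_contiguous_grid(data$age_start, data$age_interval, "life table")
  data <- dplyr::select(data, dplyr::all_of(need))
  validate_life_table(data, radix)
  structure(data, class = c("ltr_life_table", class(data)), radix = radix)
}

#' Validate life-table consistency
#'
#' Checks the survivorship and person-years invariants of an abridged life
#' table, reporting the offending age for each failure.
#'
#' @param data Life-table data frame (columns `age_start`, `age_interval`,
#'   `lx`, `Lx`).
#' @param radix Radix `l0`.
#' @return Invisibly `TRUE`; errors with class `ltrmnm_error_input` otherwise.
#' @export
validate_life_table <- function(data, radix = attr(data, "radix") %||% 1e5) {
  lx <- data$lx
  Lx <- data$Lx
  n <- data$age_interval
  if (any(!is.na(lx) & (lx < 0 | lx > radix))) {
    bad <- data$age_start[!is.na(lx) & (lx < 0 | lx > radix)]
    abort_input(sprintf("lx outside [0, radix] at age(s) %s.",
                        paste(bad, collapse = ", ")))
  }
  if (any(is.na(Lx)) || any(Lx < 0)) {
    abort_input(sprintf("Lx must be non-negative and complete (age(s) %s).",
                        paste(data$age_start[is.na(Lx) | Lx < 0], collapse = ", ")))
  }
  obs <- which(!is.na(lx))
  if (length(obs) > 1) {
    d <- diff(lx[obs])
    if (any(d > 1e-9 * radix)) {
      bad <- data$age_start[obs[-1][d > 1e-9 * radix]]
      abort_input(sprintf("Survivors lx increase at age(s) %s; lx must be non-increasing.",
                          paste(bad, collapse = ", ")))
    }
  }
  # n*l(x+n) <= L(x,n) <= n*l(x), checked where both endpoints are observed
  tol <- 1e-9 * radix
  for (i in seq_len(nrow(data))) {
    lo_ok <- TRUE
    hi_ok <- TRUE
    if (!is.na(lx[i])) hi_ok <- Lx[i] <= n[i] * lx[i] + tol
    j <- which(data$age_start == data$age_start[i] + n[i])
    if (length(j) == 1 && !is.na(lx[j])) lo_ok <- Lx[i] >= n[i] * lx[j] - tol
    if (!lo_ok || !hi_ok) {
      abort_input(sprintf(
        "Person-years L(%s,%s) = %s violate n*l(x+n) <= L <= n*l(x).",
        data$age_start[i], n[i], format(Lx[i])))
    }
  }
  invisible(TRUE)
}

#' @export
print.ltr_life_table <- function(x, ...) {
  cat(sprintf("Abridged female life table (radix l0 = %s)\n",
              format(attr(x, "radix"), big.mark = " ")))
  NextMethod()
}

#' Life-table radix
#'
#' @param lt A `ltr_life_table`.
#' @return The radix `l0` in persons.
#' @export
lt_radix <- function(lt) {
  attr(lt, "radix") %||% 1e5
}

#' Survivors at an exact age
#'
#' @param lt A `ltr_life_table`.
#' @param age Exact age in years (must be the start of a tabulated group).
#' @return `lx` at that age.
#' @export
survivors_at <- function(lt, age) {
  i <- which(lt$age_start == age)
  if (length(i) != 1 || is.na(lt$lx[i])) {
    abort_input(sprintf("Life table does not report survivors lx at exact age %s.", age))
  }
  lt$lx[i]
}

#' Expected years lived per reproductive age group, given survival to 15
#'
#' For each requested group returns \eqn{L_{x,n} / l_{15}}: the expected
#' number of years a girl who reaches her 15th birthday lives in the
#' interval \eqn{[x, x+n)}.  These weights carry the all-cause mortality
#' adjustment of the lifetime-risk estimators.
#'
#' @param lt A `ltr_life_table` with `lx` reported at exact age 15.
#' @param ages Start ages of the groups wanted (default: the reproductive grid).
#' @return A tibble with `age_start`, `age_interval`, `weight` (years).
#' @export
#' @examples
#' lt <- life_table(data.frame(age_start = 15, age_interval = 5,
#'                             lx = 100, Lx = 500), radix = 100)
#' survival_weights(lt)  # no mortality in the interval: weight = 5
survival_weights <- function(lt, ages = reproductive_grid()$age_start) {
  l15 <- survivors_at(lt, 15)
  if (l15 <= 0) abort_input("l(15) must be positive to compute survival weights.")
  miss <- setdiff(ages, lt$age_start)
  if (length(miss) > 0) {
    abort_input(sprintf("Life table has no group(s) starting at age(s) %s.",
                        paste(miss, collapse = ", ")))
  }
  lt |>
    dplyr::filter(.data$age_start %in% ages) |>
    dplyr::transmute(.data$age_start, .data$age_interval,
                     weight = .data$Lx / l15)
}

#' Survival weight of a single age group
#'
#' @inheritParams survival_weights
#' @param age_start Start age of the group.
#' @return `L(x,n)/l(15)` in years (scalar).
#' @export
survival_weight <- function(lt, age_start) {
  survival_weights(lt, ages = age_start)$weight
}

#' Construct an age-specific fertility schedule
#'
#' @param data Data frame with columns `age_start`, `age_interval`, `asfr`.
#'   A `units` column, if present, overrides the `units` argument.
#' @param units Units of the supplied rates: `"per_woman"` (live births per
#'   woman-year, stored as-is) or `"per_1000"` (per 1000 woman-years,
#'   divided by 1000 on input).  Normalisation happens exactly once, here.
#' @return A tibble of class `ltr_fertility`, `asfr` in births per woman-year.
#' @export
#' @examples
#' fertility_schedule(
#'   data.frame(age_start = seq(15, 45, 5), age_interval = 5,
#'              asfr = c(66.9, 154.3, 160, 140.9, 103.9, 45.6, 11.2)),
#'   units = "per_1000"
#' )
fertility_schedule <- function(data, units = c("per_woman", "per_1000")) {
  data <- tibble::as_tibble(data)
  if ("units" %in% names(data)) {
    u <- unique(data$units)
    if (length(u) != 1) abort_input("Mixed `units` values in fertility schedule.")
    units <- u
    data$units <- NULL
  }
  units <- rlang::arg_match(units, c("per_woman", "per_1000"))
  need <- c("age_start", "age_interval", "asfr")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort_input(sprintf("Fertility schedule is missing column(s): %s.",
                        paste(miss, collapse = ", ")))
  }
  assert_contiguous_grid(data$age_start, data$age_interval, "fertility schedule")
  if (any(!is.finite(data$asfr)) || any(data$asfr < 0)) {
    abort_input("Fertility rates must be finite and non-negative.")
  }
  scale <- if (units == "per_1000") 1000 else 1
  out <- dplyr::transmute(data, .data$age_start, .data$age_interval,
                          asfr = .data$asfr / scale)
  structure(out, class = c("ltr_fertility", class(out)))
}

#' Construct a morbidity (near miss or maternal death) schedule
#'
#' Holds per-age-group event counts, live births and/or ratios for maternal
#' near miss (MNM) or maternal death events.  Ratios are stored as pure
#' proportions (events per live birth); `per_1000` and `per_100000` input
#' dialects are normalised on construction.  When only counts are supplied
#' the ratio is derived as `cases / live_births`; when both are supplied
#' they are checked for consistency (published tables carry rounded values,
#' so the check uses `count_tol` relative tolerance).
#'
#' @param data Data frame with `age_start`, `age_interval` and at least one
#'   of (`cases` and `live_births`) or `ratio`.
#' @param units Units of a supplied `ratio` column: `"per_birth"`,
#'   `"per_1000"` or `"per_100000"`.
#' @param event Event kind label: `"mnm"`, `"maternal_death"` or `"smo"`.
#'   The label does not change the structure, only downstream semantics.
#' @param count_tol Relative tolerance for the cases/live_births vs ratio
#'   consistency check (default 5%, accommodating printed rounding).
#' @return A tibble of class `ltr_morbidity` with attribute `event`;
#'   columns `age_start`, `age_interval`, `cases`, `live_births`, `ratio`
#'   (proportion).
#' @export
#' @examples
#' morbidity_schedule(
#'   data.frame(age_start = seq(15, 45, 5), age_interval = 5,
#'              cases = c(68, 82, 107, 143, 91, 44, 11),
#'              live_births = c(7939, 18050, 18241, 12772, 7492, 2895, 612))
#' )
morbidity_schedule <- function(data,
                               units = c("per_birth", "per_1000", "per_100000"),
                               event = c("mnm", "maternal_death", "smo"),
                               count_tol = 0.05) {
  data <- tibble::as_tibble(data)
  if ("units" %in% names(data)) {
    u <- unique(data$units)
    if (length(u) != 1) abort_input("Mixed `units` values in morbidity schedule.")
    units <- u
    data$units <- NULL
  }
  units <- rlang::arg_match(units, c("per_birth", "per_1000", "per_100000"))
  event <- rlang::arg_match(event)
  need <- c("age_start", "age_interval")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort_input(sprintf("Morbidity schedule is missing column(s): %s.",
                        paste(miss, collapse = ", ")))
  }
  assert_contiguous_grid(data$age_start, data$age_interval, "morbidity schedule")
  has_counts <- all(c("cases", "live_births") %in% names(data))
  has_ratio <- "ratio" %in% names(data)
  if (!has_counts && !has_ratio) {
    abort_input("Morbidity schedule needs `cases` + `live_births` and/or `ratio`.")
  }
  scale <- c(per_birth = 1, per_1000 = 1000, per_100000 = 1e5)[[units]]
  ratio <- if (has_ratio) data$ratio / scale else NULL
  if (has_counts) {
    if (any(data$cases < 0)) abort_input("Event counts must be non-negative.")
    if (any(data$live_births <= 0)) {
      abort_input(sprintf("live_births must be positive (age(s) %s).",
                          paste(data$age_start[data$live_births <= 0], collapse = ", ")))
    }
    derived <- data$cases / data$live_births
    if (is.null(ratio)) {
      ratio <- derived
    } else {
      # allow printed rounding (relative) plus one event of integer rounding
      tol <- count_tol * pmax(derived, .Machine$double.eps) +
        0.5 / data$live_births
      bad <- which(derived > 0 & abs(ratio - derived) > tol)
      if (length(bad) > 0) {
        abort_input(sprintf(
          "ratio disagrees with cases/live_births beyond tolerance at age(s) %s.",
          paste(data$age_start[bad], collapse = ", ")))
      }
    }
  }
  if (any(!is.finite(ratio)) || any(ratio < 0)) {
    abort_input("Morbidity ratios must be finite and non-negative.")
  }
  out <- tibble::tibble(
    age_start = data$age_start,
    age_interval = data$age_interval,
    cases = if (has_counts) data$cases else NA_real_,
    live_births = if (has_counts) data$live_births else NA_real_,
    ratio = ratio
  )
  structure(out, class = c("ltr_morbidity", class(out)), event = event)
}

#' Event kind of a morbidity schedule or lifetime-risk object
#'
#' @param x A `ltr_morbidity` or `lifetime_risk` object.
#' @return `"mnm"`, `"maternal_death"` or `"smo"`.
#' @export
event_kind <- function(x) {
  attr(x, "event") %||% x$event
}

#' Net reproduction rate from fertility and survivorship schedules
#'
#' Computes the NRR (expected daughters per woman under period rates)
#' as \deqn{NRR = \sum_g f_g \frac{L_g}{l_0} \frac{100}{100 + SRB},}
#' where the sex ratio at birth `srb` (boys per 100 girls) converts
#' all-births fertility to daughter-only fertility.
#'
#' @param lt A `ltr_life_table`.
#' @param fert A `ltr_fertility` on the reproductive grid.
#' @param srb Sex ratio at birth, boys per 100 girls.
#' @return NRR, daughters per woman (scalar).
#' @export
nrr_from_schedules <- function(lt, fert, srb) {
  if (!is.numeric(srb) || length(srb) != 1 || srb <= 0) {
    abort_input("`srb` must be a single positive number (boys per 100 girls).")
  }
  ltg <- dplyr::filter(lt, .data$age_start %in% fert$age_start)
  assert_grid_aligned(fert, ltg, "fertility schedule", "life table reproductive rows")
  sum(fert$asfr * ltg$Lx / lt_radix(lt)) * 100 / (100 + srb)
}

#' Bundle the scalar inputs of the summary (NRR shortcut) estimator
#'
#' @param aggregate_ratio Events per live birth for ages 15-49 combined
#'   (interpreted through `units`).
#' @param nrr Net reproduction rate, daughters per woman.
#' @param srb Sex ratio at birth, boys per 100 girls.
#' @param l0 Life-table radix, persons.
#' @param l15 Survivors at exact age 15, persons.
#' @param units Units of `aggregate_ratio`.
#' @return A list of class `ltr_summary_inputs` with the ratio as a proportion.
#' @export
#' @examples
#' summary_inputs(8.03, nrr = 1.554, srb = 101, l15 = 95283, units = "per_1000")
summary_inputs <- function(aggregate_ratio, nrr, srb, l0 = 1e5, l15,
                           units = c("per_birth", "per_1000", "per_100000")) {
  units <- rlang::arg_match(units)
  scale <- c(per_birth = 1, per_1000 = 1000, per_100000 = 1e5)[[units]]
  ratio <- aggregate_ratio / scale
  if (ratio < 0) abort_input("`aggregate_ratio` must be non-negative.")
  if (nrr < 0) abort_input("`nrr` must be non-negative.")
  if (srb <= 0) abort_input("`srb` must be positive.")
  if (l15 <= 0) abort_input("`l15` must be positive.")
  if (l0 <= 0) abort_input("`l0` must be positive.")
  structure(list(aggregate_ratio = ratio, nrr = nrr, srb = srb,
                 l0 = l0, l15 = l15),
            class = "ltr_summary_inputs")
}
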