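# Shared helpers: error signalling, rounding conventions, grid checks.

abort_input <- function(msg, ...) {
  abort(msg, class = "ltrmnm_error_input", ...)
}

abort_grid <- function(msg, ...) {
  abort(msg, class = "ltrmnm_error_grid", ...)
}

abort_usage <- function(msg, ...) {
  abort(msg, class = "ltrmnm_error_usage", ...)
}

abort_domain <- function(msg, ...) {
  abort(msg, class = "ltrmnm_error_domain", ...)
}

# round() uses round-half-even; demographic tables round half away from zero.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' The default reproductive age grid
#'
#' Seven contiguous five-year age groups spanning exact ages 15 to 50, the
#' grid on which reproductive-age schedules (fertility, near miss ratios)
#' are defined.
#'
#' @return A tibble with columns `age_start` and `age_interval`.
#' @export
#' @examples
#' reproductive_grid()
reproductive_grid <- function() {
  tibble::tibble(age_start = seq(15, 45, by = 5), age_interval = 5L)
}

# Strict grid equality: same (start, length) pairs in the same order.
assert_grid_aligned <- function(a, b, what_a = "first input", what_b = "second input") {
  ga <- paste(a$age_start, a$age_interval, sep = "+")
  gb <- paste(b$age_start, b$age_interval, sep = "+")
  if (length(ga) != length(gb) || any(ga != gb)) {
    bad <- union(setdiff(ga, gb), setdiff(gb, ga))
    abort_grid(c(
      sprintf("Age grids of %s and %s do not align.", what_a, what_b),
      x = sprintf("Offending groups (start+interval): %s",
                  paste(bad, collapse = ", "))
    ))
  }
  invisible(TRUE)
}

assert_contiguous_grid <- function(age_start, age_interval, what = "schedule") {
  ord <- order(age_start)
  if (any(ord != seq_along(age_start))) {
    abort_input(sprintf("Age groups of %s must be in ascending order.", what))
  }
  if (anyDuplicated(age_start) > 0) {
    abort_input(sprintf("Duplicated age groups in %s.", what))
  }
  if (length(age_start) > 1) {
    gaps <- age_start[-1] - (age_start[-length(age_start)] +
                               age_interval[-length(age_interval)])
    if (any(gaps != 0)) {
      abort_input(c(
        sprintf("Age groups of %s must be contiguous and non-overlapping.", what),
        x = sprintf("Gap or overlap after age %s.",
                    paste(age_start[which(gaps != 0)], collapse = ", "))
      ))
    }
  }
  invisible(TRUE)
}

# Parse "15-19" / "15–19" style labels to start ages (convenience only;
# files use explicit age_start + age_interval).
parse_age_label <- function(x) {
  as.numeric(sub("^\\s*(\\d+).*$", "\\1", x))
}
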