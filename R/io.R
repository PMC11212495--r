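# CSV readers/writers for the three input dialects, plus the embedded
# Namibia 2019 worked-example fixture.  All readers validate on load; all
# writers produce files the readers accept unchanged (dialect closure).

read_dialect_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort_input(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!is.null(col_map)) {
    # col_map: c(age_start = "AgeGrpStart", ...) mapping our names to theirs
    present <- col_map[col_map %in% names(df)]
    df <- dplyr::rename(df, !!!as.list(present))
  }
  if ("age_group" %in% names(df) && !"age_start" %in% names(df)) {
    df$age_start <- parse_age_label(df$age_group)
  }
  df
}

scan_radix_comment <- function(path) {
  head_lines <- readLines(path, n = 5L, warn = FALSE)
  m <- grep("^#\\s*radix\\s*:", head_lines, value = TRUE)
  if (length(m) == 0) return(NULL)
  as.numeric(sub("^#\\s*radix\\s*:\\s*", "", m[1]))
}

#' Read an abridged life table from CSV
#'
#' Expects columns `age_start`, `age_interval`, `lx`, `Lx`.  The radix can
#' be declared in a `# radix: <n>` comment line (as written by
#' [write_life_table()]) or passed explicitly; it defaults to 100 000.
#' World Population Prospects exports can be mapped with `col_map`, e.g.
#' `c(age_start = "AgeGrpStart", age_interval = "AgeGrpSpan", lx = "lx", Lx = "Lx")`.
#'
#' @param path CSV path.
#' @param radix Radix override; `NULL` reads the comment line / default.
#' @param col_map Named character vector mapping this package's column
#'   names to the file's column names.
#' @return A validated [life_table()].
#' @export
read_life_table <- function(path, radix = NULL, col_map = NULL) {
  df <- read_dialect_csv(path, col_map)
  radix <- radix %||% scan_radix_comment(path) %||% 1e5
  life_table(df, radix = radix)
}

#' Write a life table to CSV
#'
#' @param lt A [life_table()].
#' @param path Output path.  The radix is recorded as a `# radix:` comment.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  writeLines(sprintf("# radix: %s", format(lt_radix(lt), scientific = FALSE)),
             path)
  readr::write_csv(as.data.frame(lt), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a fertility schedule from CSV
#'
#' Expects `age_start`, `age_interval`, `asfr` and a `units` column (or the
#' `units` argument) declaring `per_woman` or `per_1000`.
#'
#' @inheritParams read_life_table
#' @param units Unit dialect when the file has no `units` column.
#' @return A validated [fertility_schedule()].
#' @export
read_fertility <- function(path, units = "per_woman", col_map = NULL) {
  fertility_schedule(read_dialect_csv(path, col_map), units = units)
}

#' Write a fertility schedule to CSV
#'
#' @param fert A [fertility_schedule()] (rates are written per woman-year).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fertility <- function(fert, path) {
  df <- dplyr::mutate(as.data.frame(fert), units = "per_woman")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a morbidity schedule from CSV
#'
#' Expects `age_start`, `age_interval` and `cases` + `live_births` and/or
#' `ratio`, with a `units` column or argument declaring the ratio dialect
#' (`per_birth`, `per_1000`, `per_100000`).
#'
#' @inheritParams read_life_table
#' @param units Ratio unit dialect when the file has no `units` column.
#' @param event Event kind label for the schedule.
#' @param count_tol Passed to [morbidity_schedule()].
#' @return A validated [morbidity_schedule()].
#' @export
read_morbidity <- function(path, units = "per_birth", event = "mnm",
                           col_map = NULL, count_tol = 0.05) {
  morbidity_schedule(read_dialect_csv(path, col_map), units = units,
                     event = event, count_tol = count_tol)
}

#' Write a morbidity schedule to CSV
#'
#' @param morb A [morbidity_schedule()] (ratios written as proportions,
#'   `units = per_birth`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_morbidity <- function(morb, path) {
  df <- dplyr::mutate(as.data.frame(morb), units = "per_birth")
  readr::write_csv(df, path)
  invisible(path)
}

#' Load an embedded worked-example fixture
#'
#' `"namibia2019"` is the Namibia 2019 worked example: the simulated
#' J-shaped near miss schedule (546 cases over 68 001 live births,
#' aggregate ratio 8.03 per 1000), World Population Prospects fertility
#' and survivorship columns (l15 = 95 283 on a radix of 100 000), and the
#' published scalars used by the shortcut route — NRR 1.554, SRB 101,
#' stillbirth rate 17.68 per 1000 total births, maternal mortality ratio
#' 223 per 100 000 live births, and the published lifetime risk of
#' maternal death 0.00702 (whose unrounded inputs are not recoverable, so
#' it is carried as a published scalar, not recomputed).
#'
#' @param name Fixture name; currently only `"namibia2019"`.
#' @return A list of class `ltr_bundle`: `life_table`, `fertility`,
#'   `morbidity`, `srb`, `nrr`, `aggregate_ratio`, `stillbirth_rate`,
#'   `mm_ratio`, `ltr_md_published`, `source`.
#' @export
#' @examples
#' b <- load_fixture("namibia2019")
#' sum(b$morbidity$cases)  # 546
load_fixture <- function(name = "namibia2019") {
  if (!identical(name, "namibia2019")) {
    abort_usage(sprintf("Unknown fixture '%s'; available: namibia2019.", name))
  }
  p <- function(f) system.file("extdata", f, package = "ltrmnm", mustWork = TRUE)
  morb <- read_morbidity(p("namibia2019_mnm.csv"), event = "mnm")
  structure(
    list(
      life_table = read_life_table(p("namibia2019_lifetable.csv")),
      fertility = read_fertility(p("namibia2019_fertility.csv")),
      morbidity = morb,
      srb = 101,
      nrr = 1.554,
      aggregate_ratio = sum(morb$cases) / sum(morb$live_births),
      stillbirth_rate = 17.68,
      mm_ratio = 223 / 1e5,
      ltr_md_published = 0.00702,
      seed = NULL,
      source = "namibia2019"
    ),
    class = "ltr_bundle"
  )
}
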