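# Readers and writers for the tabular input/output schemas.

guess_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("csv", "json", "yaml")))
  switch(tolower(tools::file_ext(path)),
    csv = "csv",
    json = "json",
    yaml = ,
    yml = "yaml",
    abort(sprintf("cannot infer format from path '%s'; pass `format`", path))
  )
}

#' Read and write therapy tables
#'
#' The on-disk schema is one record per (therapy, subgroup) with fields
#' `therapy`, `is_new_entrant`, `history`, `subtype`, `cirrhosis`, `cost_1`,
#' `cost_2`, `weeks_1`, `weeks_2`, `svr_low`, `svr_high`, `eligible`
#' (CSV columns, or an array of objects in JSON/YAML). Reading validates via
#' [validate_therapies()]; parse failures and invariant violations raise
#' errors naming the offending record.
#'
#' @param path File path.
#' @param format `"csv"`, `"json"` or `"yaml"`; inferred from the extension
#'   when omitted.
#' @param therapies A validated therapy tibble.
#' @return `read_therapies()` returns the validated tibble;
#'   `write_therapies()` returns `path` invisibly.
#' @export
read_therapies <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  format <- guess_format(path, format)
  df <- switch(format,
    csv = readr::read_csv(path,
      col_types = readr::cols(
        therapy = readr::col_character(),
        is_new_entrant = readr::col_logical(),
        history = readr::col_character(),
        subtype = readr::col_character(),
        cirrhosis = readr::col_character(),
        eligible = readr::col_logical(),
        .default = readr::col_double()
      )
    ),
    json = as_tibble(jsonlite::fromJSON(path)),
    yaml = yaml::read_yaml(path) |>
      purrr::map(\(rec) as_tibble(purrr::map(rec, \(v) if (is.null(v)) NA else v))) |>
      purrr::list_rbind()
  )
  num_cols <- c("cost_1", "cost_2", "weeks_1", "weeks_2", "svr_low", "svr_high")
  for (nm in setdiff(num_cols, names(df))) df[[nm]] <- NA_real_ # all-NA, elided on write
  df <- df |>
    mutate(across(dplyr::all_of(num_cols), as.numeric)) |>
    select(
      "therapy", "is_new_entrant", "history", "subtype", "cirrhosis",
      dplyr::all_of(num_cols), "eligible", dplyr::everything()
    )
  validate_therapies(df)
}

#' @rdname read_therapies
#' @export
write_therapies <- function(therapies, path, format = NULL) {
  therapies <- validate_therapies(therapies)
  format <- guess_format(path, format)
  switch(format,
    csv = readr::write_csv(therapies, path, na = ""),
    json = jsonlite::write_json(therapies, path,
      dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA
    ),
    yaml = yaml::write_yaml(
      purrr::pmap(therapies, \(...) {
        rec <- list(...)
        rec[!vapply(rec, \(v) length(v) == 1 && is.na(v), logical(1))]
      }),
      path
    )
  )
  invisible(path)
}

#' Read and write population specifications
#'
#' Stored as a JSON or YAML mapping with keys `total_min`, `total_max`,
#' `subtype_props`, `history_props`, `cirrhosis_prop`, `include_naive`.
#'
#' @param path File path.
#' @param format `"json"` or `"yaml"`; inferred from the extension if omitted.
#' @param pop A [population_spec()].
#' @return `read_population()` returns a validated `ce_population`.
#' @export
read_population <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  format <- guess_format(path, format)
  if (format == "csv") abort("population specs are stored as JSON or YAML")
  raw <- switch(format,
    json = jsonlite::fromJSON(path),
    yaml = yaml::read_yaml(path)
  )
  population_spec(
    total_min = raw$total_min,
    total_max = raw$total_max,
    subtype_props = unlist(raw$subtype_props),
    history_props = unlist(raw$history_props),
    cirrhosis_prop = raw$cirrhosis_prop,
    include_naive = isTRUE(raw$include_naive)
  )
}

#' @rdname read_population
#' @export
write_population <- function(pop, path, format = NULL) {
  validate_population(pop)
  format <- guess_format(path, format)
  payload <- list(
    total_min = pop$total_min,
    total_max = pop$total_max,
    subtype_props = as.list(pop$subtype_props),
    history_props = as.list(pop$history_props),
    cirrhosis_prop = pop$cirrhosis_prop,
    include_naive = pop$include_naive
  )
  switch(format,
    json = jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA),
    yaml = yaml::write_yaml(payload, path),
    abort("population specs are stored as JSON or YAML")
  )
  invisible(path)
}

#' Write a tidy result table
#'
#' Writes any result tibble from the pipeline as tidy CSV. Monetary columns
#' (any column whose name contains `cost`, `savings`, `icer` or
#' `expenditure`) keep their raw values and additionally get a
#' `<name>_display` column rounded to the reporting granularity, matching how
#' the case study displays euro amounts at the nearest 100. An empty result
#' writes a header-only file.
#'
#' @param results A tibble.
#' @param path Output CSV path.
#' @param rounding Display granularity in euro (default 100).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, rounding = 100) {
  results <- as_tibble(results)
  money <- grepl("cost|savings|icer|expenditure", names(results)) &
    vapply(results, is.numeric, logical(1)) &
    !grepl("_display$|pct|percent", names(results))
  for (nm in names(results)[money]) {
    results[[paste0(nm, "_display")]] <- round_money(results[[nm]], rounding)
  }
  readr::write_csv(results, path, na = "")
  invisible(path)
}
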