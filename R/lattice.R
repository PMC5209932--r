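# The patient subgroup lattice: treatment history x GT1 subtype x cirrhosis.

ce_histories <- function() {
  c("naive", "relapser", "partial_responder", "null_responder")
}

ce_subtypes <- function() c("GT1a", "GT1b")

ce_cirrhosis <- function() c("none", "compensated")

#' Patient subgroup lattice
#'
#' The analysis stratifies HCV genotype 1 patients by treatment history
#' (naive, relapser, partial responder, null responder), GT1 subtype
#' (GT1a, which also absorbs mixed/unknown subtype infections, and GT1b)
#' and cirrhosis status (none or compensated), giving a 4 x 2 x 2 lattice
#' of 16 unique subgroups. The 12 treatment-experienced cells form the
#' population of the budget impact and scenario analyses; naive cells
#' appear only in the cost-effectiveness tables.
#'
#' @param experienced_only If `TRUE`, drop the four naive cells.
#'
#' @return A tibble with columns `history`, `subtype` and `cirrhosis`,
#'   one row per subgroup, in a fixed canonical order.
#' @export
#' @examples
#' subgroup_lattice()
subgroup_lattice <- function(experienced_only = FALSE) {
  grid <- tidyr::expand_grid(
    history = ce_histories(),
    subtype = ce_subtypes(),
    cirrhosis = ce_cirrhosis()
  )
  if (experienced_only) {
    grid <- dplyr::filter(grid, history != "naive")
  }
  grid
}

# Compact single-string key for a subgroup, used for joins and list names.
subgroup_key <- function(history, subtype, cirrhosis) {
  paste(history, subtype, cirrhosis, sep = "|")
}

# Human-readable label, used in plots and error messages.
subgroup_label <- function(history, subtype, cirrhosis) {
  hist <- c(
    naive = "naive", relapser = "relapser",
    partial_responder = "partial responder", null_responder = "null responder"
  )[history]
  cirr <- ifelse(cirrhosis == "compensated", "CC", "no cirrhosis")
  paste0(hist, ", ", subtype, ", ", cirr)
}

assert_subgroup_cols <- function(df, what = "input") {
  needed <- c("history", "subtype", "cirrhosis")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing subgroup column(s): %s", what,
      paste(missing, collapse = ", ")
    ))
  }
  bad_h <- setdiff(unique(df$history), ce_histories())
  bad_s <- setdiff(unique(df$subtype), ce_subtypes())
  bad_c <- setdiff(unique(df$cirrhosis), ce_cirrhosis())
  if (length(c(bad_h, bad_s, bad_c)) > 0) {
    abort(sprintf(
      "%s contains unknown subgroup level(s): %s", what,
      paste(c(bad_h, bad_s, bad_c), collapse = ", ")
    ))
  }
  invisible(df)
}
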