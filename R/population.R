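#' Annual patient population specification
#'
#' Describes the yearly pool of patients eligible for treatment: a range for
#' the annual total and independent composition proportions over the subgroup
#' lattice. The scenario and budget impact analyses draw the total uniformly
#' on `total_min:total_max` each run and allocate it to subgroup cells with a
#' single multinomial draw whose cell probabilities are the product
#' `subtype x history x cirrhosis` (independence assumption).
#'
#' By default only treatment-experienced patients are modelled
#' (`include_naive = FALSE`): naive patients stay on the standard of care and
#' are excluded from the budget impact analysis, though they do appear in the
#' cost-effectiveness tables, which do not use the population at all.
#'
#' @param total_min,total_max Bounds (inclusive) of the annual patient count.
#' @param subtype_props Named proportions over `c("GT1a", "GT1b")`.
#' @param history_props Named proportions over the experienced histories
#'   `c("relapser", "partial_responder", "null_responder")` (plus `"naive"`
#'   when `include_naive = TRUE`).
#' @param cirrhosis_prop Proportion with compensated cirrhosis.
#' @param include_naive Whether naive patients are part of the simulated pool.
#'
#' @return An object of class `ce_population`.
#' @seealso [croatia_gt1_population()] for the case study defaults,
#'   [draw_population()] for the per-run draw.
#' @export
population_spec <- function(total_min,
                            total_max,
                            subtype_props,
                            history_props,
                            cirrhosis_prop,
                            include_naive = FALSE) {
  pop <- structure(
    list(
      total_min = as.integer(total_min),
      total_max = as.integer(total_max),
      subtype_props = subtype_props,
      history_props = history_props,
      cirrhosis_prop = cirrhosis_prop,
      include_naive = isTRUE(include_naive)
    ),
    class = "ce_population"
  )
  validate_population(pop)
  pop
}

#' Validate a population specification
#'
#' Checks the invariants of a [population_spec()]: positive integer total
#' bounds with `total_min <= total_max`, proportion sets that sum to one
#' (within 1e-9) over the expected category names, and a cirrhosis proportion
#' in `[0, 1]`.
#'
#' @param pop A `ce_population` object.
#' @return `pop`, invisibly; aborts with an informative message otherwise.
#' @export
validate_population <- function(pop) {
  if (!inherits(pop, "ce_population")) abort("not a `ce_population` object")
  if (is.na(pop$total_min) || is.na(pop$total_max) ||
      pop$total_min < 1 || pop$total_min > pop$total_max) {
    abort("population total range must satisfy 1 <= total_min <= total_max")
  }
  check_props <- function(p, levels, what) {
    if (!all(sort(names(p)) == sort(levels))) {
      abort(sprintf(
        "%s must be named proportions over {%s}", what,
        paste(levels, collapse = ", ")
      ))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(sprintf(
        "%s must be non-negative and sum to 1 (got %.10f)", what, sum(p)
      ))
    }
  }
  check_props(pop$subtype_props, ce_subtypes(), "`subtype_props`")
  hist_levels <- setdiff(ce_histories(), if (pop$include_naive) character() else "naive")
  check_props(pop$history_props, hist_levels, "`history_props`")
  if (pop$cirrhosis_prop < 0 || pop$cirrhosis_prop > 1) {
    abort("`cirrhosis_prop` must be in [0, 1]")
  }
  invisible(pop)
}

#' @export
print.ce_population <- function(x, ...) {
  cat("<ce_population>\n")
  cat(sprintf("  annual total: %d-%d patients\n", x$total_min, x$total_max))
  cat(
    "  subtype:", paste(sprintf("%s %.0f%%", names(x$subtype_props), 100 * x$subtype_props),
      collapse = ", "
    ), "\n"
  )
  cat(
    "  history:", paste(sprintf("%s %.0f%%", names(x$history_props), 100 * x$history_props),
      collapse = ", "
    ), "\n"
  )
  cat(sprintf("  compensated cirrhosis: %.0f%%\n", 100 * x$cirrhosis_prop))
  cat(sprintf("  naive included: %s\n", x$include_naive))
  invisible(x)
}

# Per-cell allocation probabilities as a tibble over the modelled lattice.
population_cell_probs <- function(pop) {
  validate_population(pop)
  grid <- subgroup_lattice(experienced_only = !pop$include_naive)
  grid |>
    mutate(
      prob = unname(pop$history_props[.data$history]) *
        unname(pop$subtype_props[.data$subtype]) *
        ifelse(.data$cirrhosis == "compensated",
          pop$cirrhosis_prop, 1 - pop$cirrhosis_prop
        )
    )
}
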