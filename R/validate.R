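#' Validate a therapy table
#'
#' Checks the structural invariants of a therapy input table:
#' * all subgroup columns present with known levels; each (therapy, subgroup)
#'   pair unique; every therapy covers the full 16-cell lattice;
#' * exactly one therapy flagged as the new entrant, eligible everywhere it
#'   appears;
#' * eligible rows have positive `cost_1`, paired `weeks_1`, and an SVR range
#'   with `0 <= svr_low <= svr_high <= 1` (degenerate ranges, point
#'   estimates, are valid); a second cost variant requires a second duration
#'   and vice versa;
#' * ineligible rows carry no cost/SVR requirements.
#'
#' Errors name the offending (therapy, subgroup, field) cell.
#'
#' @param therapies A therapy tibble (see [croatia_gt1_therapies()] for the
#'   schema).
#' @return The validated table (invisibly usable in pipes).
#' @export
validate_therapies <- function(therapies) {
  therapies <- as_tibble(therapies)
  needed <- c(
    "therapy", "is_new_entrant", "history", "subtype", "cirrhosis",
    "cost_1", "cost_2", "weeks_1", "weeks_2", "svr_low", "svr_high", "eligible"
  )
  missing <- setdiff(needed, names(therapies))
  if (length(missing) > 0) {
    abort(sprintf(
      "therapy table is missing column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  assert_subgroup_cols(therapies, "therapy table")

  dup <- therapies |>
    count(.data$therapy, .data$history, .data$subtype, .data$cirrhosis) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate cell: therapy %s, subgroup %s",
      dup$therapy[1], subgroup_label(dup$history[1], dup$subtype[1], dup$cirrhosis[1])
    ))
  }
  cover <- therapies |> count(.data$therapy)
  if (any(cover$n != 16)) {
    bad <- cover$therapy[cover$n != 16][1]
    abort(sprintf(
      "therapy %s covers %d subgroup cells; the full 16-cell lattice is required",
      bad, cover$n[cover$therapy == bad]
    ))
  }

  entrant_flags <- therapies |>
    distinct(.data$therapy, .data$is_new_entrant)
  if (any(duplicated(entrant_flags$therapy))) {
    abort("`is_new_entrant` must be constant within a therapy")
  }
  if (sum(entrant_flags$is_new_entrant) != 1) {
    abort(sprintf(
      "exactly one therapy must be flagged `is_new_entrant` (found %d)",
      sum(entrant_flags$is_new_entrant)
    ))
  }
  entrant_inelig <- therapies |> filter(.data$is_new_entrant, !.data$eligible)
  if (nrow(entrant_inelig) > 0) {
    r <- entrant_inelig[1, ]
    abort(sprintf(
      "new entrant %s must be eligible in every subgroup; ineligible at %s",
      r$therapy, subgroup_label(r$history, r$subtype, r$cirrhosis)
    ))
  }

  cell_abort <- function(row, field, msg) {
    abort(sprintf(
      "invalid %s for therapy %s, subgroup %s: %s",
      field, row$therapy, subgroup_label(row$history, row$subtype, row$cirrhosis), msg
    ))
  }
  elig <- filter(therapies, .data$eligible)
  for (i in seq_len(nrow(elig))) {
    r <- elig[i, ]
    if (is.na(r$cost_1) || r$cost_1 <= 0) {
      cell_abort(r, "cost_1", "eligible cells need a positive course cost")
    }
    if (is.na(r$weeks_1) || r$weeks_1 <= 0) {
      cell_abort(r, "weeks_1", "eligible cells need a positive duration")
    }
    if (is.na(r$cost_2) != is.na(r$weeks_2)) {
      cell_abort(r, "cost_2/weeks_2", "cost and duration variants must be paired")
    }
    if (!is.na(r$cost_2) && r$cost_2 <= 0) {
      cell_abort(r, "cost_2", "course costs must be positive")
    }
    if (is.na(r$svr_low) || is.na(r$svr_high)) {
      cell_abort(r, "svr", "eligible cells need an SVR range")
    }
    if (r$svr_low < 0 || r$svr_high > 1 || r$svr_low > r$svr_high) {
      cell_abort(
        r, "svr",
        sprintf("need 0 <= low <= high <= 1, got [%g, %g]", r$svr_low, r$svr_high)
      )
    }
  }
  therapies
}

# Rivals admissible for comparison in each subgroup (eligible, not entrant).
eligible_rivals <- function(therapies, experienced_only = FALSE) {
  out <- therapies |> filter(.data$eligible, !.data$is_new_entrant)
  if (experienced_only) out <- filter(out, .data$history != "naive")
  out
}

new_entrant_name <- function(therapies) {
  unique(therapies$therapy[therapies$is_new_entrant])
}
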