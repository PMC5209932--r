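# Takeover-tier classification and scenario (market mix) construction.
#
# Market cells are (subgroup, rival) pairs. Each cell is placed in a tier by
# its simulated savings per SVR, and scenario k (k = 1..4) reassigns to the
# new entrant the baseline shares of every cell with tier <= k:
#   tier 1 - entrant cheaper per SVR in every simulated run (savings min > 0);
#   tier 2 - cheaper on average, but the savings range crosses zero;
#   tier 3 - more expensive on average by at most the tier-3 threshold
#            (EUR 10000 by default, boundary inclusive);
#   tier 4 - everything else (entrant takes these only on full takeover).
# Scenario 0 is the pre-entry baseline. Takeover sets are nested by
# construction: S1 within S2 within S3 within S4 = all cells.

#' Pre-entry baseline market mix
#'
#' The pre-entry split of each experienced subgroup across rival therapies
#' is not published, so it is an explicit modelling choice:
#' `"cheapest_per_svr"` gives the whole subgroup to the eligible rival with
#' the lowest mean cost per SVR (ties broken alphabetically), emulating a
#' payer that already buys the most cost-effective option;
#' `"equal_eligible"` splits the subgroup equally across eligible rivals.
#' The new entrant has zero share in the baseline.
#'
#' @param therapies A validated therapy table.
#' @param ce A [ce_table()] covering all eligible experienced cells (used by
#'   the cheapest strategy).
#' @param strategy `"cheapest_per_svr"` (default) or `"equal_eligible"`.
#' @return A tibble (one row per subgroup x therapy with positive share):
#'   subgroup columns, `therapy`, `share`. Shares sum to 1 per subgroup.
#' @export
baseline_mix <- function(therapies, ce,
                         strategy = c("cheapest_per_svr", "equal_eligible")) {
  strategy <- match.arg(strategy)
  therapies <- validate_therapies(therapies)
  rivals <- eligible_rivals(therapies, experienced_only = TRUE)
  lattice <- subgroup_lattice(experienced_only = TRUE)
  uncovered <- lattice |>
    anti_join(rivals, by = c("history", "subtype", "cirrhosis"))
  if (nrow(uncovered) > 0) {
    r <- uncovered[1, ]
    abort(sprintf(
      "no eligible rival for subgroup %s; a baseline mix needs at least one",
      subgroup_label(r$history, r$subtype, r$cirrhosis)
    ))
  }
  if (strategy == "equal_eligible") {
    return(
      rivals |>
        group_by(.data$history, .data$subtype, .data$cirrhosis) |>
        mutate(share = 1 / dplyr::n()) |>
        ungroup() |>
        select("history", "subtype", "cirrhosis", "therapy", "share") |>
        arrange(.data$history, .data$subtype, .data$cirrhosis, .data$therapy)
    )
  }
  rivals |>
    inner_join(
      ce |>
        as_tibble() |>
        select("therapy", "history", "subtype", "cirrhosis", "mean_cost_per_svr"),
      by = c("therapy", "history", "subtype", "cirrhosis")
    ) |>
    group_by(.data$history, .data$subtype, .data$cirrhosis) |>
    arrange(.data$mean_cost_per_svr, .data$therapy, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(share = 1) |>
    select("history", "subtype", "cirrhosis", "therapy", "share") |>
    arrange(.data$history, .data$subtype, .data$cirrhosis, .data$therapy)
}

#' Classify market cells into takeover tiers
#'
#' Applies the tier rule to a savings table: tier 1 if `savings_min > 0`,
#' tier 2 if `savings_mean > 0` and `savings_min <= 0`, tier 3 if
#' `savings_mean <= 0` and `savings_mean >= -threshold` (boundary
#' inclusive), tier 4 otherwise.
#'
#' @param savings A [savings_table()] (or any tibble with `savings_mean` and
#'   `savings_min` plus cell identifier columns).
#' @param threshold Tier-3 threshold in euro (default 10000).
#' @return The input cells with a `tier` column (integer 1-4).
#' @export
#' @examples
#' classify_tiers(
#'   tibble::tibble(savings_mean = c(5000, 2000, -10000, -10000.01),
#'                  savings_min  = c(1000, -5000, -30000, -30000)))
classify_tiers <- function(savings, threshold = 10000) {
  if (!all(c("savings_mean", "savings_min") %in% names(savings))) {
    abort("`savings` needs `savings_mean` and `savings_min` columns")
  }
  savings |>
    as_tibble() |>
    mutate(
      tier = dplyr::case_when(
        savings_min > 0 ~ 1L,
        savings_mean > 0 ~ 2L,
        savings_mean >= -threshold ~ 3L,
        TRUE ~ 4L
      )
    )
}

#' Build the five takeover scenarios
#'
#' Constructs market mixes for scenarios 0-4 from a baseline mix and tier
#' assignments: scenario 0 is the baseline; scenario k reassigns to the new
#' entrant the baseline share of every (subgroup, rival) cell with
#' tier <= k. Nesting of the takeover sets (and hence monotone entrant
#' share) holds by construction. Naive subgroups never enter: the standard
#' of care is assumed to keep them.
#'
#' @param tiers A [classify_tiers()] result covering every cell that holds
#'   baseline share (missing cells raise an incomplete-classification
#'   error).
#' @param baseline A [baseline_mix()].
#' @param entrant_name Name of the new entrant therapy.
#' @return A tibble of class `ce_scenarios`: `scenario_id` (0-4), subgroup
#'   columns, `therapy`, `share` (positive shares only). The takeover sets
#'   are attached as attribute `takeover_sets` (a list of cell tibbles,
#'   one per scenario 1-4).
#' @export
build_scenarios <- function(tiers, baseline, entrant_name) {
  needed <- c("rival", "history", "subtype", "cirrhosis", "tier")
  if (!all(needed %in% names(tiers))) {
    abort("`tiers` needs columns rival/history/subtype/cirrhosis/tier")
  }
  unassigned <- baseline |>
    anti_join(
      tiers |> rename(therapy = "rival"),
      by = c("therapy", "history", "subtype", "cirrhosis")
    )
  if (nrow(unassigned) > 0) {
    r <- unassigned[1, ]
    abort(sprintf(
      "incomplete classification: no tier for rival %s in subgroup %s",
      r$therapy, subgroup_label(r$history, r$subtype, r$cirrhosis)
    ))
  }
  with_tier <- baseline |>
    left_join(
      tiers |>
        rename(therapy = "rival") |>
        select("therapy", "history", "subtype", "cirrhosis", "tier"),
      by = c("therapy", "history", "subtype", "cirrhosis")
    )
  one_scenario <- function(k) {
    taken <- with_tier |> filter(.data$tier <= k)
    kept <- with_tier |> filter(.data$tier > k)
    mix <- bind_rows(
      kept |> select(-"tier"),
      taken |>
        mutate(therapy = entrant_name) |>
        group_by(.data$history, .data$subtype, .data$cirrhosis, .data$therapy) |>
        summarise(share = sum(.data$share), .groups = "drop")
    ) |>
      group_by(.data$history, .data$subtype, .data$cirrhosis, .data$therapy) |>
      summarise(share = sum(.data$share), .groups = "drop") |>
      mutate(scenario_id = k, .before = 1) |>
      arrange(.data$history, .data$subtype, .data$cirrhosis, .data$therapy)
    list(
      mix = mix,
      takeover = taken |> select("history", "subtype", "cirrhosis", rival = "therapy")
    )
  }
  built <- purrr::map(1:4, one_scenario)
  out <- bind_rows(
    baseline |> mutate(scenario_id = 0L, .before = 1),
    purrr::map(built, "mix")
  )
  class(out) <- c("ce_scenarios", class(out))
  attr(out, "takeover_sets") <- purrr::map(built, "takeover")
  attr(out, "entrant") <- entrant_name
  out
}

# Largest-remainder apportionment of n patients to shares; ties in the
# fractional part broken by position (therapy name order).
apportion <- function(n, shares) {
  quota <- n * shares
  base <- floor(quota)
  rem <- round(n - sum(base))
  if (rem > 0) {
    frac <- quota - base
    extra <- order(-frac, seq_along(shares))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
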