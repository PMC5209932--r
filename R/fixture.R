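# Built-in fixture: the Croatian single-payer HCV GT1 case study inputs.
#
# Direct course costs (EUR 2015, VAT included), course durations (weeks) and
# SVR ranges (fractions) for the interferon-free entrant OBV/PTV/r/DSV and
# its four rivals (dual pegIFN and the first-generation protease-inhibitor
# regimens BOC, TPV and SIM, all on a pegIFN backbone), by patient subgroup.
# Two-variant cells (e.g. cost 23200/32700, duration 28/48) are
# response-guided short/long course alternatives. Ribavirin is donated to the
# payer and carries no cost. Dual pegIFN is not an admissible comparator for
# treatment-experienced patients (SVR as low as 0%, excluded from payer
# guidelines), so those cells are marked ineligible and carry no cost or SVR.

# One row per (history, cirrhosis); subtype-constant unless split columns given.
rival_rows <- function(name, tab) {
  tab |>
    tidyr::expand_grid(subtype = ce_subtypes()) |>
    mutate(therapy = name, is_new_entrant = FALSE, .before = 1)
}

#' Case study therapy table
#'
#' The built-in input fixture of the package: direct therapy costs, course
#' durations and SVR ranges for five HCV GT1 regimens over the 16-cell
#' patient subgroup lattice, as used in the Croatian payer case study.
#' `OBV/PTV/r/DSV` is the new entrant; its SVR values are trial point
#' estimates (degenerate ranges), while rivals carry literature ranges.
#'
#' @return A tibble with one row per (therapy, subgroup): columns `therapy`,
#'   `is_new_entrant`, `history`, `subtype`, `cirrhosis`, `cost_1`, `cost_2`
#'   (NA when the course has a single variant), `weeks_1`, `weeks_2`,
#'   `svr_low`, `svr_high` and `eligible`. 80 rows, of which the 12 dual
#'   pegIFN x experienced cells are ineligible.
#' @export
#' @examples
#' fix <- croatia_gt1_therapies()
#' dplyr::filter(fix, therapy == "OBV/PTV/r/DSV", history == "naive")
croatia_gt1_therapies <- function() {
  H <- ce_histories()

  obv <- tidyr::expand_grid(
    history = H, subtype = ce_subtypes(), cirrhosis = ce_cirrhosis()
  ) |>
    mutate(
      therapy = "OBV/PTV/r/DSV", is_new_entrant = TRUE, .before = 1
    ) |>
    mutate(
      cost_1 = ifelse(.data$cirrhosis == "compensated" & .data$subtype == "GT1a",
        90000, 45000
      ),
      cost_2 = NA_real_,
      weeks_1 = ifelse(.data$cirrhosis == "compensated" & .data$subtype == "GT1a",
        24, 12
      ),
      weeks_2 = NA_real_,
      svr_low = dplyr::case_when(
        history == "naive" & cirrhosis == "none" & subtype == "GT1a" ~ 0.959,
        history == "naive" & cirrhosis == "compensated" & subtype == "GT1a" ~ 0.946,
        history == "relapser" & cirrhosis == "none" & subtype == "GT1a" ~ 0.94,
        history == "partial_responder" & cirrhosis == "compensated" & subtype == "GT1b" ~ 0.857,
        history == "null_responder" & cirrhosis == "none" & subtype == "GT1a" ~ 0.954,
        history == "null_responder" & cirrhosis == "compensated" & subtype == "GT1a" ~ 0.929,
        TRUE ~ 1
      ),
      svr_high = .data$svr_low,
      eligible = TRUE
    )

  peg <- rival_rows("pegIFN", tibble::tribble(
    ~history, ~cirrhosis, ~cost_1, ~cost_2, ~weeks_1, ~weeks_2, ~svr_low, ~svr_high, ~eligible,
    "naive", "none", 4200, 8400, 24, 48, 0.35, 0.50, TRUE,
    "naive", "compensated", 8400, NA, 48, NA, 0.33, 0.38, TRUE,
    "relapser", "none", NA, NA, NA, NA, NA, NA, FALSE,
    "relapser", "compensated", NA, NA, NA, NA, NA, NA, FALSE,
    "partial_responder", "none", NA, NA, NA, NA, NA, NA, FALSE,
    "partial_responder", "compensated", NA, NA, NA, NA, NA, NA, FALSE,
    "null_responder", "none", NA, NA, NA, NA, NA, NA, FALSE,
    "null_responder", "compensated", NA, NA, NA, NA, NA, NA, FALSE
  ))

  boc <- rival_rows("BOC+pegIFN", tibble::tribble(
    ~history, ~cirrhosis, ~cost_1, ~cost_2, ~weeks_1, ~weeks_2, ~svr_low, ~svr_high, ~eligible,
    "naive", "none", 23200, 32700, 28, 48, 0.52, 0.67, TRUE,
    "naive", "compensated", 41900, NA, 48, NA, 0.52, 0.55, TRUE,
    "relapser", "none", 32700, NA, 48, NA, 0.75, 0.93, TRUE,
    "relapser", "compensated", 41900, NA, 48, NA, 0.34, 0.54, TRUE,
    "partial_responder", "none", 32700, NA, 48, NA, 0.52, 0.67, TRUE,
    "partial_responder", "compensated", 41900, NA, 48, NA, 0.34, 0.38, TRUE,
    "null_responder", "none", 41900, NA, 48, NA, 0.38, 0.39, TRUE,
    "null_responder", "compensated", 41900, NA, 48, NA, 0.00, 0.34, TRUE
  ))

  tpv <- rival_rows("TPV+pegIFN", tibble::tribble(
    ~history, ~cirrhosis, ~cost_1, ~cost_2, ~weeks_1, ~weeks_2, ~svr_low, ~svr_high, ~eligible,
    "naive", "none", 30200, 34300, 24, 48, 0.64, 0.85, TRUE,
    "naive", "compensated", 34300, NA, 48, NA, 0.53, 0.71, TRUE,
    "relapser", "none", 30200, 34300, 24, 48, 0.83, 0.88, TRUE,
    "relapser", "compensated", 34300, NA, 48, NA, 0.742, 0.84, TRUE,
    "partial_responder", "none", 30200, 34300, 24, 48, 0.54, 0.79, TRUE,
    "partial_responder", "compensated", 34300, NA, 48, NA, 0.34, 0.40, TRUE,
    "null_responder", "none", 34300, NA, 48, NA, 0.33, 0.43, TRUE,
    "null_responder", "compensated", 34300, NA, 48, NA, 0.14, 0.19, TRUE
  ))

  sim <- rival_rows("SIM+pegIFN", tibble::tribble(
    ~history, ~cirrhosis, ~cost_1, ~cost_2, ~weeks_1, ~weeks_2, ~svr_low, ~svr_high, ~eligible,
    "naive", "none", 32800, NA, 24, NA, 0.68, 0.84, TRUE,
    "naive", "compensated", 32800, NA, 24, NA, 0.57, 0.60, TRUE,
    "relapser", "none", 32800, NA, 24, NA, 0.57, 0.82, TRUE,
    "relapser", "compensated", 32800, NA, 24, NA, 0.46, 0.74, TRUE,
    "partial_responder", "none", 36900, NA, 48, NA, 0.57, 0.79, TRUE,
    "partial_responder", "compensated", 36900, NA, 48, NA, 0.46, 0.82, TRUE,
    "null_responder", "none", 36900, NA, 48, NA, 0.33, 0.66, TRUE,
    "null_responder", "compensated", 36900, NA, 48, NA, 0.31, 0.46, TRUE
  ))

  cols <- c(
    "therapy", "is_new_entrant", "history", "subtype", "cirrhosis",
    "cost_1", "cost_2", "weeks_1", "weeks_2", "svr_low", "svr_high", "eligible"
  )
  out <- bind_rows(obv, peg, boc, tpv, sim) |>
    select(dplyr::all_of(cols)) |>
    arrange(.data$therapy != "OBV/PTV/r/DSV", .data$therapy)
  validate_therapies(out)
}

#' Case study population
#'
#' The annual pool of treatment-experienced HCV GT1 patients eligible for the
#' new therapy in the Croatian case: 90-100 per year (a practitioner
#' estimate), with subtype split 36% GT1a / 64% GT1b (GT1a absorbs the 14%
#' mixed/unknown infections on top of the 22% typed 1a).
#'
#' The composition of the experienced pool across treatment history and
#' cirrhosis was never published; the defaults here
#' (relapser/partial/null 40/30/30%, compensated cirrhosis 30%) are
#' documented modelling assumptions, exposed as arguments so sensitivity
#' sweeps can vary them.
#'
#' @param history_props,cirrhosis_prop Override the assumed composition.
#' @return A [population_spec()].
#' @export
croatia_gt1_population <- function(history_props = c(
                                     relapser = 0.40,
                                     partial_responder = 0.30,
                                     null_responder = 0.30
                                   ),
                                   cirrhosis_prop = 0.30) {
  population_spec(
    total_min = 90, total_max = 100,
    subtype_props = c(GT1a = 0.36, GT1b = 0.64),
    history_props = history_props,
    cirrhosis_prop = cirrhosis_prop
  )
}

#' Full case study input set
#'
#' Convenience bundle of [croatia_gt1_therapies()], [croatia_gt1_population()]
#' and a default [ce_config()].
#'
#' @param ... Passed to [ce_config()] (e.g. `n_runs`, `seed`).
#' @return A list with elements `therapies`, `population` and `config`.
#' @export
#' @examples
#' inp <- croatia_gt1(n_runs = 200, seed = 7)
#' nrow(inp$therapies)
croatia_gt1 <- function(...) {
  list(
    therapies = croatia_gt1_therapies(),
    population = croatia_gt1_population(),
    config = ce_config(...)
  )
}
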