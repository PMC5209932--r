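# Shared toy fixtures, built in code.

# A therapy covering the full lattice with constant parameters.
toy_therapy <- function(name, entrant = FALSE, cost = 30000, cost2 = NA,
                        svr_low = 0.5, svr_high = svr_low, eligible = TRUE) {
  subgroup_lattice() |>
    dplyr::mutate(
      therapy = name, is_new_entrant = entrant, .before = 1
    ) |>
    dplyr::mutate(
      cost_1 = cost, cost_2 = as.numeric(cost2),
      weeks_1 = 12, weeks_2 = ifelse(is.na(cost2), NA_real_, 24),
      svr_low = svr_low, svr_high = svr_high, eligible = eligible
    )
}

# Entrant (cost 45000, point SVR 0.9) + one rival (cost 32800, point SVR 0.5).
toy_inputs <- function(rival_svr = 0.5, rival_cost = 32800,
                       entrant_svr = 0.9, entrant_cost = 45000) {
  dplyr::bind_rows(
    toy_therapy("entrant", entrant = TRUE, cost = entrant_cost, svr_low = entrant_svr),
    toy_therapy("rival_a", cost = rival_cost, svr_low = rival_svr)
  )
}

# Population concentrated on a single experienced cell with a fixed total.
point_population <- function(total = 50) {
  population_spec(
    total_min = total, total_max = total,
    subtype_props = c(GT1a = 1, GT1b = 0),
    history_props = c(relapser = 1, partial_responder = 0, null_responder = 0),
    cirrhosis_prop = 0
  )
}

# Scenario table assigning one therapy 100% of every experienced subgroup.
single_therapy_scenarios <- function(ids_to_therapy) {
  purrr::imap(ids_to_therapy, \(ther, id) {
    subgroup_lattice(experienced_only = TRUE) |>
      dplyr::mutate(
        scenario_id = as.integer(id), .before = 1
      ) |>
      dplyr::mutate(therapy = ther, share = 1)
  }) |>
    purrr::list_rbind()
}

expect_money_rounds_to <- function(x, display) {
  expect_equal(round(x / 100) * 100, display)
}
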