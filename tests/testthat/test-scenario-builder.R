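# Baseline mixes, the tier rule, and nested scenario construction.

test_that("the cheapest-per-SVR baseline picks the rival the payer would already buy", {
  fix <- croatia_gt1_therapies()
  ce <- ce_table(fix, ce_config(n_runs = 2000, seed = 2))
  base <- baseline_mix(fix, ce, "cheapest_per_svr")

  # shares sum to 1 per experienced subgroup, entrant absent
  sums <- base |>
    dplyr::summarise(s = sum(share), .by = c(history, subtype, cirrhosis))
  expect_equal(sums$s, rep(1, 12))
  expect_false("OBV/PTV/r/DSV" %in% base$therapy)

  # non-cirrhotic relapsers: TPV has the lowest mean cost per SVR
  # (~37.7k against ~39.2k BOC and ~47.6k SIM)
  rel <- dplyr::filter(base, history == "relapser", cirrhosis == "none")
  expect_equal(unique(rel$therapy), "TPV+pegIFN")
  # non-cirrhotic null responders: SIM (~77.5k vs ~90.8k / ~108.8k)
  nul <- dplyr::filter(base, history == "null_responder", cirrhosis == "none")
  expect_equal(unique(nul$therapy), "SIM+pegIFN")
})

test_that("the equal-eligible baseline splits each subgroup across its rivals", {
  fix <- croatia_gt1_therapies()
  ce <- ce_table(fix, ce_config(n_runs = 500, seed = 2))
  base <- baseline_mix(fix, ce, "equal_eligible")
  expect_equal(sort(unique(base$share)), 1 / 3) # three PI rivals everywhere
  sums <- base |>
    dplyr::summarise(s = sum(share), .by = c(history, subtype, cirrhosis))
  expect_equal(sums$s, rep(1, 12))

  # a single-rival input gives that rival full share under either strategy
  toy <- toy_inputs()
  toy_ce <- ce_table(toy, ce_config(n_runs = 10, seed = 1))
  for (strat in c("cheapest_per_svr", "equal_eligible")) {
    b <- baseline_mix(toy, toy_ce, strat)
    expect_equal(unique(b$therapy), "rival_a")
    expect_equal(unique(b$share), 1)
  }

  # no eligible rival anywhere is a configuration error
  no_rival <- toy_therapy("entrant", entrant = TRUE, svr_low = 0.9)
  expect_error(
    baseline_mix(no_rival, toy_ce, "equal_eligible"),
    "no eligible rival"
  )
})

test_that("the tier rule follows the savings summary, boundary inclusive", {
  cells <- tibble::tibble(
    savings_mean = c(61666, 2000, -10000, -10000.01, 0, 1e-9),
    savings_min = c(40000, -5000, -30000, -30000, -1, -1)
  )
  tiers <- classify_tiers(cells, threshold = 10000)
  expect_equal(tiers$tier, c(1L, 2L, 3L, 4L, 3L, 2L))
  expect_error(classify_tiers(tibble::tibble(x = 1)), "savings_mean")
})

test_that("scenarios nest, conserve shares, and scenario 4 is full takeover", {
  fix <- croatia_gt1_therapies()
  cfg <- ce_config(n_runs = 2000, seed = 7)
  ce <- ce_table(fix, cfg)
  sav <- savings_table(fix, cfg) |> dplyr::filter(history != "naive")
  tiers <- classify_tiers(sav, cfg$tier3_threshold)
  base <- baseline_mix(fix, ce, "cheapest_per_svr")
  scen <- build_scenarios(tiers, base, "OBV/PTV/r/DSV")

  # conservation at every scenario
  sums <- scen |>
    dplyr::summarise(s = sum(share), .by = c(scenario_id, history, subtype, cirrhosis))
  expect_equal(sums$s, rep(1, nrow(sums)))

  # nesting: entrant share non-decreasing in scenario id, per subgroup
  entrant_share <- subgroup_lattice(experienced_only = TRUE) |>
    tidyr::expand_grid(scenario_id = 0:4) |>
    dplyr::left_join(
      dplyr::filter(scen, therapy == "OBV/PTV/r/DSV"),
      by = c("scenario_id", "history", "subtype", "cirrhosis")
    ) |>
    dplyr::mutate(share = dplyr::coalesce(share, 0)) |>
    dplyr::arrange(history, subtype, cirrhosis, scenario_id)
  mono <- entrant_share |>
    dplyr::summarise(ok = all(diff(share) >= 0),
      .by = c(history, subtype, cirrhosis))
  expect_true(all(mono$ok))

  # takeover sets nest too
  sets <- attr(scen, "takeover_sets")
  for (k in 1:3) {
    expect_equal(nrow(dplyr::anti_join(sets[[k]], sets[[k + 1]],
      by = names(sets[[k]]))), 0)
  }

  # scenario 0 is the baseline; scenario 4 gives the entrant everything
  expect_equal(
    dplyr::filter(scen, scenario_id == 0) |> dplyr::select(-scenario_id),
    base,
    ignore_attr = TRUE
  )
  s4 <- dplyr::filter(scen, scenario_id == 4)
  expect_equal(unique(s4$therapy), "OBV/PTV/r/DSV")
  expect_equal(s4$share, rep(1, 12))
})

test_that("hand-built tier patterns produce the expected mixes", {
  base <- tibble::tibble(
    history = "relapser", subtype = c("GT1a", "GT1b"), cirrhosis = "none",
    therapy = "rival_a", share = 1
  )
  tiers <- tibble::tibble(
    rival = "rival_a", history = "relapser",
    subtype = c("GT1a", "GT1b"), cirrhosis = "none", tier = c(1L, 3L)
  )
  scen <- build_scenarios(tiers, base, "entrant")
  mix_of <- function(k) {
    dplyr::filter(scen, scenario_id == k) |>
      dplyr::select(-scenario_id) |>
      dplyr::arrange(subtype, therapy)
  }
  # tier {1, 3}: scenario 2 adds nothing beyond scenario 1
  expect_equal(mix_of(1), mix_of(2))
  expect_false(identical(mix_of(2), mix_of(3)))
  expect_equal(unique(mix_of(4)$therapy), "entrant")

  # all cells tier 1: scenarios 1-4 identical, entrant share 1 everywhere
  tiers1 <- dplyr::mutate(tiers, tier = 1L)
  scen1 <- build_scenarios(tiers1, base, "entrant")
  for (k in 2:4) {
    expect_equal(
      dplyr::filter(scen1, scenario_id == 1) |> dplyr::select(-scenario_id),
      dplyr::filter(scen1, scenario_id == k) |> dplyr::select(-scenario_id)
    )
  }
  expect_equal(unique(dplyr::filter(scen1, scenario_id == 1)$therapy), "entrant")

  # a baseline cell with no tier is an incomplete classification
  expect_error(
    build_scenarios(tiers[1, ], base, "entrant"),
    "incomplete classification"
  )
})
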