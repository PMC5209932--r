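# Population draws, the paired scenario engine and its derived quantities.

test_that("population draws respect the total range and composition", {
  pop <- croatia_gt1_population()
  set.seed(21)
  d <- draw_population(pop, n_draws = 2000)
  totals <- d |> dplyr::summarise(n = sum(count), .by = run)
  expect_true(all(totals$n >= 90 & totals$n <= 100))
  expect_equal(nrow(d), 2000 * 12) # experienced lattice only

  # GT1b fraction close to 64% (binomial SE over ~95*2000 patients)
  n_pat <- sum(totals$n)
  frac_1b <- sum(d$count[d$subtype == "GT1b"]) / n_pat
  expect_lt(abs(frac_1b - 0.64), 3 * sqrt(0.64 * 0.36 / n_pat))

  # degenerate spec: all mass on one cell, fixed total
  set.seed(22)
  dd <- draw_population(point_population(50), n_draws = 5)
  expect_true(all(dd$count[dd$history == "relapser" & dd$subtype == "GT1a" &
    dd$cirrhosis == "none"] == 50))
  expect_equal(sum(dd$count), 5 * 50)
})

test_that("largest-remainder apportionment conserves patients with the documented tie rule", {
  expect_equal(apportion(9, c(0.5, 0.5)), c(5L, 4L)) # tie to first name
  expect_equal(apportion(10, c(0.5, 0.5)), c(5L, 5L))
  expect_equal(sum(apportion(97, c(0.2, 0.3, 0.5))), 97L)
  expect_equal(apportion(1, c(1 / 3, 1 / 3, 1 / 3)), c(1L, 0L, 0L))
  expect_equal(apportion(0, c(0.4, 0.6)), c(0L, 0L))
})

test_that("a deterministic block yields exact cost and success totals", {
  toy <- toy_inputs(entrant_svr = 1, entrant_cost = 45000)
  counts <- tibble::tibble(
    history = "relapser", subtype = "GT1a", cirrhosis = "none", count = 10
  )
  mix <- tibble::tibble(
    history = "relapser", subtype = "GT1a", cirrhosis = "none",
    therapy = "entrant", share = 1
  )
  set.seed(1)
  r <- simulate_run(mix, counts, toy)
  expect_equal(r$total_cost, 450000)
  expect_equal(r$n_svr, 10) # SVR probability 1
  expect_equal(r$n_treated, 10)

  # a populated subgroup without any market share is a configuration error
  expect_error(
    simulate_run(mix, dplyr::mutate(counts, history = "null_responder"), toy),
    "zero total market share"
  )
})

test_that("binomial successes have the right mean and expectation mode removes the noise", {
  toy <- toy_inputs(rival_svr = 0.5)
  pop <- point_population(100)
  scen <- single_therapy_scenarios(c("0" = "rival_a"))
  sim <- run_scenarios(toy, pop, scen, ce_config(n_runs = 4000, seed = 31))
  expect_lt(abs(mean(sim$runs$n_svr) - 50), 3 * sqrt(100 * 0.25) / sqrt(4000))
  expect_true(all(sim$runs$n_svr >= 0 & sim$runs$n_svr <= sim$runs$n_treated))

  simE <- run_scenarios(toy, pop, scen,
    ce_config(n_runs = 50, seed = 31, success_mode = "expectation"))
  expect_equal(simE$runs$n_svr, rep(50, 50)) # point SVR, fixed population
})

test_that("identical seeds reproduce runs and identical mixes difference to zero", {
  fix <- croatia_gt1_therapies()
  pop <- croatia_gt1_population()
  cfg <- ce_config(n_runs = 300, seed = 17)
  res1 <- market_entry_analysis(fix, pop, cfg)
  res2 <- market_entry_analysis(fix, pop, cfg)
  expect_identical(res1$sim$runs, res2$sim$runs)
  expect_identical(as.data.frame(res1$ce), as.data.frame(res2$ce))

  # the same mix listed under two scenario ids: per-run differences all zero
  toy <- toy_inputs()
  scen <- single_therapy_scenarios(c("0" = "rival_a", "1" = "rival_a"))
  sim <- run_scenarios(toy, point_population(60), scen, ce_config(n_runs = 100, seed = 5))
  bi <- budget_impact(sim, 1, 0)
  expect_equal(bi$delta_cost_mean, 0)
  expect_equal(c(bi$delta_cost_min, bi$delta_cost_max), c(0, 0))
  ic <- icer(sim, 1, 0)
  expect_true(ic$dominated) # zero extra SVRs: ICER undefined, tagged not thrown
  expect_true(is.na(ic$icer))
})

test_that("per-run conservation identities hold against the recorded draws", {
  fix <- croatia_gt1_therapies()
  pop <- croatia_gt1_population()
  cfg <- ce_config(n_runs = 150, seed = 13)
  res <- market_entry_analysis(fix, pop, cfg)
  sim <- run_scenarios(fix, pop, res$scenarios, cfg, keep_draws = TRUE)
  d <- sim$draws
  for (k in as.character(sim$scenario_ids)) {
    assigned <- d$assigned[[k]]
    runs_k <- dplyr::filter(sim$runs, scenario_id == as.integer(k))
    # patients conserved: per-run assignments sum to the drawn population
    expect_equal(rowSums(assigned), rowSums(d$population))
    expect_equal(runs_k$n_treated, rowSums(d$population))
    # block costs accumulate exactly
    expect_equal(runs_k$total_cost, rowSums(assigned * d$cost))
    # successes accumulate exactly and respect block sizes
    succ <- matrix(
      qbinom(d$u_success, assigned, d$svr),
      nrow(assigned), ncol(assigned)
    )
    expect_true(all(succ <= assigned))
    expect_equal(runs_k$n_svr, rowSums(succ))
  }
})

test_that("budget impact, expenditure per SVR and ICER satisfy their algebra", {
  # toy: 10 patients moved from a 32800 to a 45000 course cost 122000 exactly
  toy <- toy_inputs(rival_svr = 0.5, rival_cost = 32800, entrant_cost = 45000)
  scen <- single_therapy_scenarios(c("0" = "rival_a", "4" = "entrant"))
  pop10 <- population_spec(10, 10,
    subtype_props = c(GT1a = 1, GT1b = 0),
    history_props = c(relapser = 1, partial_responder = 0, null_responder = 0),
    cirrhosis_prop = 0
  )
  sim <- run_scenarios(toy, pop10, scen, ce_config(n_runs = 200, seed = 8))
  bi <- budget_impact(sim, 4, 0)
  expect_equal(bi$delta_cost_mean, 122000)
  expect_equal(bi$pct_increase, 100 * 122000 / 328000)

  # paired-run identity on the case study pipeline
  res <- market_entry_analysis(config = ce_config(n_runs = 400, seed = 23))
  s <- tidy(res$sim)
  for (k in 1:4) {
    bi_k <- budget_impact(res$sim, k)
    expect_equal(
      bi_k$delta_cost_mean + s$mean_cost[s$scenario_id == 0],
      s$mean_cost[s$scenario_id == k],
      tolerance = 1e-9
    )
  }

  # expenditure per SVR: per-run ratio identity and summary bounds
  ex <- expenditure_per_svr(res$sim)
  runs0 <- dplyr::filter(res$sim$runs, scenario_id == 0)
  expect_equal(
    ex$mean[ex$scenario_id == 0],
    mean(runs0$total_cost / runs0$n_svr)
  )
  expect_true(all(ex$min <= ex$mean & ex$mean <= ex$max))
  expect_equal(sum(ex$n_excluded), 0) # SVR floors keep successes positive

  # ICER is the ratio of paired means, exactly
  for (k in 1:4) {
    ic <- icer(res$sim, k)
    expect_equal(ic$icer * ic$delta_svr_mean, ic$delta_cost_mean,
      tolerance = 1e-9)
    d <- attr(ic, "deltas")
    expect_equal(mean(d$delta_cost), ic$delta_cost_mean)
    expect_equal(mean(d$delta_svr), ic$delta_svr_mean)
  }

  # hand arithmetic: mean delta-cost 250000 over mean delta-SVR 12.5 is 20000
  expect_equal(250000 / 12.5, 20000)
})

test_that("SVR percentages rise with scenario id when the entrant dominates on efficacy", {
  res <- market_entry_analysis(config = ce_config(n_runs = 400, seed = 41))
  s <- tidy(res$sim) |> dplyr::arrange(scenario_id)
  expect_true(all(diff(s$mean_pct_svr) >= 0))
  expect_true(all(s$mean_pct_svr >= 0 & s$mean_pct_svr <= 100))
})
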