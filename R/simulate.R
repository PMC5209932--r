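# Population draws and the paired scenario simulation (budget impact,
# percent achieving SVR, expenditure per SVR, ICER).

#' Draw annual patient populations
#'
#' Each draw takes the annual total uniformly on the integer range of the
#' population spec and allocates it to subgroup cells with a single
#' multinomial draw whose probabilities are the product of the subtype,
#' history and cirrhosis proportions. Counts sum to the drawn total by
#' construction.
#'
#' @param pop A [population_spec()].
#' @param n_draws Number of independent draws.
#' @return A tibble with columns `run`, `history`, `subtype`, `cirrhosis`,
#'   `count`.
#' @export
#' @examples
#' set.seed(1)
#' draw_population(croatia_gt1_population(), n_draws = 2)
draw_population <- function(pop, n_draws = 1) {
  d <- draw_population_matrix(pop, n_draws)
  d$cells |>
    tidyr::expand_grid(run = seq_len(n_draws)) |>
    arrange(.data$run) |>
    mutate(count = as.vector(t(d$counts))) |>
    select("run", "history", "subtype", "cirrhosis", "count")
}

# Matrix form used internally: totals[n], counts[n x n_cells], cells tibble.
draw_population_matrix <- function(pop, n_draws) {
  cells <- population_cell_probs(pop)
  # index into the value grid (sample(x, ...) would misbehave for scalar x)
  tot_vals <- seq(pop$total_min, pop$total_max)
  totals <- tot_vals[sample.int(length(tot_vals), n_draws, replace = TRUE)]
  counts <- matrix(0L, nrow = n_draws, ncol = nrow(cells))
  for (tot in unique(totals)) {
    idx <- which(totals == tot)
    counts[idx, ] <- t(rmultinom(length(idx), tot, cells$prob))
  }
  list(totals = totals, counts = counts, cells = cells)
}

#' Simulate one run of one market mix
#'
#' Patients in each subgroup are apportioned to therapies by the mix's
#' shares with largest-remainder rounding (ties by therapy name order).
#' For each (therapy, subgroup) block one SVR and one course cost are drawn
#' from the regimen's ranges, successes are drawn binomially with the
#' sampled SVR, and cost accrues as `count x sampled course cost`.
#' Consumes the current RNG stream. The full paired analysis lives in
#' [run_scenarios()]; this single-run form exists for inspection and
#' testing.
#'
#' @param mix A market mix tibble (subgroup columns, `therapy`, `share`).
#' @param counts A population draw for one run (subgroup columns, `count`).
#' @param therapies A validated therapy table.
#' @param success_mode `"binomial"` or `"expectation"`.
#' @return A one-row tibble: `total_cost`, `n_treated`, `n_svr`.
#' @export
simulate_run <- function(mix, counts, therapies,
                         success_mode = c("binomial", "expectation")) {
  success_mode <- match.arg(success_mode)
  therapies <- validate_therapies(therapies)
  counts <- filter(counts, .data$count > 0)
  total_cost <- 0
  n_svr <- 0
  for (i in seq_len(nrow(counts))) {
    cell <- counts[i, ]
    block <- mix |>
      filter(
        .data$history == cell$history, .data$subtype == cell$subtype,
        .data$cirrhosis == cell$cirrhosis, .data$share > 0
      ) |>
      arrange(.data$therapy)
    if (nrow(block) == 0) {
      abort(sprintf(
        "populated subgroup %s has zero total market share",
        subgroup_label(cell$history, cell$subtype, cell$cirrhosis)
      ))
    }
    alloc <- apportion(cell$count, block$share / sum(block$share))
    for (j in seq_len(nrow(block))) {
      if (alloc[j] == 0) next
      entry <- therapies |>
        filter(
          .data$therapy == block$therapy[j], .data$history == cell$history,
          .data$subtype == cell$subtype, .data$cirrhosis == cell$cirrhosis
        )
      if (!entry$eligible) {
        abort(sprintf(
          "therapy %s assigned to subgroup %s where it is not eligible",
          entry$therapy, subgroup_label(cell$history, cell$subtype, cell$cirrhosis)
        ))
      }
      svr <- sample_svr(entry$svr_low, entry$svr_high, 1)
      cost <- sample_course_cost(entry$cost_1, entry$cost_2, 1)
      succ <- if (success_mode == "binomial") {
        stats::rbinom(1, alloc[j], svr)
      } else {
        alloc[j] * svr
      }
      total_cost <- total_cost + alloc[j] * cost
      n_svr <- n_svr + succ
    }
  }
  tibble(total_cost = total_cost, n_treated = sum(counts$count), n_svr = n_svr)
}

#' Run the paired scenario simulation
#'
#' The heart of the budget impact analysis. For each of `config$n_runs`
#' simulation runs, one population draw and one set of SVR / course-cost /
#' success draws per (therapy, subgroup) cell are shared across all
#' scenarios (common random numbers), so per-run differences between
#' scenarios isolate the market-mix change. Successes within a block use a
#' single shared uniform mapped through the binomial inverse CDF
#' (`qbinom(u, n_assigned, svr)`), which keeps them comparable across
#' scenarios even when block sizes differ; `"expectation"` mode replaces the
#' draw with `n_assigned x svr`. The whole simulation is deterministic given
#' `config$seed`.
#'
#' @param therapies A validated therapy table.
#' @param pop A [population_spec()].
#' @param scenarios A [build_scenarios()] result (or any mix tibble with a
#'   `scenario_id` column).
#' @param config A [ce_config()].
#' @param keep_draws Attach per-run draw detail (cell counts, sampled SVRs
#'   and costs) for independent recomputation; memory scales with
#'   `n_runs x cells`, so reserve it for validation work.
#' @return An object of class `ce_sim`: a list with `runs` (tibble:
#'   `scenario_id`, `run`, `total_cost`, `n_treated`, `n_svr`, `pct_svr`),
#'   `config`, and (optionally) `draws`. Use [tidy()] for per-scenario
#'   summaries, [budget_impact()], [expenditure_per_svr()] and [icer()] for
#'   derived quantities.
#' @export
run_scenarios <- function(therapies, pop, scenarios, config = ce_config(),
                          keep_draws = FALSE) {
  therapies <- validate_therapies(therapies)
  validate_population(pop)
  n <- config$n_runs
  seeds <- child_seeds(config$seed, c("population", "cells"))

  scen_ids <- sort(unique(scenarios$scenario_id))
  # Every (subgroup, therapy) cell holding share in any scenario.
  active <- scenarios |>
    as_tibble() |>
    filter(.data$share > 0) |>
    distinct(.data$history, .data$subtype, .data$cirrhosis, .data$therapy) |>
    arrange(.data$therapy, .data$history, .data$subtype, .data$cirrhosis) |>
    inner_join(therapies,
      by = c("therapy", "history", "subtype", "cirrhosis")
    )
  if (any(!active$eligible)) {
    r <- active[!active$eligible, ][1, ]
    abort(sprintf(
      "therapy %s holds market share in subgroup %s where it is not eligible",
      r$therapy, subgroup_label(r$history, r$subtype, r$cirrhosis)
    ))
  }
  active$cell_id <- seq_len(nrow(active))

  set.seed(seeds[["population"]])
  d <- draw_population_matrix(pop, n)
  pop_key <- subgroup_key(d$cells$history, d$cells$subtype, d$cells$cirrhosis)

  # Populated subgroups must carry market share in every scenario.
  for (k in scen_ids) {
    mix_keys <- scenarios |>
      filter(.data$scenario_id == k, .data$share > 0)
    mix_keys <- unique(subgroup_key(mix_keys$history, mix_keys$subtype, mix_keys$cirrhosis))
    missing <- setdiff(pop_key[d$cells$prob > 0], mix_keys)
    if (length(missing) > 0) {
      abort(sprintf(
        "scenario %d assigns zero total share to populated subgroup %s",
        k, missing[1]
      ))
    }
  }

  set.seed(seeds[["cells"]])
  n_cells <- nrow(active)
  svr_draws <- matrix(0, n, n_cells)
  cost_draws <- matrix(0, n, n_cells)
  u_succ <- matrix(runif(n * n_cells), n, n_cells)
  for (j in seq_len(n_cells)) {
    e <- active[j, ]
    svr_draws[, j] <- sample_svr(e$svr_low, e$svr_high, n)
    cost_draws[, j] <- sample_course_cost(
      e$cost_1, e$cost_2, n, config$two_variant_prob
    )
  }

  active_key <- subgroup_key(active$history, active$subtype, active$cirrhosis)
  totals_by_run <- d$totals

  runs_list <- vector("list", length(scen_ids))
  draws_counts <- if (keep_draws) list() else NULL
  for (si in seq_along(scen_ids)) {
    k <- scen_ids[si]
    mix_k <- scenarios |> filter(.data$scenario_id == k, .data$share > 0)
    assigned <- matrix(0L, n, n_cells)
    for (ci in seq_len(ncol(d$counts))) {
      key <- pop_key[ci]
      block <- mix_k |>
        filter(subgroup_key(.data$history, .data$subtype, .data$cirrhosis) == key) |>
        arrange(.data$therapy)
      if (nrow(block) == 0) next # unpopulated subgroup (prob 0)
      cols <- match(
        paste(block$therapy, key), paste(active$therapy, active_key)
      )
      w <- block$share / sum(block$share)
      n_vec <- d$counts[, ci]
      if (length(w) == 1) {
        assigned[, cols] <- n_vec
      } else {
        for (tot in unique(n_vec)) {
          idx <- which(n_vec == tot)
          assigned[idx, cols] <- rep(apportion(tot, w), each = length(idx))
        }
      }
    }
    cost_k <- rowSums(assigned * cost_draws)
    succ_k <- if (config$success_mode == "binomial") {
      s <- qbinom(u_succ, assigned, svr_draws)
      rowSums(matrix(s, n, n_cells))
    } else {
      rowSums(assigned * svr_draws)
    }
    runs_list[[si]] <- tibble(
      scenario_id = k, run = seq_len(n),
      total_cost = cost_k, n_treated = totals_by_run,
      n_svr = succ_k, pct_svr = 100 * succ_k / totals_by_run
    )
    if (keep_draws) draws_counts[[as.character(k)]] <- assigned
  }

  out <- list(
    runs = bind_rows(runs_list),
    config = config,
    scenario_ids = scen_ids
  )
  if (keep_draws) {
    out$draws <- list(
      cells = active |>
        select(
          "cell_id", "therapy", "history", "subtype", "cirrhosis",
          "cost_1", "cost_2", "svr_low", "svr_high"
        ),
      population = d$counts,
      population_cells = d$cells,
      svr = svr_draws, cost = cost_draws, u_success = u_succ,
      assigned = draws_counts
    )
  }
  structure(out, class = "ce_sim")
}

#' @export
print.ce_sim <- function(x, ...) {
  cat(sprintf(
    "<ce_sim> %d scenarios x %d runs (seed %d, %s successes)\n",
    length(x$scenario_ids), x$config$n_runs, x$config$seed,
    x$config$success_mode
  ))
  print(tidy(x))
  invisible(x)
}

sim_runs_pair <- function(sim, scenario_id, reference_id) {
  for (k in c(scenario_id, reference_id)) {
    if (!k %in% sim$scenario_ids) {
      abort(sprintf("scenario %s not present in the simulation", k))
    }
  }
  a <- sim$runs |> filter(.data$scenario_id == !!scenario_id) |> arrange(.data$run)
  b <- sim$runs |> filter(.data$scenario_id == !!reference_id) |> arrange(.data$run)
  if (nrow(a) != nrow(b) || any(a$run != b$run)) {
    abort("scenario run sets are not paired")
  }
  list(k = a, ref = b)
}

#' Budget impact of a scenario
#'
#' Per-run difference in total annual expenditure between a scenario and the
#' reference (pre-entry baseline by default), summarised over the paired
#' runs, plus the percent increase relative to the reference mean.
#'
#' @param sim A [run_scenarios()] result (runs are paired by construction).
#' @param scenario_id Scenario to evaluate.
#' @param reference_id Reference scenario (default 0).
#' @return A one-row tibble: `scenario_id`, `reference_id`, `delta_cost_mean`,
#'   `delta_cost_min`, `delta_cost_max`, `delta_cost_sd`, `pct_increase`,
#'   `n_runs`.
#' @export
budget_impact <- function(sim, scenario_id, reference_id = 0) {
  p <- sim_runs_pair(sim, scenario_id, reference_id)
  delta <- p$k$total_cost - p$ref$total_cost
  tibble(
    scenario_id = scenario_id, reference_id = reference_id,
    delta_cost_mean = mean(delta), delta_cost_min = min(delta),
    delta_cost_max = max(delta),
    delta_cost_sd = if (length(delta) > 1) sd(delta) else 0,
    pct_increase = 100 * mean(delta) / mean(p$ref$total_cost),
    n_runs = length(delta)
  )
}

#' Expenditure per achieved SVR
#'
#' Per-run ratio of total cost to number of patients achieving SVR,
#' summarised per scenario. Runs with zero successes carry no finite ratio;
#' they are excluded with a count (`n_excluded`).
#'
#' @param sim A [run_scenarios()] result.
#' @return A tibble, one row per scenario: `scenario_id`, `mean`, `min`,
#'   `max`, `sd`, `n_runs`, `n_excluded`.
#' @export
expenditure_per_svr <- function(sim) {
  sim$runs |>
    group_by(.data$scenario_id) |>
    group_modify(\(g, key) {
      ratio <- g$total_cost / g$n_svr
      summarise_draws(ratio)
    }) |>
    ungroup()
}

#' Incremental cost-effectiveness ratio
#'
#' Additional cost per additional patient achieving SVR when moving from the
#' reference mix to a scenario: the ratio of the paired-run mean cost
#' difference to the mean SVR difference (ratio of means, the standard
#' health-economics convention; per-run ratios are unstable when the SVR
#' difference is small and are returned only for inspection). When the mean
#' SVR difference is not positive the ICER is undefined and the result is
#' tagged `dominated` (`icer = NA`), not an error.
#'
#' @inheritParams budget_impact
#' @return A one-row tibble: `scenario_id`, `reference_id`,
#'   `delta_cost_mean`, `delta_svr_mean`, `icer`, `dominated`, `n_runs`;
#'   per-run deltas attached as attribute `deltas`.
#' @export
icer <- function(sim, scenario_id, reference_id = 0) {
  p <- sim_runs_pair(sim, scenario_id, reference_id)
  d_cost <- p$k$total_cost - p$ref$total_cost
  d_svr <- p$k$n_svr - p$ref$n_svr
  dominated <- mean(d_svr) <= 0
  out <- tibble(
    scenario_id = scenario_id, reference_id = reference_id,
    delta_cost_mean = mean(d_cost), delta_svr_mean = mean(d_svr),
    icer = if (dominated) NA_real_ else mean(d_cost) / mean(d_svr),
    dominated = dominated, n_runs = length(d_cost)
  )
  attr(out, "deltas") <- tibble(
    run = p$k$run, delta_cost = d_cost, delta_svr = d_svr
  )
  out
}

#' Full market-entry analysis
#'
#' One-call pipeline over a therapy table and population: cost-per-SVR table,
#' savings per SVR under common random numbers, tier classification, baseline
#' mix, the five takeover scenarios, the paired outcome simulation, and the
#' derived budget impact and ICER tables. Everything is driven by the single
#' master seed in `config`.
#'
#' @param therapies A validated therapy table (default: the built-in case
#'   study fixture).
#' @param pop A [population_spec()] (default: the case study population).
#' @param config A [ce_config()].
#' @return An object of class `market_entry`: a list with `ce`, `savings`,
#'   `tiers`, `baseline`, `scenarios`, `sim`, `bia`, `expenditure`, `icer`
#'   and `config`.
#' @export
#' @examples
#' res <- market_entry_analysis(config = ce_config(n_runs = 200, seed = 1))
#' res$bia
market_entry_analysis <- function(therapies = croatia_gt1_therapies(),
                                  pop = croatia_gt1_population(),
                                  config = ce_config()) {
  therapies <- validate_therapies(therapies)
  ce <- ce_table(therapies, config)
  savings <- savings_table(therapies, config)
  tiers <- classify_tiers(
    savings |> filter(.data$history != "naive"),
    config$tier3_threshold
  )
  baseline <- baseline_mix(therapies, ce, config$baseline_strategy)
  scenarios <- build_scenarios(tiers, baseline, new_entrant_name(therapies))
  sim <- run_scenarios(therapies, pop, scenarios, config)
  ks <- setdiff(sim$scenario_ids, 0)
  structure(
    list(
      ce = ce, savings = savings, tiers = tiers, baseline = baseline,
      scenarios = scenarios, sim = sim,
      bia = purrr::map(ks, \(k) budget_impact(sim, k)) |> purrr::list_rbind(),
      expenditure = expenditure_per_svr(sim),
      icer = purrr::map(ks, \(k) icer(sim, k)) |> purrr::list_rbind(),
      config = config
    ),
    class = "market_entry"
  )
}

#' @export
print.market_entry <- function(x, ...) {
  cat(sprintf(
    "<market_entry> %d therapies, %d runs, seed %d\n",
    dplyr::n_distinct(x$ce$therapy), x$config$n_runs, x$config$seed
  ))
  cat("\nPer-scenario outcomes:\n")
  print(tidy(x$sim))
  cat("\nBudget impact vs baseline:\n")
  print(x$bia |> select("scenario_id", "delta_cost_mean", "pct_increase"))
  cat("\nICER vs baseline:\n")
  print(x$icer |> select("scenario_id", "delta_cost_mean", "delta_svr_mean", "icer"))
  invisible(x)
}
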