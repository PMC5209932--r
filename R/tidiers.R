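# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scenario simulation
#'
#' One row per scenario with the distribution of total annual cost, percent
#' of patients achieving SVR, and the mean SVR count over the paired runs.
#'
#' @param x A [run_scenarios()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ce_sim <- function(x, ...) {
  x$runs |>
    group_by(.data$scenario_id) |>
    summarise(
      mean_cost = mean(.data$total_cost),
      min_cost = min(.data$total_cost),
      max_cost = max(.data$total_cost),
      sd_cost = sd(.data$total_cost),
      mean_pct_svr = mean(.data$pct_svr),
      min_pct_svr = min(.data$pct_svr),
      max_pct_svr = max(.data$pct_svr),
      mean_n_svr = mean(.data$n_svr),
      n_runs = dplyr::n(),
      .groups = "drop"
    )
}

#' @rdname tidy.ce_sim
#' @export
glance.ce_sim <- function(x, ...) {
  tibble(
    n_scenarios = length(x$scenario_ids),
    n_runs = x$config$n_runs,
    seed = x$config$seed,
    success_mode = x$config$success_mode
  )
}

#' Tidy a full market-entry analysis
#'
#' Joins the per-scenario outcome summaries with budget impact, expenditure
#' per SVR and ICER into one table (baseline rows carry `NA` deltas).
#'
#' @param x A [market_entry_analysis()] result.
#' @param ... Unused.
#' @return A tibble, one row per scenario.
#' @export
tidy.market_entry <- function(x, ...) {
  tidy(x$sim) |>
    left_join(
      x$expenditure |>
        select("scenario_id", expenditure_per_svr_mean = "mean"),
      by = "scenario_id"
    ) |>
    left_join(
      x$bia |> select("scenario_id", "delta_cost_mean", "pct_increase"),
      by = "scenario_id"
    ) |>
    left_join(
      x$icer |> select("scenario_id", "delta_svr_mean", "icer"),
      by = "scenario_id"
    )
}

#' @rdname tidy.market_entry
#' @export
glance.market_entry <- function(x, ...) {
  s <- tidy(x)
  tibble(
    n_runs = x$config$n_runs,
    seed = x$config$seed,
    baseline_strategy = x$config$baseline_strategy,
    baseline_pct_svr = s$mean_pct_svr[s$scenario_id == 0],
    full_takeover_pct_svr = s$mean_pct_svr[s$scenario_id == max(s$scenario_id)],
    max_delta_cost = max(s$delta_cost_mean, na.rm = TRUE),
    max_icer = max(s$icer, na.rm = TRUE)
  )
}
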