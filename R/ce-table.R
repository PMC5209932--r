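# Monte Carlo cost-per-SVR and savings-per-SVR tables.

#' Monte Carlo cost per SVR for one regimen cell
#'
#' Draws `n_runs` paired (course cost, SVR) samples for a single
#' (therapy, subgroup) entry and summarises the per-draw cost per SVR.
#' Non-finite ratios (possible only when the SVR range floor is exactly
#' zero) are excluded from the summary and counted in `n_excluded`.
#' Consumes the current RNG stream; seed it (or use [ce_table()], which
#' manages seeding) for reproducibility. Degenerate cells (point SVR,
#' single cost variant) are computed exactly without consuming RNG draws:
#' `mean = min = max = cost/svr`, `sd = 0`.
#'
#' @param entry A single eligible row of a therapy table.
#' @param n_runs Number of Monte Carlo draws.
#' @param p_first Probability of the first course variant.
#' @return A one-row tibble: `mean`, `min`, `max`, `sd`, `n_runs`,
#'   `n_excluded`.
#' @export
#' @examples
#' fix <- croatia_gt1_therapies()
#' boc <- dplyr::filter(fix, therapy == "BOC+pegIFN",
#'   history == "null_responder", cirrhosis == "none", subtype == "GT1a")
#' set.seed(1)
#' mc_cost_per_svr(boc, n_runs = 1000)
mc_cost_per_svr <- function(entry, n_runs = 10000, p_first = 0.5) {
  if (nrow(entry) != 1) abort("`entry` must be a single therapy-table row")
  if (!entry$eligible) {
    abort(sprintf(
      "therapy %s is not an admissible comparator for subgroup %s",
      entry$therapy, subgroup_label(entry$history, entry$subtype, entry$cirrhosis)
    ))
  }
  degenerate <- entry$svr_low == entry$svr_high && is.na(entry$cost_2)
  if (degenerate) {
    if (entry$svr_low == 0) abort("all Monte Carlo draws were non-finite; no summary exists")
    v <- entry$cost_1 / entry$svr_low
    return(tibble(
      mean = v, min = v, max = v, sd = 0,
      n_runs = as.integer(n_runs), n_excluded = 0L
    ))
  }
  svr <- sample_svr(entry$svr_low, entry$svr_high, n_runs)
  cost <- sample_course_cost(entry$cost_1, entry$cost_2, n_runs, p_first)
  summarise_draws(cost / svr)
}

#' Cost-per-SVR table over all eligible cells
#'
#' The package's analogue of the case study's cost-effectiveness table:
#' mean (and range) direct cost per successfully treated patient for every
#' eligible (therapy, subgroup) cell, from `config$n_runs` Monte Carlo draws
#' per cell, together with the closed-form mean where it exists
#' ([analytic_mean_cost_per_svr()], `NA` for cells whose SVR floor is 0).
#'
#' @param therapies A validated therapy table.
#' @param config A [ce_config()]; `seed` makes the table reproducible.
#' @return A tibble of class `ce_table`: subgroup columns plus
#'   `mean_cost_per_svr`, `min_cost_per_svr`, `max_cost_per_svr`,
#'   `sd_cost_per_svr`, `analytic_mean`, `n_runs`, `n_excluded`.
#' @export
#' @examples
#' ce <- ce_table(croatia_gt1_therapies(), ce_config(n_runs = 500, seed = 1))
#' dplyr::filter(ce, history == "relapser", cirrhosis == "none")
ce_table <- function(therapies, config = ce_config()) {
  therapies <- validate_therapies(therapies)
  set.seed(child_seeds(config$seed, "ce_table"))
  cells <- therapies |>
    filter(.data$eligible) |>
    arrange(.data$therapy, .data$history, .data$subtype, .data$cirrhosis)
  summaries <- purrr::map(seq_len(nrow(cells)), \(i) {
    mc_cost_per_svr(cells[i, ], config$n_runs, config$two_variant_prob)
  }) |> purrr::list_rbind()
  out <- cells |>
    select("therapy", "is_new_entrant", "history", "subtype", "cirrhosis") |>
    bind_cols(
      summaries |> rename(
        mean_cost_per_svr = "mean", min_cost_per_svr = "min",
        max_cost_per_svr = "max", sd_cost_per_svr = "sd"
      )
    ) |>
    mutate(
      analytic_mean = purrr::map_dbl(seq_len(nrow(cells)), \(i) {
        r <- cells[i, ]
        if (r$svr_low == 0) {
          NA_real_
        } else {
          analytic_mean_cost_per_svr(
            r$cost_1, r$cost_2, r$svr_low, r$svr_high, config$two_variant_prob
          )
        }
      })
    )
  class(out) <- c("ce_table", class(out))
  attr(out, "config") <- config
  out
}

#' Savings per SVR of the new entrant versus each rival
#'
#' For every eligible (rival, subgroup) cell, simulates the per-run
#' difference `rival cost per SVR - entrant cost per SVR` under common
#' random numbers (the same underlying uniforms drive both therapies' SVR
#' and course-variant draws within a run), and summarises mean, range and
#' sd of the savings. Positive values mean the entrant is expected to be
#' cheaper per successfully treated patient.
#'
#' The same draws also yield each side's mean cost per SVR, so
#' `savings_mean == rival_mean - entrant_mean` holds exactly.
#'
#' @inheritParams ce_table
#' @return A tibble of class `ce_savings`: `rival`, subgroup columns,
#'   `savings_mean`, `savings_min`, `savings_max`, `savings_sd`,
#'   `rival_mean`, `entrant_mean`, `n_runs`, `n_excluded`.
#' @export
savings_table <- function(therapies, config = ce_config()) {
  therapies <- validate_therapies(therapies)
  entrant <- filter(therapies, .data$is_new_entrant)
  rivals <- eligible_rivals(therapies) |>
    arrange(.data$therapy, .data$history, .data$subtype, .data$cirrhosis)
  set.seed(child_seeds(config$seed, "savings"))
  n <- config$n_runs

  draw_cell <- function(row, u_svr, u_cost) {
    svr <- if (row$svr_low == row$svr_high) {
      rep(row$svr_low, length(u_svr))
    } else {
      row$svr_low + u_svr * (row$svr_high - row$svr_low)
    }
    cost <- if (is.na(row$cost_2)) {
      rep(row$cost_1, length(u_cost))
    } else {
      ifelse(u_cost < config$two_variant_prob, row$cost_1, row$cost_2)
    }
    cost / svr
  }

  # One pair of uniform streams per subgroup, shared by every therapy in it.
  keys <- rivals |> distinct(.data$history, .data$subtype, .data$cirrhosis)
  u_svr <- purrr::map(seq_len(nrow(keys)), \(i) runif(n))
  u_cost <- purrr::map(seq_len(nrow(keys)), \(i) runif(n))
  names(u_svr) <- names(u_cost) <-
    subgroup_key(keys$history, keys$subtype, keys$cirrhosis)

  out <- purrr::map(seq_len(nrow(rivals)), \(i) {
    r <- rivals[i, ]
    key <- subgroup_key(r$history, r$subtype, r$cirrhosis)
    e <- entrant |>
      filter(
        .data$history == r$history, .data$subtype == r$subtype,
        .data$cirrhosis == r$cirrhosis
      )
    rv <- draw_cell(r, u_svr[[key]], u_cost[[key]])
    ev <- draw_cell(e, u_svr[[key]], u_cost[[key]])
    diff <- rv - ev
    keep <- is.finite(diff)
    tibble(
      rival = r$therapy,
      history = r$history, subtype = r$subtype, cirrhosis = r$cirrhosis,
      savings_mean = mean(diff[keep]), savings_min = min(diff[keep]),
      savings_max = max(diff[keep]),
      savings_sd = if (sum(keep) > 1) sd(diff[keep]) else 0,
      rival_mean = mean(rv[keep]), entrant_mean = mean(ev[keep]),
      n_runs = sum(keep), n_excluded = sum(!keep)
    )
  }) |> purrr::list_rbind()
  class(out) <- c("ce_savings", class(out))
  attr(out, "config") <- config
  out
}

#' Savings per SVR for one rival cell
#'
#' Single-cell convenience wrapper around the common-random-numbers savings
#' computation: compares the new entrant with one rival on one subgroup.
#'
#' @param entrant,rival Single eligible therapy-table rows for the same
#'   subgroup.
#' @param n_runs Number of paired draws.
#' @param p_first Probability of the first course variant.
#' @return A one-row tibble with the `savings_*` summary columns.
#' @export
savings_per_svr <- function(entrant, rival, n_runs = 10000, p_first = 0.5) {
  for (e in list(entrant, rival)) {
    if (nrow(e) != 1 || !e$eligible) abort("both entries must be single eligible rows")
  }
  same <- entrant$history == rival$history && entrant$subtype == rival$subtype &&
    entrant$cirrhosis == rival$cirrhosis
  if (!same) abort("entrant and rival must describe the same subgroup")
  u_svr <- runif(n_runs)
  u_cost <- runif(n_runs)
  val <- function(row) {
    svr <- row$svr_low + u_svr * (row$svr_high - row$svr_low)
    cost <- if (is.na(row$cost_2)) row$cost_1 else ifelse(u_cost < p_first, row$cost_1, row$cost_2)
    cost / svr
  }
  diff <- val(rival) - val(entrant)
  keep <- is.finite(diff)
  tibble(
    savings_mean = mean(diff[keep]), savings_min = min(diff[keep]),
    savings_max = max(diff[keep]),
    savings_sd = if (sum(keep) > 1) sd(diff[keep]) else 0,
    n_runs = sum(keep), n_excluded = sum(!keep)
  )
}
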