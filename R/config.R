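#' Analysis configuration
#'
#' Bundles the knobs shared by the Monte Carlo engine, the scenario builder
#' and the outcome simulator.
#'
#' @param n_runs Number of Monte Carlo runs (default 10000, the count used
#'   throughout the case study).
#' @param seed Master seed (integer). Every random quantity in the pipeline is
#'   derived from it, so identical `(inputs, config)` give identical results.
#' @param tier3_threshold Tier-3 boundary in euro: a rival cell whose mean
#'   savings per SVR is negative but no worse than `-tier3_threshold` is still
#'   taken over in scenario 3 (default 10000).
#' @param baseline_strategy How pre-entry market shares are assigned, since
#'   the real pre-entry split among rivals is not published:
#'   `"cheapest_per_svr"` gives each subgroup's whole share to the rival with
#'   the lowest mean cost per SVR (rational single payer; the default),
#'   `"equal_eligible"` splits it equally across eligible rivals.
#' @param rounding Monetary reporting granularity in euro (default 100).
#'   Internal values are never rounded; this only affects display columns.
#' @param success_mode `"binomial"` draws integer SVR counts per
#'   (therapy, subgroup) block; `"expectation"` uses the exact expected count
#'   (no sampling noise), useful for variance-free validation.
#' @param two_variant_prob Probability of drawing the first listed course
#'   variant when a regimen has two response-guided course lengths
#'   (default 0.5).
#'
#' @return An object of class `ce_config` (a named list).
#' @export
#' @examples
#' ce_config(n_runs = 500, seed = 42)
ce_config <- function(n_runs = 10000,
                      seed = 1L,
                      tier3_threshold = 10000,
                      baseline_strategy = c("cheapest_per_svr", "equal_eligible"),
                      rounding = 100,
                      success_mode = c("binomial", "expectation"),
                      two_variant_prob = 0.5) {
  baseline_strategy <- match.arg(baseline_strategy)
  success_mode <- match.arg(success_mode)
  if (!is.numeric(n_runs) || length(n_runs) != 1 || n_runs < 1) {
    abort("`n_runs` must be a single integer >= 1")
  }
  if (!is.numeric(tier3_threshold) || tier3_threshold < 0) {
    abort("`tier3_threshold` must be a non-negative amount in euro")
  }
  if (!is.numeric(two_variant_prob) || two_variant_prob < 0 || two_variant_prob > 1) {
    abort("`two_variant_prob` must be a probability")
  }
  structure(
    list(
      n_runs = as.integer(n_runs),
      seed = as.integer(seed),
      tier3_threshold = tier3_threshold,
      baseline_strategy = baseline_strategy,
      rounding = rounding,
      success_mode = success_mode,
      two_variant_prob = two_variant_prob
    ),
    class = "ce_config"
  )
}

#' @export
print.ce_config <- function(x, ...) {
  cat("<ce_config>\n")
  cat(sprintf("  runs: %d   seed: %d\n", x$n_runs, x$seed))
  cat(sprintf(
    "  baseline: %s   tier-3 threshold: EUR %s\n",
    x$baseline_strategy, format(x$tier3_threshold, big.mark = " ")
  ))
  cat(sprintf(
    "  successes: %s   reporting granularity: EUR %s\n",
    x$success_mode, format(x$rounding, big.mark = " ")
  ))
  invisible(x)
}

# Derive independent child seeds from the master seed, one per named
# pipeline stage, without disturbing the caller's RNG state.
child_seeds <- function(seed, stages) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

# Round monetary amounts to the reporting granularity (default EUR 100).
round_money <- function(x, granularity = 100) {
  round(x / granularity) * granularity
}
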