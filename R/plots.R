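# ggplot2 views of the result tables. The contract of the package is the
# data series; these are convenience charts over them.

#' Plot savings per SVR
#'
#' Mean savings per SVR of the new entrant against each rival (points) with
#' the simulated range (vertical lines), faceted by cirrhosis status.
#' Positive values: the entrant is expected to be cheaper per successfully
#' treated patient.
#'
#' @param object A [savings_table()] result.
#' @param histories Subset of history levels to show (default: all present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ce_savings <- function(object, histories = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(histories)) df <- filter(df, .data$history %in% histories)
  df <- df |>
    mutate(
      cell = paste(
        subgroup_label(.data$history, .data$subtype, .data$cirrhosis),
        "vs", .data$rival
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$savings_mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$savings_min, ymax = .data$savings_max),
      colour = "steelblue"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Savings per SVR (EUR)",
      title = "Projected savings per successfully treated patient"
    )
}

#' Plot scenario outcomes
#'
#' Distributions over runs of the percent of patients achieving SVR (or the
#' total annual cost) per takeover scenario.
#'
#' @param object A [run_scenarios()] result.
#' @param what `"pct_svr"` or `"total_cost"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ce_sim <- function(object, what = c("pct_svr", "total_cost"), ...) {
  what <- match.arg(what)
  lab <- c(
    pct_svr = "Patients achieving SVR (%)",
    total_cost = "Total annual cost (EUR)"
  )[[what]]
  ggplot2::ggplot(
    object$runs,
    ggplot2::aes(x = factor(.data$scenario_id), y = .data[[what]])
  ) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6, outlier.alpha = 0.2) +
    ggplot2::labs(x = "Scenario", y = lab, title = "Takeover scenario outcomes")
}

#' @rdname autoplot.ce_savings
#' @export
plot_savings <- function(object, histories = NULL) {
  autoplot.ce_savings(object, histories = histories)
}

#' @rdname autoplot.ce_sim
#' @export
plot_scenarios <- function(object, what = "pct_svr") {
  autoplot.ce_sim(object, what = what)
}
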