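# Synthetic input generator: random but structurally valid therapy tables
# and populations mirroring the shape of the case study inputs (per-cell
# uniform SVR ranges, one- or two-variant course costs, composition
# proportions over the subgroup lattice). Used to test every pipeline stage
# independently of the built-in fixture. It is not a calibration tool and
# makes no attempt to fit real epidemiology.

#' Specification for synthetic input generation
#'
#' @param n_rivals Number of rival therapies (>= 1).
#' @param n_subgroups Number of experienced lattice cells that receive
#'   population mass (1-12); the full 16-cell lattice is always emitted so
#'   the generated table passes the same validation as real inputs.
#' @param svr_width_range Interval of SVR range widths to draw per cell.
#' @param cost_range Interval of course costs in euro.
#' @param dominance_mode `"random"` draws entrant and rivals independently;
#'   `"new_dominates"` forces the entrant's SVR interval strictly above all
#'   rivals' and its cost at or below the cheapest rival in every cell
#'   (every cell then classifies tier 1); `"new_dominated"` forces the
#'   reverse (no cell in tiers 1-2).
#' @param two_variant_prob Probability that a rival cell gets a second
#'   response-guided cost variant.
#' @param allow_zero_floor Permit SVR ranges with floor 0. By default ranges
#'   are clipped to `[0.01, 1]` so the closed-form mean oracle always
#'   exists; zero floors exercise the non-finite-draw exclusion path.
#' @param seed Generation seed; identical specs give identical inputs.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_rivals = 3,
                       n_subgroups = 12,
                       svr_width_range = c(0.02, 0.25),
                       cost_range = c(5000, 90000),
                       dominance_mode = c("random", "new_dominates", "new_dominated"),
                       two_variant_prob = 0.3,
                       allow_zero_floor = FALSE,
                       seed = 1L) {
  dominance_mode <- match.arg(dominance_mode)
  if (n_rivals < 1) abort("`n_rivals` must be >= 1")
  if (n_subgroups < 1 || n_subgroups > 12) abort("`n_subgroups` must be in 1..12")
  if (any(svr_width_range <= 0) || any(cost_range <= 0)) {
    abort("SVR widths and costs must be positive")
  }
  structure(
    list(
      n_rivals = as.integer(n_rivals), n_subgroups = as.integer(n_subgroups),
      svr_width_range = svr_width_range, cost_range = cost_range,
      dominance_mode = dominance_mode, two_variant_prob = two_variant_prob,
      allow_zero_floor = isTRUE(allow_zero_floor), seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

#' Generate synthetic inputs
#'
#' @param spec A [synth_spec()].
#' @return A list with a validated `therapies` tibble and a `population`
#'   spec, in the same schemas as the built-in fixture.
#' @export
#' @examples
#' inp <- generate_inputs(synth_spec(n_rivals = 2, seed = 9))
#' nrow(inp$therapies)
generate_inputs <- function(spec) {
  if (!inherits(spec, "synth_spec")) abort("`spec` must be a `synth_spec`")
  set.seed(spec$seed)
  lattice <- subgroup_lattice()
  floor_min <- if (spec$allow_zero_floor) 0 else 0.01

  draw_range <- function(lo_min, lo_max) {
    width <- runif(1, spec$svr_width_range[1], spec$svr_width_range[2])
    low <- runif(1, max(floor_min, lo_min), max(lo_max, floor_min + 1e-6))
    high <- min(low + width, 1)
    c(low, high)
  }
  draw_cost <- function(two_variant_ok = TRUE, at_most = Inf) {
    c1 <- runif(1, spec$cost_range[1], min(spec$cost_range[2], at_most))
    if (two_variant_ok && runif(1) < spec$two_variant_prob && c1 * 1.3 <= at_most) {
      c(c1, min(c1 * runif(1, 1.05, 1.5), at_most))
    } else {
      c(c1, NA)
    }
  }

  make_therapy <- function(name, entrant) {
    rows <- purrr::map(seq_len(nrow(lattice)), \(i) {
      sg <- lattice[i, ]
      sv <- draw_range(floor_min, 0.7)
      co <- draw_cost()
      tibble(
        therapy = name, is_new_entrant = entrant,
        history = sg$history, subtype = sg$subtype, cirrhosis = sg$cirrhosis,
        cost_1 = co[1], cost_2 = co[2],
        weeks_1 = sample(c(12, 24, 48), 1),
        weeks_2 = ifelse(is.na(co[2]), NA, 48),
        svr_low = sv[1], svr_high = sv[2], eligible = TRUE
      )
    })
    purrr::list_rbind(rows)
  }

  rivals <- purrr::map(
    seq_len(spec$n_rivals),
    \(i) make_therapy(sprintf("rival_%02d", i), FALSE)
  ) |> purrr::list_rbind()

  entrant <- purrr::map(seq_len(nrow(lattice)), \(i) {
    sg <- lattice[i, ]
    cell_rivals <- rivals |>
      filter(
        .data$history == sg$history, .data$subtype == sg$subtype,
        .data$cirrhosis == sg$cirrhosis
      )
    r_high <- max(cell_rivals$svr_high)
    r_low <- min(cell_rivals$svr_low)
    r_cheapest <- min(cell_rivals$cost_1, na.rm = TRUE)
    r_dearest <- max(c(cell_rivals$cost_1, cell_rivals$cost_2), na.rm = TRUE)
    if (spec$dominance_mode == "new_dominates") {
      if (r_high >= 1 - 1e-6) {
        abort(sprintf(
          "cannot place entrant SVR strictly above rivals in subgroup %s (rival ceiling %.4f)",
          subgroup_label(sg$history, sg$subtype, sg$cirrhosis), r_high
        ))
      }
      low <- r_high + (1 - r_high) * runif(1, 0.05, 0.4)
      high <- min(low + runif(1, 0, (1 - low) / 2), 1)
      cost <- runif(1, spec$cost_range[1] * 0.5, r_cheapest)
    } else if (spec$dominance_mode == "new_dominated") {
      if (r_low <= floor_min + 1e-6) {
        abort(sprintf(
          "cannot place entrant SVR strictly below rivals in subgroup %s (rival floor %.4f)",
          subgroup_label(sg$history, sg$subtype, sg$cirrhosis), r_low
        ))
      }
      high <- max(floor_min + 1e-4, r_low * runif(1, 0.4, 0.9))
      low <- max(floor_min, high * runif(1, 0.6, 1))
      cost <- r_dearest * runif(1, 1.5, 3)
    } else {
      sv <- draw_range(floor_min, 0.7)
      low <- sv[1]
      high <- sv[2]
      cost <- runif(1, spec$cost_range[1], spec$cost_range[2])
    }
    tibble(
      therapy = "entrant", is_new_entrant = TRUE,
      history = sg$history, subtype = sg$subtype, cirrhosis = sg$cirrhosis,
      cost_1 = cost, cost_2 = NA_real_,
      weeks_1 = 12, weeks_2 = NA_real_,
      svr_low = low, svr_high = high, eligible = TRUE
    )
  }) |> purrr::list_rbind()

  hist_p <- runif(3)
  sub_p <- runif(2)
  pop <- population_spec(
    total_min = 50, total_max = 120,
    subtype_props = setNames(sub_p / sum(sub_p), ce_subtypes()),
    history_props = setNames(
      hist_p / sum(hist_p),
      c("relapser", "partial_responder", "null_responder")
    ),
    cirrhosis_prop = runif(1, 0.1, 0.5)
  )
  pop <- restrict_population(pop, spec$n_subgroups)

  list(
    therapies = validate_therapies(bind_rows(entrant, rivals)),
    population = pop
  )
}

# Concentrate population mass on the first n experienced cells by zeroing
# composition levels where possible (only meaningful for n < 12; the
# independence structure limits which patterns are expressible, so this
# zeroes whole axes: n determines how many history/cirrhosis levels stay).
restrict_population <- function(pop, n_subgroups) {
  if (n_subgroups >= 12) return(pop)
  if (n_subgroups <= 4) {
    pop$history_props <- c(relapser = 1, partial_responder = 0, null_responder = 0)
  } else if (n_subgroups <= 8) {
    p <- pop$history_props
    pop$history_props <- c(
      relapser = unname(p["relapser"] / (p["relapser"] + p["partial_responder"])),
      partial_responder = unname(p["partial_responder"] / (p["relapser"] + p["partial_responder"])),
      null_responder = 0
    )
  }
  if (n_subgroups %in% c(1, 2, 5, 6, 9, 10)) pop$cirrhosis_prop <- 0
  if (n_subgroups %in% c(1, 5, 9)) pop$subtype_props <- c(GT1a = 1, GT1b = 0)
  validate_population(pop)
  pop
}

#' Generate fully degenerate synthetic inputs
#'
#' All SVR ranges are points and all courses single-variant, so every Monte
#' Carlo quantity downstream has an exact closed form; combined with
#' `success_mode = "expectation"` the whole pipeline becomes deterministic
#' given the population draw, enabling exact-oracle testing.
#'
#' @param seed Generation seed.
#' @param n_rivals Number of rival therapies.
#' @return A list with `therapies` and `population`, as [generate_inputs()].
#' @export
generate_degenerate_inputs <- function(seed = 1L, n_rivals = 2) {
  inp <- generate_inputs(synth_spec(n_rivals = n_rivals, seed = seed))
  inp$therapies <- inp$therapies |>
    mutate(
      svr_low = round((.data$svr_low + .data$svr_high) / 2, 3),
      svr_high = .data$svr_low,
      cost_1 = round(.data$cost_1, -2),
      cost_2 = NA_real_, weeks_2 = NA_real_
    )
  inp$therapies <- validate_therapies(inp$therapies)
  inp
}
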