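---
title: "Methods: savings-ordered market entry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: savings-ordered market entry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marketce)
```

## The model

`marketce` takes a payer's perspective on one decision: in what order should
an expensive new therapy displace existing regimens, when effectiveness is a
binary cure (sustained virological response, SVR) observed within a year?
The analysis is deliberately short-horizon — direct drug costs only, no
discounting, no quality-adjustment — mirroring how reimbursement decisions
are actually made by payers that run budget impact analyses rather than
utility-based allocation.

Patients are stratified on a 4 × 2 × 2 lattice: treatment history (naive,
relapser, partial responder, null responder) × HCV GT1 subtype (GT1a, which
also absorbs mixed/unknown subtype infections; GT1b) × cirrhosis (none,
compensated). Each (therapy, subgroup) cell carries one or two full-course
costs (two when the course is response-guided, short/long), matching
durations, and an SVR range `[low, high]` from the clinical literature; the
entrant's cells are trial point estimates (degenerate ranges). Dual pegIFN
is not an admissible comparator for experienced patients (SVR floors at 0%,
excluded from payer guidelines), so those cells are ineligible and carry no
cost or SVR data.

All quantities derive from the per-cell **cost per SVR** = course cost /
SVR probability, its per-cell Monte Carlo distribution, and the entrant's
**savings per SVR** against each rival cell.

## The sampling model

The evidence base reports SVR *ranges*, not distributions, and says rates
were varied across their complete ranges. Two choices therefore had to be
made by this package and are its own design decisions:

* **SVR draws are continuous uniform on `[low, high]`** — the
  maximum-entropy distribution on a bounded interval, i.e. the weakest
  assumption consistent with "anywhere in the range". Degenerate ranges
  return their point value without consuming randomness.
* **Two-variant course costs are a fair 50/50 draw** between the printed
  short/long variants (`two_variant_prob` in `ce_config()` changes the
  split); the actual response-guided proportion is not published.

A draw with SVR = 0 has no finite cost per SVR. Under continuous uniform
sampling this has probability zero unless a range is exactly `[0, 0]`
(which never occurs in the built-in inputs); such draws are excluded from
summaries with a logged `n_excluded` count rather than propagating
infinities. One rival cell (BOC for cirrhotic null responders, SVR 0–34%)
has a zero floor: its *sample* mean is finite in any run set but has no
population mean, which is exactly why the published table prints no average
for it; the closed-form oracle returns `NA` there.

For cells with `low > 0` the mean cost per SVR has the closed form
`E[cost] · log(high/low)/(high − low)` (or `E[cost]/low` when degenerate).
`analytic_mean_cost_per_svr()` exposes it as an independent oracle; the
test suite holds the Monte Carlo engine to it, and `ce_table()` reports it
alongside the empirical summaries. Reported minima/maxima are empirical
Monte Carlo extremes (matching how the source figures show ranges), not the
analytic bounds.

## Common random numbers

Savings per SVR and all scenario comparisons are *paired*. Within
`savings_table()` each subgroup gets one uniform stream for SVR and one for
the course variant per run, shared by entrant and rival, so the savings
range reflects joint variation and `savings_mean` decomposes exactly into
`rival_mean − entrant_mean`.

In the scenario engine (`run_scenarios()`), one population draw and one
(SVR, cost, success) draw per (therapy, subgroup) cell are shared by all
scenarios in a run. Success counts use the inverse-CDF construction
`qbinom(u, n_assigned, svr)` with a single uniform `u` per (run, cell):
when two scenarios assign the same block size the counts are identical
(duplicating a scenario yields per-run differences of exactly zero), and
the count responds monotonically to the block size. An
`"expectation"` success mode replaces the draw with `n_assigned × svr` for
variance-free validation; the default `"binomial"` mode produces the
integer cure counts a payer would observe. Whether the published ranges of
successfully treated patients arise from binomial noise or only from
parameter variation is not stated in the source; both modes are provided
and binomial is the default as the more complete error model.

A single master seed (`ce_config(seed = )`) spawns independent child seeds
per pipeline stage, so every result — including written CSVs — is
byte-reproducible from `(inputs, config)`.

## Population and composition assumptions

The annual experienced pool is drawn uniformly on 90–100 patients (a
practitioner estimate in the case study, and explicitly a rough one) and
allocated to the 12 experienced cells by a single multinomial draw with
independent composition: subtype 36% GT1a / 64% GT1b (the published 22%
typed 1a plus 14% mixed/unknown merged into GT1a, per the source's own
grouping), and — **not published anywhere, therefore this package's
documented assumptions** — history 40/30/30% relapser/partial/null and 30%
compensated cirrhosis. These defaults are arguments of
`croatia_gt1_population()` precisely so sensitivity sweeps can vary them.
Naive patients stay on the dual-therapy standard of care and are excluded
from the scenario simulation (they appear only in the cost-effectiveness
tables).

The pre-entry market split among the three PI rivals is likewise not
published. Two baseline strategies are provided: `cheapest_per_svr`
(default; each subgroup fully on the rival with the lowest mean cost per
SVR — a rational-payer assumption that reproduces the published pre-entry
cure rate of ~69% well) and `equal_eligible` (uniform across rivals) for
sensitivity.

## Scenario construction

Tiers follow the savings summary: tier 1 if the savings minimum over runs
is positive; tier 2 if the mean is positive but the range crosses zero;
tier 3 if the mean is negative by at most the threshold (default €10 000,
**boundary inclusive** at exactly −threshold); tier 4 otherwise. Takeover
granularity is the (subgroup, rival) cell. Scenario k reassigns the
baseline shares of all cells with tier ≤ k to the entrant, so takeover sets
are nested by construction and scenario 4 is full takeover regardless of
tiers.

Within a simulated run, patients are apportioned to a subgroup's therapies
by largest-remainder rounding of `count × share`, ties broken by therapy
name order — integer patients are conserved exactly.

ICER is the **ratio of paired-run means**, mean ΔC / mean ΔSVR, the
standard convention; per-run ratios are unstable when ΔSVR is small and are
returned only for inspection. When mean ΔSVR ≤ 0 the result is tagged
dominated (`icer = NA`) rather than raising an error.

## Numerical and reporting conventions

Monetary values are never rounded internally; CSV exports add `_display`
columns at the configured granularity (€100, matching the source tables'
display precision). One published cell is knowingly not matched: the
cirrhotic GT1a naive entrant cell prints 95 200, while direct division of
its own printed inputs gives 90 000 / 0.946 = 95 137 → 95 100 at €100
display. The package reports the division result and treats the printed
value as unexplainable from the stated inputs.

## The synthetic generator

`generate_inputs(synth_spec(...))` emits structurally valid inputs — full
16-cell lattice, per-cell uniform SVR ranges of controllable width, one- or
two-variant costs, random composition — so every pipeline stage is testable
without the built-in fixture. Dominance modes construct inputs where the
entrant is provably tier 1 everywhere (`new_dominates`: SVR interval
strictly above all rivals', cost below the cheapest) or never in tiers 1–2
(`new_dominated`), which the tests assert across many seeds. Ranges are
clipped to a 0.01 floor by default so the closed-form oracle always exists
(`allow_zero_floor` lifts this to exercise the exclusion path).
`generate_degenerate_inputs()` collapses all ranges to points, making the
whole pipeline linear-algebraically exact in expectation mode — the
strongest oracle the tests use.

What the generator does **not** emulate: correlation between a therapy's
performance across subgroups, cost–efficacy correlation, multi-year uptake
dynamics, or any real epidemiology. Passing tests on synthetic inputs
demonstrate the machinery's correctness, not the realism of any particular
input set.

## Problem sizes

The reproduction runs (acceptance script, headline tests) use the full
10 000-run design of the case study; structural and property tests use
80–4 000 runs and 20–100 generator seeds, sizes chosen so the whole suite
exercises every path in well under the time a routine check should take.

## Known limitations

* **Scenario-1 membership is baseline-sensitive.** Under the default
  cheapest-rival baseline, the first takeover step consists of the
  SIM-backed null-responder cells only, and its ICER computes to ~€15.7k
  per additional cure — below the ~€21k the source reports for its smallest
  expansion. The source's narrative (scenario 1 covering "a large portion"
  of cirrhotic patients) implies a pre-entry market where BOC/TPV also held
  cirrhotic share; the `equal_eligible` baseline reproduces that membership
  (and a higher scenario-1 ICER) at the price of a pre-entry cure rate well
  below the published 69%. With the pre-entry shares unpublished, no single
  baseline reproduces both aggregates; the package defaults to the one that
  anchors scenario 0 and documents the tension rather than tuning it away.
* The direction of the scenario-4 vs scenario-0 *expenditure per SVR*
  comparison is composition-dependent; under the default assumptions it is
  marginally lower, not marginally higher.
* One-year horizon, direct drug costs only, static mixes, no re-treatment
  of failures, no interferon-intolerant stratum, and no non-GT1 genotypes —
  all scope choices inherited from the analysis design, not removable by
  configuration.
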