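---
title: "Scoring the greenness of pharmaceutical 3D printing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the greenness of pharmaceutical 3D printing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igapp)
```

## The model

`igapp` scores a pharmaceutical 3D-printing workflow on ten criteria
spanning its three stages — feed preparation (solvents, preparation
temperature, solvent removal, number of actives), printing (energy class,
temperature, time per product, waste handling) and post-curing (process
type, duration). Each criterion is banded **green**, **yellow** or **red**,
worth 100%, 50% or 0% of its weight; weights are
`r paste(igapp_criteria()$weight, collapse = ", ")` points and sum to 10, so

$$S \;=\; \sum_{i=1}^{10} w_i f_i, \qquad f_i \in \{1, \tfrac12, 0\},
\qquad 0 \le S \le 10 .$$

Energy consumption carries double weight (2 points) on the assumption that
printer energy is drawn from non-renewable sources and dominates the
footprint; the two post-curing criteria carry half weight (0.5 each) as the
stage is optional and short relative to the others.

The score is *relative*, not absolute: it flags which parts of a workflow
could be made greener (a red sector is an invitation to substitute a
solvent or lower a temperature), and it supports ranking competing methods
for the same product. It does not estimate emissions, toxicity loads or a
life-cycle inventory.

### Exact arithmetic

All weights are quarter-point rationals and band fractions are halves, so
every reachable total is a multiple of 0.25. The engine therefore works in
integer quarter-points internally (weights ×4, fractions in halves) and
divides once at the end: totals such as 7.25 and 5.75 are bit-exact, and
the test suite checks the engine against a brute-force floating-point dot
product over all $3^{10} = 59{,}049$ possible assignments.

## Banding rules and their conventions

The per-criterion rules are tabulated in `?igapp_criteria` and the README.
Conventions that required a decision:

* **Closed middle intervals.** Printed band edges (30–60 °C, 2.5–10 min,
  100–500 kPa, 26–110 °C) are read as closed: the green band is strictly
  below the lower edge, red strictly above the upper edge. This matches the
  reference profiles, where a 2.5-min print banded yellow.
* **The 110 °C printing edge.** Printing temperatures up to 110 °C count as
  moderate (yellow); above 110 °C red; an unheated ("ambient") print bed is
  green. Ambient is treated as a category, not a number, except in the
  feed-temperature rule where it counts as 25 °C (below the 30 °C edge).
* **Ranges classify by their maximum.** Sources typically report ranges
  ("printing at 80–100 °C", "11–14 min per product"); the conservative
  worst-case end governs. This reproduces every reference profile.
* **Post-curing time.** The published rubric prints "< 1 h | > 1 h",
  leaving exactly one hour unassigned; consistent with the closed-middle
  convention we band 1 h yellow. A workflow without post-curing is green on
  both post-curing criteria.
* **Multi-solvent feeds.** The rubric defines banding for one EI score.
  With several solvents the worst (minimum EI) governs by default — the
  conservative reading; `solvent_band(..., policy = "mean")` offers
  mean-EI aggregation as an alternative.
* **Combined post-curing steps** (e.g. washing followed by drying) band by
  their most energy-demanding step.

### Overall thresholds: two published variants

The source rubric states two conflicting overall bandings: its tabulated
form (> 7.5 green, 5–7.5 yellow, < 5 red) and its narrative form (> 7
green, 0–4.75 red), and its own validation classifies a 7.25-point method
as green — only consistent with the narrative form. We implement both as
named variants of `igapp_rubric()` and default to `"narrative"` because it
reproduces the published classifications; `"table2"` is one argument away.
Both leave boundary totals (5, and 7 or 7.5) in yellow, and the narrative
variant's unassigned gap (4.75, 5) falls to red under "< 5". Note that no
quarter-point total can actually land in that open interval.

### Solvent registry

Solvent environmental-impact scores (integer 1–10, 10 = most benign) follow
the GSK solvent selection guide. The bundled registry
(`default_solvents()`) ships only the four entries validated against the
reference profiles — water 10, ethanol 8, propanol 7, methylene chloride 6 —
rather than reproducing the full third-party guide; other solvents are
added via a user CSV (`read_solvents()`) or passed as explicit EI scores in
the process description. "Propanol" maps both the 1- and 2-isomer synonyms
to the published score, as the source does not state which was used.

### Overrides

A process description may force any criterion to a stated band
(`overrides =`). Overrides are applied after the rules, are only flagged
when they actually differ from the rule-derived band, and stay visible in
every report (`overridden` column, rationale text). They exist because the
published validation itself needs one: the reference SSE tablet profile
banded ambient drying at the intermediate level, while the banding rule —
and the comparative SSE film profile with the identical description — treat
ambient drying as a non-energy (green) step. The bundled Table-style SSE
fixture carries that override explicitly rather than hiding the
inconsistency in the rules.

## The bundled reference profiles

`igapp_fixtures()` returns nine encoded literature methods: one tablet
method per technology (BJ, FDM, SLA, SLS, SSE), a comparative FDM pair
(hot-melt extrusion vs. solvent casting) and a comparative SSE pair
(solvent-free hot extrusion at 600 kPa vs. aqueous ambient extrusion at
65 kPa). They are first-class package data — each is a validated
`igapp_process` re-created in code, not a stored file — and double as the
acceptance surface: their totals are 7.25, 5, 7.25, 5.75, 5.75, then
5 vs. 3.5 and 5 vs. 7.5 for the pairs.

```{r fixtures}
purrr::map_dbl(igapp_fixtures(), ~ igapp_score(.x)$total)
```

These fixtures emulate how published methods are reported — banded
descriptors, ranges, occasional missing waste information filled by stated
assumptions. They do not emulate measurement noise, solvent amounts, or
printer-model variability; a passing suite shows the rubric arithmetic and
rules are faithful, not that the rubric itself captures all real-world
impact (see Limitations).

## Rendering

`igapp_pictogram()` draws the score card as an SVG: ten equal 36° ring
sectors clockwise from the top in rubric order, heavier spokes delimiting
the three stages, and a centre disc filled with the overall band colour and
the two-decimal total. The published tool does not specify geometry or
palette, so both are free design, chosen once: default palette green
`#2E7D32`, yellow `#F9A825`, red `#C62828` (colour-blind-tolerant,
overridable via `igapp_style()`). Rendering is byte-deterministic — no
timestamps, no generated ids, fixed three-decimal coordinates — so golden
files are stable across machines. `autoplot()` gives the same chart as a
ggplot for interactive use.

```{r pictogram, fig.width = 5, fig.height = 5}
ggplot2::autoplot(igapp_score(igapp_fixtures()$BJ))
```

## Degenerate and edge inputs

* An empty solvent list means a solvent-free feed (green), not missing data;
  an unknown solvent name is an error instructing the user to extend the
  registry or pass an explicit EI score.
* A non-SSE process must not carry an extrusion pressure (it is structurally
  meaningless); an SSE process without one is an error, since its energy
  band would be undefined.
* `cure_process = "none"` requires `cure_time = "none"` and vice versa.
* Totals outside [0, 10] (impossible from the engine, possible from user
  input to `overall_band()`) raise a range error rather than clamping.

## Problem sizes

Everything here is desk-scale: the exhaustive assignment sweep is 59,049
ten-element sums, the property tests run a few thousand classifications,
and the full suite plus acceptance script complete in a few minutes on one
CPU.

## Limitations

Inherited from the rubric: solvent *amounts* are not weighed, energy is
classed per technology (plus SSE pressure) regardless of product size or
printer model, and the banding reflects small-scale lab printing — upscaled
manufacturing would need recalibrated edges. The registry is deliberately
minimal; extending it with further guide entries is the user's
responsibility. And the score is ordinal by construction: a 6.0 method is
not "twice as green" as a 3.0 one.
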