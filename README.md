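# igapp

Greenness scoring for pharmaceutical 3D printing.

Formulation scientists increasingly print dosage forms — tablets, polypills,
drug-eluting films — with binder jetting (BJ), fused deposition modeling
(FDM), stereolithography (SLA), selective laser sintering (SLS) or semisolid
extrusion (SSE). These workflows differ widely in solvent use, energy demand
and waste, yet greenness metrics built for analytical chemistry (NEMI,
eco-scale, GAPI, AGREE) do not capture a printing workflow's three stages:
feed preparation, printing, and post-curing. `igapp` implements a
ten-criterion, ten-point rubric for exactly that, for formulation scientists
who want to compare methods or find the weak points of their own.

## The rubric

Each criterion *i* is banded green, yellow or red, earning 100%, 50% or 0%
of its weight *w_i*; the total is the weighted sum

> S = Σᵢ wᵢ · fᵢ,  fᵢ ∈ {1, ½, 0},  Σᵢ wᵢ = 10.

| # | Criterion (weight) | green | yellow | red |
|---|--------------------|-------|--------|-----|
| 1 | Solvent environmental impact (1) | EI ≥ 8 | EI 4–7 | EI ≤ 3 |
| 2 | Feed temperature, °C (1) | < 30 | 30–60 | > 60 |
| 3 | Solvent removal (1) | none | ambient evaporation | heated (> 25 °C) |
| 4 | Active constituents (1) | > 2 | 2 | 1 |
| 5 | Energy consumption (2) | BJ, SSE < 100 kPa | SLA, SLS, SSE 100–500 kPa | FDM, SSE > 500 kPa |
| 6 | Printing temperature, °C (1) | ambient | 26–110 | > 110 |
| 7 | Printing time, min/product (1) | < 2.5 | 2.5–10 | > 10 |
| 8 | Waste treatment (1) | none | recycled | disposed |
| 9 | Post-curing process (0.5) | none / non-energy | drying < 60 °C | UV / high temperature |
| 10 | Post-curing time, h (0.5) | none | ≤ 1 | > 1 |

Solvent EI scores (1–10, 10 = most benign) follow the GSK solvent selection
guide; a small registry ships with the package and is user-extensible.
Totals are banded overall: above 7 green, below 5 red, otherwise yellow
(the default "narrative" variant; a stricter "table2" variant draws the
green line at 7.5). Arithmetic is exact quarter-point integer arithmetic, so
totals like 7.25 carry no floating-point fuzz. The result renders as the
familiar colour-coded pictogram: ten ring sectors around a centre disc with
the total.

## Worked example

Score the bundled SLS tablet method (ethanol-based feed, solvent removal at
40 °C, printing at 80–100 °C, recycled powder):

```r
library(igapp)
card <- igapp_score(igapp_fixtures()$SLS)
card
#> <igapp score card: SLS>
#>   total 5.75 / 10  [YELLOW overall, narrative thresholds]
#>   pre_processing:
#>     [G] Solvent environmental impact 1.00/1
#>     [G] Feed preparation temperature 1.00/1
#>     [R] Solvent removal              0.00/1
#>     [R] No. active constituents      0.00/1
#>   printing:
#>     [Y] Energy consumption           1.00/2
#>     [Y] Printing temperature         0.50/1
#>     [G] Printing time per product    1.00/1
#>     [Y] Waste treatment              0.50/1
#>   post_curing:
#>     [G] Post-curing process          0.50/0.5
#>     [Y] Post-curing time             0.25/0.5
```

The method totals 5.75 of 10 — an intermediate-green ("acceptable")
procedure; the red rows (heated solvent removal, single active) are its
weak points. `tidy(card)` returns the per-criterion audit trail as a
tibble, `glance(card)` the one-row summary, `ggplot2::autoplot(card)` the
pictogram as a ggplot, and `write_pictogram(card, "sls.svg")` the
deterministic SVG.

Comparing two FDM feed-preparation strategies (hot-melt extrusion vs.
solvent casting with methylene chloride):

```r
fx <- igapp_fixtures()
igapp_compare(fx$`FDM 1`, fx$`FDM 2`)[, 1:5]
#>    rank method total overall solvent_ei
#> 1     1 FDM 1    5   yellow  green
#> 2     2 FDM 2    3.5 red     yellow
```

The solvent-cast route loses 1.5 points to its solvent and removal step and
is classified nongreen.

Your own methods are described with `igapp_process()` in R, or as YAML/JSON
documents read by `read_process()`; a thin command-line wrapper lives at
`inst/cli/igapp.R` (`score`, `compare`, `solvents`, `fixtures` subcommands).

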