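Package: igapp
Title: Greenness Assessment of 3D-Printed Pharmaceuticals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the environmental friendliness ("greenness") of
    pharmaceutical three-dimensional printing workflows against a
    ten-criterion, ten-point weighted rubric spanning feed preparation,
    printing, and post-curing. Classifies structured process descriptions
    into green/yellow/red bands per criterion, computes exact quarter-point
    totals, looks up solvent environmental-impact scores from an extensible
    registry, renders the result as a deterministic colour-coded SVG
    pictogram, and ranks competing methods. Bundles the nine reference
    method profiles used to validate the rubric.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
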