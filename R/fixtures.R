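#' Bundled reference method profiles
#'
#' Returns the nine literature 3D-printing methods used to validate the
#' rubric: one tablet method per technology (BJ, FDM, SLA, SLS, SSE), a pair
#' of FDM tablet methods differing in feed preparation (hot-melt extrusion
#' vs. solvent casting), and a pair of SSE film methods differing in printing
#' temperature and extrusion pressure. Each fixture encodes the published
#' process descriptors; the Table-3 SSE fixture carries an explicit override
#' of the post-curing-process criterion to yellow, because the published
#' profile scores its ambient drying at the intermediate level while the
#' banding rule (and the comparative SSE profile with the identical
#' description) treats ambient drying as green.
#'
#' Expected totals under the default rubric: BJ 7.25, FDM 5, SLA 7.25,
#' SLS 5.75, SSE 5.75; FDM 1 5, FDM 2 3.5; SSE 1 5, SSE 2 7.5.
#'
#' @return A named list of nine [igapp_process()] objects: `BJ`, `FDM`,
#'   `SLA`, `SLS`, `SSE`, `FDM 1`, `FDM 2`, `SSE 1`, `SSE 2`.
#' @examples
#' purrr::map_dbl(igapp_fixtures(), ~ igapp_score(.x)$total)
#' @export
igapp_fixtures <- function() {
  fx <- list(
    # binder-jetted tablets: water-based binder, ambient processing,
    # post-cured by washing plus ~12 h drying at 40 degC
    igapp_process(
      name = "BJ", technology = "BJ",
      feed_solvents = "water", feed_temperature = "ambient",
      solvent_removal = "none", n_actives = 1,
      print_temperature = "ambient", print_time = 2.5,
      waste = "recycled",
      cure_process = "low_heat_drying", cure_time = 12
    ),
    # FDM tablets from hot-melt-extruded filament; solvent-free, hot
    igapp_process(
      name = "FDM", technology = "FDM",
      feed_solvents = list(), feed_temperature = c(80, 110),
      solvent_removal = "none", n_actives = 1,
      print_temperature = c(180, 190), print_time = 2,
      waste = "none",
      cure_process = "none", cure_time = "none"
    ),
    # SLA polypill: four actives photopolymerised at ambient temperature,
    # support resin disposed, washed after printing
    igapp_process(
      name = "SLA", technology = "SLA",
      feed_solvents = list(), feed_temperature = "ambient",
      solvent_removal = "none", n_actives = 4,
      print_temperature = "ambient", print_time = c(2.5, 10),
      waste = "disposed",
      cure_process = "non_energy", cure_time = 0.5
    ),
    # SLS tablets: ethanol in feed, removed at 40 degC; powder recycled
    igapp_process(
      name = "SLS", technology = "SLS",
      feed_solvents = "ethanol", feed_temperature = "ambient",
      solvent_removal = "evap_heated", n_actives = 1,
      print_temperature = c(80, 100), print_time = 2,
      waste = "recycled",
      cure_process = "non_energy", cure_time = 0.5
    ),
    # SSE tablets: propanol-based gel extruded at 55-65 kPa, slow printing,
    # dried at room temperature for over an hour. The published profile
    # banded the ambient drying at the intermediate level; kept via override.
    igapp_process(
      name = "SSE", technology = "SSE",
      feed_solvents = "propanol", feed_temperature = 70,
      solvent_removal = "none", n_actives = 1,
      extrusion_pressure = c(55, 65),
      print_temperature = "ambient", print_time = c(11, 14),
      waste = "none",
      cure_process = "non_energy", cure_time = 2,
      overrides = c(cure_process = "yellow")
    ),
    # comparative FDM pair: hot-melt extrusion ...
    igapp_process(
      name = "FDM 1", technology = "FDM",
      feed_solvents = list(), feed_temperature = c(170, 200),
      solvent_removal = "none", n_actives = 1,
      print_temperature = c(195, 208), print_time = 2,
      waste = "none",
      cure_process = "none", cure_time = "none"
    ),
    # ... vs. solvent casting with methylene chloride (EI 6), removed by
    # ambient evaporation
    igapp_process(
      name = "FDM 2", technology = "FDM",
      feed_solvents = 6, feed_temperature = 140,
      solvent_removal = "evap_ambient", n_actives = 1,
      print_temperature = 164, print_time = c(2.5, 10),
      waste = "none",
      cure_process = "none", cure_time = "none"
    ),
    # comparative SSE pair: solvent-free hot extrusion at 600 kPa ...
    igapp_process(
      name = "SSE 1", technology = "SSE",
      feed_solvents = list(), feed_temperature = 140,
      solvent_removal = "none", n_actives = 1,
      extrusion_pressure = 600,
      print_temperature = 140, print_time = 2,
      waste = "none",
      cure_process = "none", cure_time = "none"
    ),
    # ... vs. aqueous feed extruded at 65 kPa at room temperature, dried
    # ambiently for over an hour
    igapp_process(
      name = "SSE 2", technology = "SSE",
      feed_solvents = 10, feed_temperature = 70,
      solvent_removal = "none", n_actives = 1,
      extrusion_pressure = 65,
      print_temperature = "ambient", print_time = 2,
      waste = "none",
      cure_process = "non_energy", cure_time = 2
    )
  )
  stats::setNames(fx, purrr::map_chr(fx, "name"))
}
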