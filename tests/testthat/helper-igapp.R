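# Shared fixtures for the test suite.

criteria_ids <- igapp_criteria()$criterion

# Complete band assignment with per-criterion overrides
make_bands <- function(..., default = "green") {
  bands <- stats::setNames(rep(default, length(criteria_ids)), criteria_ids)
  dots <- c(...)
  bands[names(dots)] <- dots
  bands
}

# Published per-criterion sub-scores (points) of the nine reference
# profiles, in rubric order, as printed in the validation tables.
published_points <- list(
  "BJ"    = c(1, 1, 1, 0, 2, 1, 0.5, 0.5, 0.25, 0),
  "FDM"   = c(1, 0, 1, 0, 0, 0, 1, 1, 0.5, 0.5),
  "SLA"   = c(1, 1, 1, 1, 1, 1, 0.5, 0, 0.5, 0.25),
  "SLS"   = c(1, 1, 0, 0, 1, 0.5, 1, 0.5, 0.5, 0.25),
  "SSE"   = c(0.5, 0, 1, 0, 2, 1, 0, 1, 0.25, 0),
  "FDM 1" = c(1, 0, 1, 0, 0, 0, 1, 1, 0.5, 0.5),
  "FDM 2" = c(0.5, 0, 0.5, 0, 0, 0, 0.5, 1, 0.5, 0.5),
  "SSE 1" = c(1, 0, 1, 0, 0, 0, 1, 1, 0.5, 0.5),
  "SSE 2" = c(1, 0, 1, 0, 2, 1, 1, 1, 0.5, 0)
)

# A minimal valid SSE process, modifiable field-by-field for boundary tests
base_sse <- function(...) {
  args <- list(
    name = "probe", technology = "SSE",
    feed_solvents = list(), feed_temperature = "ambient",
    solvent_removal = "none", n_actives = 1,
    extrusion_pressure = 50, print_temperature = "ambient",
    print_time = 1, waste = "none",
    cure_process = "none", cure_time = "none"
  )
  dots <- list(...)
  args[names(dots)] <- dots # [<- keeps NULLs, so fields can be blanked
  do.call(igapp_process, args)
}

band_of <- function(process, criterion) {
  a <- classify_process(process)
  a$band[a$criterion == criterion]
}
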