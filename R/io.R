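# Document I/O: process descriptions and rubrics serialise to YAML or JSON
# (chosen by file extension); score reports serialise to JSON with the full
# audit trail.

doc_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) "yaml" else if (ext == "json") "json" else {
    stop(sprintf("unsupported document extension '.%s' (use .yaml or .json)", ext),
      call. = FALSE
    )
  }
}

read_doc <- function(path) {
  switch(doc_format(path),
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE)
  )
}

write_doc <- function(x, path) {
  switch(doc_format(path),
    yaml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path,
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
  )
  invisible(path)
}

process_to_list <- function(process) {
  num_or <- function(v) if (is.numeric(v)) as.numeric(v) else v
  out <- list(
    name = process$name,
    technology = process$technology,
    feed_solvents = process$feed_solvents,
    feed_temperature = num_or(process$feed_temperature),
    solvent_removal = process$solvent_removal,
    n_actives = process$n_actives,
    print_temperature = num_or(process$print_temperature),
    print_time = process$print_time,
    waste = process$waste,
    cure_process = process$cure_process,
    cure_time = process$cure_time
  )
  if (!is.null(process$extrusion_pressure)) {
    out$extrusion_pressure <- process$extrusion_pressure
  }
  if (!is.null(process$overrides)) {
    out$overrides <- as.list(process$overrides)
  }
  out
}

#' Read a process description from YAML or JSON
#'
#' The document carries the fields of [igapp_process()] with fixed units
#' (degC, kPa, minutes, hours) and the literal `ambient` for unheated steps.
#' The description is validated on read; malformed documents fail with a
#' message naming the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [igapp_process()].
#' @export
read_process <- function(path) {
  doc <- read_doc(path)
  if (!is.list(doc) || is.null(doc$name)) {
    stop(sprintf("'%s' does not contain a process description", path),
      call. = FALSE
    )
  }
  overrides <- if (!is.null(doc$overrides)) unlist(doc$overrides)
  igapp_process(
    name = doc$name,
    technology = doc$technology %||% stop("field 'technology' is required", call. = FALSE),
    feed_solvents = doc$feed_solvents %||% list(),
    feed_temperature = simplify_field(doc$feed_temperature %||% "ambient"),
    solvent_removal = doc$solvent_removal %||% "none",
    n_actives = doc$n_actives %||% 1L,
    extrusion_pressure = simplify_field(doc$extrusion_pressure),
    print_temperature = simplify_field(doc$print_temperature %||% "ambient"),
    print_time = simplify_field(doc$print_time),
    waste = doc$waste %||% "none",
    cure_process = doc$cure_process %||% "none",
    cure_time = simplify_field(doc$cure_time %||% "none"),
    overrides = overrides
  )
}

# YAML list fields (e.g. a 2-element temperature range) arrive as lists
simplify_field <- function(x) {
  if (is.list(x)) unlist(x) else x
}

#' Write a process description to YAML or JSON
#'
#' Inverse of [read_process()]; the two round-trip to an identical object.
#'
#' @param process An [igapp_process()].
#' @param path Output `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_process <- function(process, path) {
  stopifnot(inherits(process, "igapp_process"))
  write_doc(process_to_list(process), path)
}

#' Write a rubric specification to YAML or JSON
#'
#' @param rubric An [igapp_rubric()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rubric <- function(rubric, path) {
  stopifnot(inherits(rubric, "igapp_rubric"))
  write_doc(
    list(
      variant = rubric$variant,
      weights = as.list(rubric$weights),
      green_threshold = rubric$green_threshold,
      red_threshold = rubric$red_threshold
    ),
    path
  )
}

#' Read a rubric specification from YAML or JSON
#'
#' @param path Path to a rubric document written by [write_rubric()].
#' @return An [igapp_rubric()].
#' @export
read_rubric <- function(path) {
  doc <- read_doc(path)
  rubric <- igapp_rubric(
    variant = doc$variant %||% "narrative",
    weights = unlist(doc$weights %||% NULL)
  )
  if (!is.null(doc$green_threshold)) rubric$green_threshold <- doc$green_threshold
  if (!is.null(doc$red_threshold)) rubric$red_threshold <- doc$red_threshold
  if (rubric$red_threshold >= rubric$green_threshold) {
    stop("rubric red threshold must be below the green threshold", call. = FALSE)
  }
  rubric
}

#' Write a machine-readable score report
#'
#' Serialises the full score card — total, overall band, rubric variant, and
#' the per-criterion audit trail (encoded value, band, rule-derived band,
#' awarded points, rationale, override flag) — as JSON.
#'
#' @param card An `igapp_scorecard`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(card, path) {
  stopifnot(inherits(card, "igapp_scorecard"))
  report <- list(
    method = card$name,
    total = card$total,
    total_formatted = format_total(card$total),
    overall = card$overall,
    rubric = list(
      variant = card$rubric$variant,
      green_threshold = card$rubric$green_threshold,
      red_threshold = card$rubric$red_threshold
    ),
    criteria = card$assignments
  )
  jsonlite::write_json(report, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
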