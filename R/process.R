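technologies <- function() c("BJ", "FDM", "SLA", "SLS", "SSE")

ambient_tokens <- function() c("ambient", "room temperature", "rt")

is_ambient <- function(x) {
  is.character(x) && length(x) == 1 && normalise_name(x) %in% ambient_tokens()
}

check_temperature <- function(x, field) {
  if (is_ambient(x)) {
    return("ambient")
  }
  if (!is.numeric(x) || length(x) < 1 || length(x) > 2 || any(is.na(x)) ||
      any(x < 0)) {
    stop(sprintf(
      "%s must be 'ambient' or a non-negative temperature (or range) in degC",
      field
    ), call. = FALSE)
  }
  as.numeric(x)
}

#' Describe a 3D-printing workflow
#'
#' Builds a validated structured description of one pharmaceutical
#' 3D-printing method, covering the three assessed stages: feed preparation,
#' printing and post-curing. This is the input to [classify_process()] /
#' [igapp_score()].
#'
#' Temperatures are in degrees Celsius, pressures in kPa, printing time in
#' minutes per product, post-curing time in hours. Where a source reports a
#' range (e.g. printing at 80–100 degC), pass the range as a length-2 numeric
#' vector; classification is conservative and uses the maximum. The literal
#' `"ambient"` (or `"room temperature"`) marks unheated steps and is treated
#' as a category, not a number, except for the feed-temperature rule where it
#' counts as 25 degC.
#'
#' @param name Method name used in reports.
#' @param technology One of `"BJ"`, `"FDM"`, `"SLA"`, `"SLS"`, `"SSE"`.
#' @param feed_solvents Solvents used to prepare the printer feed: a
#'   character vector of names resolved against the registry, a numeric
#'   vector of explicit EI scores, or a mixed list. Empty means
#'   solvent-free.
#' @param feed_temperature Feed-preparation temperature (degC, range allowed)
#'   or `"ambient"`.
#' @param solvent_removal `"none"`, `"evap_ambient"` (evaporation at room
#'   temperature) or `"evap_heated"` (any evaporation above 25 degC).
#' @param n_actives Number of active constituents combined in the product
#'   (positive integer).
#' @param extrusion_pressure Extrusion pressure in kPa (range allowed).
#'   Required for SSE, disallowed otherwise.
#' @param print_temperature Printing temperature (degC, range allowed) or
#'   `"ambient"`.
#' @param print_time Printing time per product in minutes (range allowed).
#' @param waste `"none"`, `"recycled"` or `"disposed"`.
#' @param cure_process `"none"`, `"non_energy"` (ambient drying, washing,
#'   powder removal), `"low_heat_drying"` (drying below 60 degC) or
#'   `"high_energy"` (UV curing, high-temperature treatment).
#' @param cure_time Post-curing duration in hours, or `"none"` when there is
#'   no post-curing.
#' @param overrides Optional named character vector forcing specific
#'   criteria to a band (names from [igapp_criteria()], values band levels).
#'   Overrides are applied after the rules and flagged in every report.
#' @return An object of class `igapp_process`.
#' @examples
#' igapp_process(
#'   name = "example SSE", technology = "SSE",
#'   feed_solvents = "water", feed_temperature = 70,
#'   solvent_removal = "none", n_actives = 1,
#'   extrusion_pressure = 65, print_temperature = "ambient",
#'   print_time = 2, waste = "none",
#'   cure_process = "non_energy", cure_time = 12
#' )
#' @export
igapp_process <- function(name,
                          technology,
                          feed_solvents = list(),
                          feed_temperature = "ambient",
                          solvent_removal = c("none", "evap_ambient", "evap_heated"),
                          n_actives = 1L,
                          extrusion_pressure = NULL,
                          print_temperature = "ambient",
                          print_time,
                          waste = c("none", "recycled", "disposed"),
                          cure_process = c("none", "non_energy", "low_heat_drying", "high_energy"),
                          cure_time = "none",
                          overrides = NULL) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("process name must be a non-empty string", call. = FALSE)
  }
  technology <- toupper(as.character(technology))
  if (length(technology) != 1 || !technology %in% technologies()) {
    stop(sprintf(
      "technology must be one of %s", paste(technologies(), collapse = ", ")
    ), call. = FALSE)
  }
  solvent_removal <- match.arg(solvent_removal)
  waste <- match.arg(waste)
  cure_process <- match.arg(cure_process)

  feed_solvents <- as.list(feed_solvents)
  ok <- purrr::map_lgl(feed_solvents, function(s) {
    (is.character(s) && length(s) == 1 && nzchar(trimws(s))) ||
      (is.numeric(s) && length(s) == 1 && !is.na(s))
  })
  if (!all(ok)) {
    stop("feed_solvents entries must be solvent names or single EI scores",
      call. = FALSE
    )
  }

  if (!is.numeric(n_actives) || length(n_actives) != 1 || is.na(n_actives) ||
      n_actives < 1 || n_actives != round(n_actives)) {
    stop("n_actives must be a positive integer (at least one active)",
      call. = FALSE
    )
  }

  if (technology == "SSE") {
    if (is.null(extrusion_pressure) || !is.numeric(extrusion_pressure) ||
        length(extrusion_pressure) < 1 || length(extrusion_pressure) > 2 ||
        any(is.na(extrusion_pressure)) || any(extrusion_pressure < 0)) {
      stop(paste(
        "SSE processes require a non-negative extrusion_pressure in kPa",
        "(the energy band is undefined without it)"
      ), call. = FALSE)
    }
  } else if (!is.null(extrusion_pressure)) {
    stop(sprintf(
      "extrusion_pressure applies only to SSE, not %s", technology
    ), call. = FALSE)
  }

  if (missing(print_time) || !is.numeric(print_time) ||
      length(print_time) < 1 || length(print_time) > 2 ||
      any(is.na(print_time)) || any(print_time < 0)) {
    stop("print_time must be a non-negative time (or range) in minutes",
      call. = FALSE
    )
  }

  if (identical(cure_time, "none") || is.null(cure_time)) {
    cure_time <- "none"
  } else if (!is.numeric(cure_time) || length(cure_time) != 1 ||
             is.na(cure_time) || cure_time < 0) {
    stop("cure_time must be 'none' or a non-negative duration in hours",
      call. = FALSE
    )
  }
  if (cure_process == "none" && !identical(cure_time, "none")) {
    stop("cure_time given but cure_process is 'none'", call. = FALSE)
  }
  if (cure_process != "none" && identical(cure_time, "none")) {
    stop(sprintf(
      "cure_process '%s' requires a cure_time in hours", cure_process
    ), call. = FALSE)
  }

  if (!is.null(overrides)) {
    if (is.null(names(overrides)) ||
        !all(names(overrides) %in% igapp_criteria()$criterion)) {
      stop("overrides must be named by criterion identifiers", call. = FALSE)
    }
    overrides <- stats::setNames(check_band(overrides, "override"), names(overrides))
  }

  structure(
    list(
      name = name,
      technology = technology,
      feed_solvents = feed_solvents,
      feed_temperature = check_temperature(feed_temperature, "feed_temperature"),
      solvent_removal = solvent_removal,
      n_actives = as.integer(n_actives),
      extrusion_pressure = if (technology == "SSE") as.numeric(extrusion_pressure),
      print_temperature = check_temperature(print_temperature, "print_temperature"),
      print_time = as.numeric(print_time),
      waste = waste,
      cure_process = cure_process,
      cure_time = cure_time,
      overrides = overrides
    ),
    class = "igapp_process"
  )
}

#' @export
print.igapp_process <- function(x, ...) {
  fmt_rng <- function(v) {
    if (identical(v, "ambient")) "ambient" else paste(v, collapse = "-")
  }
  solv <- if (length(x$feed_solvents) == 0) {
    "none"
  } else {
    paste(purrr::map_chr(x$feed_solvents, ~ paste(.x)), collapse = ", ")
  }
  cat(sprintf("<igapp process: %s (%s)>\n", x$name, x$technology))
  cat(sprintf(
    "  feed: solvents %s; %s degC; removal %s; %d active(s)\n",
    solv, fmt_rng(x$feed_temperature), x$solvent_removal, x$n_actives
  ))
  cat(sprintf(
    "  printing: %s degC; %s min/product%s; waste %s\n",
    fmt_rng(x$print_temperature), fmt_rng(x$print_time),
    if (!is.null(x$extrusion_pressure)) {
      sprintf("; %s kPa", fmt_rng(x$extrusion_pressure))
    } else {
      ""
    },
    x$waste
  ))
  cat(sprintf(
    "  post-curing: %s%s\n", x$cure_process,
    if (identical(x$cure_time, "none")) "" else sprintf(", %g h", x$cure_time)
  ))
  if (!is.null(x$overrides)) {
    cat(sprintf(
      "  overrides: %s\n",
      paste(names(x$overrides), x$overrides, sep = "=", collapse = ", ")
    ))
  }
  invisible(x)
}
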