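# Per-criterion banding rules. Each returns list(band, value, rationale).
# Ranges are classified by their maximum (conservative, worst-case reading).

rule_solvent_ei <- function(process, registry) {
  if (length(process$feed_solvents) == 0) {
    return(list(
      band = "green", value = "no solvent",
      rationale = "solvent-free feed preparation"
    ))
  }
  scores <- purrr::map_int(process$feed_solvents, function(s) {
    if (is.numeric(s)) {
      if (s < 1 || s > 10) {
        stop(sprintf("explicit solvent EI score %s outside 1..10", s),
          call. = FALSE
        )
      }
      as.integer(s)
    } else {
      solvent_lookup(s, registry)$ei_score
    }
  })
  labels <- purrr::map_chr(process$feed_solvents, function(s) {
    if (is.numeric(s)) sprintf("EI %d", as.integer(s)) else as.character(s)
  })
  band <- solvent_band(scores)
  list(
    band = band,
    value = paste(sprintf("%s (%d)", labels, scores), collapse = ", "),
    rationale = sprintf(
      "minimum solvent EI %d: %s", min(scores),
      switch(band,
        green = ">= 8 (green solvent)",
        yellow = "in 4-7 (intermediate solvent)",
        red = "<= 3 (nongreen solvent)"
      )
    )
  )
}

rule_feed_temp <- function(process) {
  t <- process$feed_temperature
  ambient <- identical(t, "ambient")
  tmax <- if (ambient) 25 else max(t)
  band <- if (tmax < 30) "green" else if (tmax <= 60) "yellow" else "red"
  list(
    band = band,
    value = if (ambient) "ambient" else paste0(paste(t, collapse = "-"), " degC"),
    rationale = sprintf(
      "feed prepared at %s degC%s: %s",
      format(tmax), if (ambient) " (ambient)" else "",
      switch(band, green = "< 30", yellow = "in 30-60", red = "> 60")
    )
  )
}

rule_solvent_removal <- function(process) {
  switch(process$solvent_removal,
    none = list(
      band = "green", value = "none",
      rationale = "no solvent removal required"
    ),
    evap_ambient = list(
      band = "yellow", value = "evaporation at room temperature",
      rationale = "solvent evaporated at room temperature"
    ),
    evap_heated = list(
      band = "red", value = "heated evaporation",
      rationale = "solvent evaporated above 25 degC (heated)"
    )
  )
}

rule_n_actives <- function(process) {
  n <- process$n_actives
  band <- if (n > 2) "green" else if (n == 2) "yellow" else "red"
  list(
    band = band, value = as.character(n),
    rationale = sprintf(
      "%d active constituent(s): %s", n,
      switch(band,
        green = "more than two combined",
        yellow = "two combined",
        red = "single active"
      )
    )
  )
}

rule_energy <- function(process) {
  tech <- process$technology
  if (tech == "SSE") {
    p <- max(process$extrusion_pressure)
    band <- if (p < 100) "green" else if (p <= 500) "yellow" else "red"
    return(list(
      band = band,
      value = sprintf("SSE at %s kPa", paste(process$extrusion_pressure, collapse = "-")),
      rationale = sprintf(
        "SSE extrusion pressure %s kPa: %s", format(p),
        switch(band, green = "< 100", yellow = "in 100-500", red = "> 500")
      )
    ))
  }
  band <- switch(tech, BJ = "green", SLA = "yellow", SLS = "yellow", FDM = "red")
  list(
    band = band, value = tech,
    rationale = switch(tech,
      BJ = "binder jetting runs under ambient conditions (lowest energy class)",
      SLA = "UV-laser photopolymerisation (intermediate energy class)",
      SLS = "laser sintering (intermediate energy class)",
      FDM = "heated-extrusion printing (highest energy class)"
    )
  )
}

rule_print_temp <- function(process) {
  t <- process$print_temperature
  ambient <- identical(t, "ambient")
  if (ambient) {
    return(list(
      band = "green", value = "ambient",
      rationale = "printing at room temperature (no heating)"
    ))
  }
  tmax <- max(t)
  band <- if (tmax <= 25) "green" else if (tmax <= 110) "yellow" else "red"
  list(
    band = band, value = paste0(paste(t, collapse = "-"), " degC"),
    rationale = sprintf(
      "printing at %s degC: %s", format(tmax),
      switch(band,
        green = "at or below room temperature",
        yellow = "moderate heating (26-110)",
        red = "> 110"
      )
    )
  )
}

rule_print_time <- function(process) {
  tmax <- max(process$print_time)
  band <- if (tmax < 2.5) "green" else if (tmax <= 10) "yellow" else "red"
  list(
    band = band,
    value = paste0(paste(process$print_time, collapse = "-"), " min"),
    rationale = sprintf(
      "%s min per product: %s", format(tmax),
      switch(band, green = "< 2.5", yellow = "in 2.5-10", red = "> 10")
    )
  )
}

rule_waste <- function(process) {
  switch(process$waste,
    none = list(
      band = "green", value = "no waste",
      rationale = "process generates no waste"
    ),
    recycled = list(
      band = "yellow", value = "recycled",
      rationale = "waste is recycled"
    ),
    disposed = list(
      band = "red", value = "disposed",
      rationale = "waste is disposed of"
    )
  )
}

rule_cure_process <- function(process) {
  switch(process$cure_process,
    none = list(
      band = "green", value = "none",
      rationale = "no post-curing step"
    ),
    non_energy = list(
      band = "green", value = "non-energy-consuming",
      rationale = "non-energy-consuming post-processing (ambient drying, washing or powder removal)"
    ),
    low_heat_drying = list(
      band = "yellow", value = "drying < 60 degC",
      rationale = "drying at low heat (below 60 degC)"
    ),
    high_energy = list(
      band = "red", value = "high-energy curing",
      rationale = "UV or high-temperature post-curing (highest energy demand)"
    )
  )
}

rule_cure_time <- function(process) {
  if (identical(process$cure_time, "none")) {
    return(list(
      band = "green", value = "none",
      rationale = "no post-curing step"
    ))
  }
  h <- process$cure_time
  band <- if (h <= 1) "yellow" else "red"
  list(
    band = band, value = sprintf("%g h", h),
    rationale = sprintf(
      "post-curing for %g h: %s", h,
      switch(band, yellow = "at most 1 h", red = "longer than 1 h")
    )
  )
}

#' Classify a process against the ten criteria
#'
#' Applies the banding rules to a process description and returns the ten
#' per-criterion assignments with a full audit trail: the encoded value, the
#' triggering rule, and whether a user override replaced the rule-derived
#' band. Classification is a pure function of its inputs.
#'
#' @param process An [igapp_process()].
#' @param registry Solvent registry used to resolve named solvents.
#' @param rubric Rubric supplying criterion weights.
#' @return A tibble with one row per criterion: `criterion`, `section`,
#'   `label`, `band`, `rule_band`, `overridden`, `weight`, `points`, `value`,
#'   `rationale`.
#' @examples
#' classify_process(igapp_fixtures()$BJ)
#' @export
classify_process <- function(process, registry = default_solvents(),
                             rubric = igapp_rubric()) {
  stopifnot(inherits(process, "igapp_process"))
  rules <- list(
    solvent_ei = rule_solvent_ei(process, registry),
    feed_temp = rule_feed_temp(process),
    solvent_removal = rule_solvent_removal(process),
    n_actives = rule_n_actives(process),
    energy = rule_energy(process),
    print_temp = rule_print_temp(process),
    print_time = rule_print_time(process),
    waste = rule_waste(process),
    cure_process = rule_cure_process(process),
    cure_time = rule_cure_time(process)
  )
  tab <- igapp_criteria()
  tab$value <- unname(purrr::map_chr(rules[tab$criterion], "value"))
  tab$rule_band <- unname(purrr::map_chr(rules[tab$criterion], "band"))
  tab$rationale <- unname(purrr::map_chr(rules[tab$criterion], "rationale"))
  tab$band <- tab$rule_band
  tab$overridden <- FALSE
  if (!is.null(process$overrides)) {
    idx <- match(names(process$overrides), tab$criterion)
    tab$band[idx] <- unname(process$overrides)
    tab$overridden[idx] <- tab$band[idx] != tab$rule_band[idx]
    tab$rationale[idx] <- ifelse(
      tab$overridden[idx],
      sprintf(
        "user override to %s (rule gave %s: %s)",
        tab$band[idx], tab$rule_band[idx], tab$rationale[idx]
      ),
      tab$rationale[idx]
    )
  }
  tab$weight <- unname(rubric$weights[tab$criterion])
  qp <- rubric_weights_qp(rubric)
  tab$points <- (unname(qp[tab$criterion]) * band_halves(tab$band)) %/% 2L / 4
  tab[, c(
    "criterion", "section", "label", "band", "rule_band", "overridden",
    "weight", "points", "value", "rationale"
  )]
}

#' Score a 3D-printing workflow
#'
#' End-to-end scoring: classifies the process per criterion (see
#' [classify_process()]), sums the weighted band fractions in exact
#' quarter-point arithmetic, and bands the total. The result prints as a
#' readable breakdown and renders as a pictogram with [igapp_pictogram()] /
#' [autoplot()].
#'
#' @inheritParams classify_process
#' @return An `igapp_scorecard` (see [igapp_score_card()]).
#' @examples
#' card <- igapp_score(igapp_fixtures()$BJ)
#' card$total # 7.25
#' glance(card)
#' @export
igapp_score <- function(process, registry = default_solvents(),
                        rubric = igapp_rubric()) {
  assignments <- classify_process(process, registry, rubric)
  bands <- stats::setNames(assignments$band, assignments$criterion)
  igapp_score_card(bands, rubric, name = process$name, assignments = assignments)
}
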