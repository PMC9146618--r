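#' The ten assessment criteria
#'
#' Returns the criterion table of the greenness rubric: ten criteria grouped
#' into three workflow sections — feed pre-processing (4 criteria), the
#' printing process itself (4), and post-curing (2). Each criterion carries a
#' point weight; the weights sum to 10, so a fully green process scores 10.
#'
#' @return A tibble with one row per criterion and columns `criterion`
#'   (identifier), `section` (`"pre_processing"`, `"printing"`,
#'   `"post_curing"`), `label` (human-readable name) and `weight` (points).
#' @examples
#' igapp_criteria()
#' @export
igapp_criteria <- function() {
  tibble::tibble(
    criterion = c(
      "solvent_ei", "feed_temp", "solvent_removal", "n_actives",
      "energy", "print_temp", "print_time", "waste",
      "cure_process", "cure_time"
    ),
    section = rep(c("pre_processing", "printing", "post_curing"), c(4L, 4L, 2L)),
    label = c(
      "Solvent environmental impact", "Feed preparation temperature",
      "Solvent removal", "No. active constituents",
      "Energy consumption", "Printing temperature",
      "Printing time per product", "Waste treatment",
      "Post-curing process", "Post-curing time"
    ),
    weight = c(1, 1, 1, 1, 2, 1, 1, 1, 0.5, 0.5)
  )
}

# Criterion weights in integer quarter-points; all total arithmetic is done on
# these so quarter-valued totals (7.25, 5.75, ...) are bit-exact.
criterion_weights_qp <- function() {
  w <- igapp_criteria()
  stats::setNames(as.integer(round(w$weight * 4)), w$criterion)
}

band_levels <- function() c("green", "yellow", "red")

#' Band score fractions
#'
#' A criterion banded green earns 100% of its weight, yellow 50%, red 0%.
#'
#' @param level Character vector of band levels (`"green"`, `"yellow"`,
#'   `"red"`).
#' @return Numeric vector of fractions in `{1, 0.5, 0}`.
#' @examples
#' band_fraction(c("green", "yellow", "red"))
#' @export
band_fraction <- function(level) {
  level <- check_band(level)
  c(green = 1, yellow = 0.5, red = 0)[level]
}

# band fractions in halves (green 2, yellow 1, red 0) for exact arithmetic
band_halves <- function(level) {
  unname(c(green = 2L, yellow = 1L, red = 0L)[level])
}

check_band <- function(level, arg = "band") {
  level <- tolower(trimws(as.character(level)))
  bad <- setdiff(unique(level), band_levels())
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid %s level(s): %s (expected green, yellow or red)",
      arg, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  level
}

#' Rubric specification
#'
#' Builds the scoring rubric: criterion weights plus the thresholds that band
#' the overall total. Two published threshold variants exist and disagree at
#' the green edge:
#'
#' * `"narrative"` (default): totals strictly above 7 are green, strictly
#'   below 5 red, otherwise yellow. This variant reproduces the reference
#'   classifications of the validation profiles (a 7.25 method is green).
#' * `"table2"`: green above 7.5, red below 5, the closed interval
#'   \[5, 7.5\] yellow.
#'
#' Under both variants the boundary totals 5 and 7 (or 7.5) fall in yellow.
#'
#' @param variant `"narrative"` or `"table2"`.
#' @param weights Optional named numeric vector of criterion weights
#'   (quarter-point granularity, must cover the ten criteria and sum to 10).
#'   Defaults to the standard weights.
#' @return An object of class `igapp_rubric`.
#' @examples
#' igapp_rubric()
#' igapp_rubric("table2")
#' @export
igapp_rubric <- function(variant = c("narrative", "table2"), weights = NULL) {
  variant <- match.arg(variant)
  if (is.null(weights)) {
    weights <- with(igapp_criteria(), stats::setNames(weight, criterion))
  }
  validate_rubric_weights(weights)
  thresholds <- switch(variant,
    narrative = c(green = 7, red = 5),
    table2 = c(green = 7.5, red = 5)
  )
  structure(
    list(
      variant = variant,
      weights = weights[igapp_criteria()$criterion],
      green_threshold = unname(thresholds["green"]),
      red_threshold = unname(thresholds["red"])
    ),
    class = "igapp_rubric"
  )
}

validate_rubric_weights <- function(weights) {
  crit <- igapp_criteria()$criterion
  if (!setequal(names(weights), crit) || length(weights) != length(crit)) {
    stop("rubric weights must be named for exactly the ten criteria", call. = FALSE)
  }
  qp <- weights * 4
  if (any(abs(qp - round(qp)) > 1e-9) || any(weights < 0)) {
    stop("rubric weights must be non-negative quarter-point values", call. = FALSE)
  }
  if (abs(sum(weights) - 10) > 1e-9) {
    stop("rubric weights must sum to 10 points", call. = FALSE)
  }
  invisible(weights)
}

#' @export
print.igapp_rubric <- function(x, ...) {
  cat(sprintf(
    "<igapp rubric: variant '%s'; green > %s, red < %s, yellow otherwise>\n",
    x$variant, format(x$green_threshold), format(x$red_threshold)
  ))
  invisible(x)
}

rubric_weights_qp <- function(rubric) {
  stats::setNames(as.integer(round(rubric$weights * 4)), names(rubric$weights))
}

check_assignments <- function(bands) {
  crit <- igapp_criteria()$criterion
  if (is.null(names(bands))) {
    stop("band assignments must be a named vector (criterion -> band)", call. = FALSE)
  }
  dup <- unique(names(bands)[duplicated(names(bands))])
  if (length(dup) > 0) {
    stop(sprintf("duplicate criterion assignment: %s", paste(dup, collapse = ", ")),
      call. = FALSE
    )
  }
  missing <- setdiff(crit, names(bands))
  if (length(missing) > 0) {
    stop(sprintf("missing criterion assignment: %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  unknown <- setdiff(names(bands), crit)
  if (length(unknown) > 0) {
    stop(sprintf("unknown criterion: %s", paste(unknown, collapse = ", ")),
      call. = FALSE
    )
  }
  stats::setNames(check_band(bands), names(bands))[crit]
}

#' Weighted total greenness score
#'
#' Sums `weight × band fraction` over the ten criteria. Arithmetic is carried
#' out in integer quarter-points, so the result is always an exact multiple
#' of 0.25 in \[0, 10\].
#'
#' @param bands Named character vector mapping every criterion (see
#'   [igapp_criteria()]) to a band level.
#' @param rubric An [igapp_rubric()].
#' @return A single numeric total.
#' @examples
#' bands <- c(
#'   solvent_ei = "green", feed_temp = "green", solvent_removal = "green",
#'   n_actives = "red", energy = "green", print_temp = "green",
#'   print_time = "yellow", waste = "yellow", cure_process = "yellow",
#'   cure_time = "red"
#' )
#' igapp_total(bands) # 7.25
#' @export
igapp_total <- function(bands, rubric = igapp_rubric()) {
  bands <- check_assignments(bands)
  qp <- rubric_weights_qp(rubric)
  # weight_qp is even for every quarter-point weight times half-fractions,
  # so the integer division below is exact
  sum(qp * band_halves(bands)) %/% 2L / 4
}

#' Band an overall total score
#'
#' @param total Numeric total(s) in \[0, 10\].
#' @param rubric An [igapp_rubric()] supplying the thresholds.
#' @return Character vector of band levels: green strictly above the green
#'   threshold, red strictly below the red threshold, yellow otherwise.
#' @examples
#' overall_band(c(8, 7.25, 4), igapp_rubric("table2"))
#' overall_band(7.25, igapp_rubric("narrative"))
#' @export
overall_band <- function(total, rubric = igapp_rubric()) {
  if (!is.numeric(total) || any(is.na(total)) || any(total < 0 | total > 10)) {
    stop("total score must lie in [0, 10]", call. = FALSE)
  }
  dplyr::case_when(
    total > rubric$green_threshold ~ "green",
    total < rubric$red_threshold ~ "red",
    .default = "yellow"
  )
}

#' Score card from explicit band assignments
#'
#' Assembles the full per-criterion score card for a complete map of band
#' assignments: awarded points per criterion (`weight × fraction`), the exact
#' quarter-point total and the overall band.
#'
#' @inheritParams igapp_total
#' @param name Optional method name carried into reports.
#' @param assignments Optional pre-built assignment tibble (as produced by
#'   [classify_process()]); when supplied, its audit columns (rationale,
#'   override flags) are preserved.
#' @return An object of class `igapp_scorecard`: a list with elements
#'   `name`, `assignments` (tibble), `total`, `overall` and `rubric`.
#' @examples
#' card <- igapp_score_card(
#'   c(
#'     solvent_ei = "green", feed_temp = "green", solvent_removal = "green",
#'     n_actives = "red", energy = "green", print_temp = "green",
#'     print_time = "yellow", waste = "yellow", cure_process = "yellow",
#'     cure_time = "red"
#'   ),
#'   name = "example"
#' )
#' card$total
#' @export
igapp_score_card <- function(bands, rubric = igapp_rubric(), name = NULL,
                             assignments = NULL) {
  bands <- check_assignments(bands)
  qp <- rubric_weights_qp(rubric)
  points_qp <- (qp[names(bands)] * band_halves(bands)) %/% 2L
  tab <- igapp_criteria()
  tab$band <- unname(bands[tab$criterion])
  tab$weight <- unname(rubric$weights[tab$criterion])
  tab$points <- unname(points_qp[tab$criterion]) / 4
  if (!is.null(assignments)) {
    extra <- assignments[, intersect(
      c("criterion", "value", "rationale", "rule_band", "overridden"),
      names(assignments)
    )]
    tab <- dplyr::left_join(tab, extra, by = "criterion")
  } else {
    tab$rationale <- sprintf("assigned %s", tab$band)
    tab$rule_band <- tab$band
    tab$overridden <- FALSE
  }
  total <- sum(points_qp) / 4
  structure(
    list(
      name = name %||% "unnamed method",
      assignments = tab,
      total = total,
      overall = overall_band(total, rubric),
      rubric = rubric
    ),
    class = "igapp_scorecard"
  )
}

#' Format a total score
#'
#' Totals are printed with two decimals (the pictogram centre text).
#'
#' @param total Numeric total.
#' @return Character scalar, e.g. `"7.25"`.
#' @export
format_total <- function(total) sprintf("%.2f", total)

#' @export
print.igapp_scorecard <- function(x, ...) {
  cat(sprintf(
    "<igapp score card: %s>\n  total %s / 10  [%s overall, %s thresholds]\n",
    x$name, format_total(x$total), toupper(x$overall), x$rubric$variant
  ))
  sym <- c(green = "G", yellow = "Y", red = "R")
  a <- x$assignments
  for (s in unique(a$section)) {
    rows <- a[a$section == s, ]
    cat(sprintf("  %s:\n", s))
    for (i in seq_len(nrow(rows))) {
      cat(sprintf(
        "    [%s] %-28s %4.2f/%g%s\n",
        sym[[rows$band[i]]], rows$label[i], rows$points[i], rows$weight[i],
        if (isTRUE(rows$overridden[i])) "  (override)" else ""
      ))
    }
  }
  invisible(x)
}
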