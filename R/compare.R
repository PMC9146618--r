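#' Compare the greenness of several methods
#'
#' Scores two or more processes under the same rubric and ranks them by
#' total score (descending), breaking ties alphabetically by method name so
#' the ranking is deterministic.
#'
#' @param ... [igapp_process()] objects and/or `igapp_scorecard`s, or a
#'   single list of them.
#' @param registry Solvent registry used when scoring processes.
#' @param rubric Rubric applied to every entry.
#' @return An `igapp_comparison`: a tibble with columns `rank`, `method`,
#'   `total`, `overall` and one band column per criterion, plus the score
#'   cards in the `"cards"` attribute.
#' @examples
#' fx <- igapp_fixtures()
#' igapp_compare(fx$`FDM 1`, fx$`FDM 2`)
#' @export
igapp_compare <- function(..., registry = default_solvents(),
                          rubric = igapp_rubric()) {
  entries <- rlang::list2(...)
  if (length(entries) == 1 && is.list(entries[[1]]) &&
      !inherits(entries[[1]], c("igapp_process", "igapp_scorecard"))) {
    entries <- entries[[1]]
  }
  if (length(entries) < 2) {
    stop("comparison needs at least two methods", call. = FALSE)
  }
  cards <- purrr::map(entries, function(e) {
    if (inherits(e, "igapp_scorecard")) {
      e
    } else if (inherits(e, "igapp_process")) {
      igapp_score(e, registry, rubric)
    } else {
      stop("entries must be igapp_process or igapp_scorecard objects",
        call. = FALSE
      )
    }
  })
  wide <- purrr::map(cards, function(card) {
    bands <- tidyr::pivot_wider(
      card$assignments[, c("criterion", "band")],
      names_from = "criterion", values_from = "band"
    )
    dplyr::bind_cols(
      tibble::tibble(method = card$name, total = card$total, overall = card$overall),
      bands
    )
  })
  out <- dplyr::arrange(
    dplyr::bind_rows(wide),
    dplyr::desc(.data$total), .data$method
  )
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  structure(out,
    cards = stats::setNames(cards, purrr::map_chr(cards, "name")),
    class = c("igapp_comparison", class(out))
  )
}

#' Per-criterion band differences between two compared methods
#'
#' @param comparison An [igapp_compare()] result.
#' @param a,b Method names present in the comparison.
#' @return A tibble with one row per criterion: the two bands and `delta`,
#'   the signed difference in band fractions (`fraction(a) - fraction(b)`;
#'   positive where `a` is greener).
#' @examples
#' cmp <- igapp_compare(igapp_fixtures()[c("SSE 1", "SSE 2")])
#' compare_deltas(cmp, "SSE 2", "SSE 1")
#' @export
compare_deltas <- function(comparison, a, b) {
  cards <- attr(comparison, "cards")
  for (nm in c(a, b)) {
    if (!nm %in% names(cards)) {
      stop(sprintf("method '%s' is not part of this comparison", nm),
        call. = FALSE
      )
    }
  }
  band_a <- stats::setNames(
    cards[[a]]$assignments$band, cards[[a]]$assignments$criterion
  )
  band_b <- stats::setNames(
    cards[[b]]$assignments$band, cards[[b]]$assignments$criterion
  )
  crit <- igapp_criteria()$criterion
  delta <- unname(band_fraction(band_a[crit]) - band_fraction(band_b[crit]))
  tibble::tibble(
    criterion = crit,
    band_a = unname(band_a[crit]),
    band_b = unname(band_b[crit]),
    delta = delta
  )
}

#' @export
print.igapp_comparison <- function(x, ...) {
  cat("<igapp comparison>\n")
  NextMethod()
  invisible(x)
}

#' Write a comparison as CSV
#'
#' @param comparison An [igapp_compare()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.csv(as.data.frame(comparison), path, row.names = FALSE)
  invisible(path)
}
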