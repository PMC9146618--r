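#' Tidy a score card into its per-criterion assignments
#'
#' @param x An `igapp_scorecard`.
#' @param ... Unused.
#' @return The assignment tibble: one row per criterion with its band,
#'   weight, awarded points, encoded value, rationale and override flag.
#' @examples
#' tidy(igapp_score(igapp_fixtures()$SLA))
#' @export
tidy.igapp_scorecard <- function(x, ...) {
  dplyr::mutate(x$assignments, method = x$name, .before = 1)
}

#' One-row summary of a score card
#'
#' @param x An `igapp_scorecard`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `total`, `overall`, `variant`,
#'   `n_overridden`.
#' @examples
#' glance(igapp_score(igapp_fixtures()$FDM))
#' @export
glance.igapp_scorecard <- function(x, ...) {
  tibble::tibble(
    method = x$name,
    total = x$total,
    overall = x$overall,
    variant = x$rubric$variant,
    n_overridden = sum(x$assignments$overridden)
  )
}

#' @export
generics::tidy

#' @export
generics::glance
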