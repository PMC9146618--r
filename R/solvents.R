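#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

normalise_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

#' Bundled solvent environmental-impact registry
#'
#' Loads the registry of solvent environmental-impact (EI) scores shipped
#' with the package. EI scores follow the GSK solvent-selection-guide scale
#' (integer 1–10, 10 = most benign). Only the reference-validated entries are
#' bundled (water, ethanol, propanol, methylene chloride); extend the
#' registry with [read_solvents()] on your own CSV, or pass explicit EI
#' scores in the process description.
#'
#' @return A tibble with columns `canonical_name`, `synonyms` (list column),
#'   `ei_score` (integer) and `provenance`.
#' @examples
#' default_solvents()
#' @export
default_solvents <- function() {
  read_solvents(system.file("extdata", "solvents.csv", package = "igapp"))
}

#' Read a solvent registry from CSV
#'
#' The file must have columns `canonical_name`, `synonyms`
#' (semicolon-separated, may be empty), `ei_score` and `provenance`.
#' Names and synonyms must be unique across the registry after lower-casing
#' and whitespace trimming; EI scores must be integers in 1–10.
#'
#' @param path Path to a CSV file.
#' @return A validated registry tibble (see [default_solvents()]).
#' @export
read_solvents <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("canonical_name", "synonyms", "ei_score", "provenance")
  if (!all(needed %in% names(raw))) {
    stop(sprintf(
      "solvent registry must have columns: %s", paste(needed, collapse = ", ")
    ), call. = FALSE)
  }
  reg <- tibble::tibble(
    canonical_name = as.character(raw$canonical_name),
    synonyms = purrr::map(raw$synonyms, function(s) {
      s <- trimws(strsplit(as.character(s %||% ""), ";")[[1]])
      s[nzchar(s)]
    }),
    ei_score = as.integer(raw$ei_score),
    provenance = as.character(raw$provenance)
  )
  validate_solvents(reg)
}

validate_solvents <- function(registry) {
  if (any(is.na(registry$ei_score)) ||
      any(registry$ei_score < 1L | registry$ei_score > 10L)) {
    stop("solvent EI scores must be integers in 1..10", call. = FALSE)
  }
  keys <- normalise_name(c(registry$canonical_name, unlist(registry$synonyms)))
  dup <- unique(keys[duplicated(keys)])
  if (length(dup) > 0) {
    stop(sprintf(
      "solvent names/synonyms not unique after normalisation: %s",
      paste(dup, collapse = ", ")
    ), call. = FALSE)
  }
  registry
}

#' Write a solvent registry to CSV
#'
#' Inverse of [read_solvents()]; the two round-trip losslessly.
#'
#' @param registry A registry tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_solvents <- function(registry, path) {
  validate_solvents(registry)
  out <- data.frame(
    canonical_name = registry$canonical_name,
    synonyms = vapply(registry$synonyms, paste, character(1), collapse = "; "),
    ei_score = registry$ei_score,
    provenance = registry$provenance
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Look up a solvent's environmental-impact score
#'
#' Matches `name` against canonical names and synonyms, case-insensitively
#' and ignoring surrounding/repeated whitespace.
#'
#' @param name Solvent name (character scalar).
#' @param registry A registry tibble; defaults to the bundled registry.
#' @return A one-row tibble (`canonical_name`, `synonyms`, `ei_score`,
#'   `provenance`).
#' @examples
#' solvent_lookup("Water")$ei_score # 10
#' solvent_lookup("dichloromethane")$ei_score # 6
#' @export
solvent_lookup <- function(name, registry = default_solvents()) {
  if (!is.character(name) || length(name) != 1 || !nzchar(trimws(name))) {
    stop("solvent name must be a non-empty string", call. = FALSE)
  }
  key <- normalise_name(name)
  hit <- purrr::map_lgl(seq_len(nrow(registry)), function(i) {
    key == normalise_name(registry$canonical_name[i]) ||
      key %in% normalise_name(registry$synonyms[[i]])
  })
  if (!any(hit)) {
    stop(sprintf(
      paste0(
        "solvent '%s' is not in the registry; add it with an EI score ",
        "(1-10) or supply the score directly in the process description"
      ), name
    ), call. = FALSE)
  }
  registry[which(hit)[1], ]
}

#' Band a set of solvent EI scores
#'
#' Maps the solvents used in feed preparation to a single green/yellow/red
#' band. An empty set (solvent-free process) is green. With several solvents
#' the default policy is conservative: the worst (minimum) EI score governs.
#' Band edges: EI >= 8 green, 4–7 yellow, <= 3 red.
#'
#' @param ei_scores Numeric vector of EI scores in 1–10 (may be empty).
#' @param policy `"min"` (default, worst solvent governs) or `"mean"`
#'   (band of the mean EI).
#' @return A band level (`"green"`, `"yellow"` or `"red"`).
#' @examples
#' solvent_band(integer(0)) # solvent-free: green
#' solvent_band(c(10, 7)) # worst of the two: yellow
#' @export
solvent_band <- function(ei_scores, policy = c("min", "mean")) {
  policy <- match.arg(policy)
  if (length(ei_scores) == 0) {
    return("green")
  }
  if (!is.numeric(ei_scores) || any(is.na(ei_scores)) ||
      any(ei_scores < 1 | ei_scores > 10)) {
    stop("solvent EI scores must lie in 1..10", call. = FALSE)
  }
  x <- switch(policy, min = min(ei_scores), mean = mean(ei_scores))
  if (x >= 8) "green" else if (x <= 3) "red" else "yellow"
}
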