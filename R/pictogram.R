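#' Pictogram style
#'
#' Palette, canvas size and fonts for [igapp_pictogram()]. Comparisons of
#' pictograms are structural (band colours, centre text), so the geometry is
#' free design; these defaults give a 420 px square canvas with a
#' colour-blind-tolerant deep green / amber / red palette.
#'
#' @param green,yellow,red Hex fill colours for the three bands.
#' @param size Canvas edge length in px.
#' @param font_family Font family used for all text.
#' @return A list of style settings.
#' @export
igapp_style <- function(green = "#2E7D32", yellow = "#F9A825", red = "#C62828",
                        size = 420, font_family = "Helvetica, Arial, sans-serif") {
  list(
    palette = c(green = green, yellow = yellow, red = red),
    size = size,
    font_family = font_family
  )
}

# fixed-format numbers so identical inputs give byte-identical SVG
svg_num <- function(x) sprintf("%.3f", x)

sector_path <- function(cx, cy, r0, r1, a0, a1) {
  # angles in degrees, clockwise from 12 o'clock
  pt <- function(r, a) {
    rad <- (a - 90) * pi / 180
    c(cx + r * cos(rad), cy + r * sin(rad))
  }
  p1 <- pt(r1, a0)
  p2 <- pt(r1, a1)
  p3 <- pt(r0, a1)
  p4 <- pt(r0, a0)
  large <- if ((a1 - a0) > 180) 1L else 0L
  sprintf(
    "M %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
    svg_num(p1[1]), svg_num(p1[2]), svg_num(r1), svg_num(r1), large,
    svg_num(p2[1]), svg_num(p2[2]), svg_num(p3[1]), svg_num(p3[2]),
    svg_num(r0), svg_num(r0), large, svg_num(p4[1]), svg_num(p4[2])
  )
}

#' Render a score card as an SVG pictogram
#'
#' Draws the greenness pictogram: ten ring sectors (clockwise from the top,
#' in rubric order — four feed-preparation criteria, four printing criteria,
#' two post-curing criteria, the three sections separated by heavier
#' spokes) around a centre disc carrying the two-decimal total score filled
#' with the overall band colour. Output is a deterministic SVG 1.1 document:
#' identical card and style give byte-identical markup (no timestamps, no
#' generated ids).
#'
#' @param card An `igapp_scorecard`.
#' @param style An [igapp_style()].
#' @return The SVG document as a single character string.
#' @examples
#' svg <- igapp_pictogram(igapp_score(igapp_fixtures()$BJ))
#' grepl("7.25", svg, fixed = TRUE)
#' @export
igapp_pictogram <- function(card, style = igapp_style()) {
  stopifnot(inherits(card, "igapp_scorecard"))
  a <- card$assignments
  if (nrow(a) != 10) stop("score card must carry ten criteria", call. = FALSE)
  s <- style$size
  cx <- s / 2
  cy <- s / 2
  r_outer <- 0.405 * s
  r_inner <- 0.20 * s
  r_centre <- 0.165 * s
  r_label <- (r_outer + r_inner) / 2
  pal <- style$palette
  step <- 360 / 10

  short <- c(
    solvent_ei = "Solvent EI", feed_temp = "Feed T",
    solvent_removal = "Removal", n_actives = "Actives",
    energy = "Energy", print_temp = "Print T",
    print_time = "Time", waste = "Waste",
    cure_process = "Cure", cure_time = "Cure t"
  )

  sectors <- character(0)
  labels <- character(0)
  for (i in seq_len(10)) {
    a0 <- (i - 1) * step
    a1 <- i * step
    sectors <- c(sectors, sprintf(
      '  <path d="%s" fill="%s" stroke="#FFFFFF" stroke-width="1.5"/>',
      sector_path(cx, cy, r_inner, r_outer, a0, a1),
      unname(pal[a$band[i]])
    ))
    mid <- (a0 + a1) / 2
    rad <- (mid - 90) * pi / 180
    lx <- cx + r_label * cos(rad)
    ly <- cy + r_label * sin(rad)
    labels <- c(labels, sprintf(
      paste0(
        '  <text x="%s" y="%s" text-anchor="middle" dominant-baseline="middle" ',
        'font-size="%s" fill="#FFFFFF">%s</text>'
      ),
      svg_num(lx), svg_num(ly), svg_num(0.026 * s), short[[a$criterion[i]]]
    ))
  }

  # heavier spokes delimit the three sections (after criteria 4, 8 and 10)
  spokes <- purrr::map_chr(c(0, 4, 8) * step, function(ang) {
    rad <- (ang - 90) * pi / 180
    sprintf(
      '  <line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#FFFFFF" stroke-width="4"/>',
      svg_num(cx + r_inner * cos(rad)), svg_num(cy + r_inner * sin(rad)),
      svg_num(cx + r_outer * cos(rad)), svg_num(cy + r_outer * sin(rad))
    )
  })

  centre <- c(
    sprintf(
      '  <circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#FFFFFF" stroke-width="2"/>',
      svg_num(cx), svg_num(cy), svg_num(r_centre), unname(pal[card$overall])
    ),
    sprintf(
      paste0(
        '  <text x="%s" y="%s" text-anchor="middle" dominant-baseline="middle" ',
        'font-size="%s" font-weight="bold" fill="#FFFFFF">%s</text>'
      ),
      svg_num(cx), svg_num(cy), svg_num(0.11 * s), format_total(card$total)
    )
  )

  paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      paste0(
        '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
        'width="%d" height="%d" viewBox="0 0 %d %d" font-family="%s">'
      ),
      as.integer(s), as.integer(s), as.integer(s), as.integer(s),
      style$font_family
    ),
    sprintf('  <title>%s</title>', card$name),
    sectors, spokes, labels, centre,
    "</svg>"
  ), collapse = "\n")
}

#' Write a pictogram to an SVG file
#'
#' @inheritParams igapp_pictogram
#' @param path Output `.svg` path.
#' @return `path`, invisibly.
#' @export
write_pictogram <- function(card, path, style = igapp_style()) {
  writeLines(igapp_pictogram(card, style), path, useBytes = TRUE)
  invisible(path)
}

#' Plot a score card as a polar band chart
#'
#' A ggplot2 rendering of the pictogram: one ring segment per criterion
#' coloured by band, with the total score in the centre.
#'
#' @param object An `igapp_scorecard`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(igapp_score(igapp_fixtures()$SLA))
#' @export
autoplot.igapp_scorecard <- function(object, ...) {
  style <- igapp_style()
  a <- dplyr::mutate(
    object$assignments,
    ord = dplyr::row_number(),
    band = factor(.data$band, levels = band_levels())
  )
  ggplot2::ggplot(a) +
    ggplot2::geom_col(
      ggplot2::aes(x = factor(.data$ord), y = 1, fill = .data$band),
      width = 0.97, colour = "white"
    ) +
    ggplot2::scale_fill_manual(values = style$palette, drop = FALSE) +
    ggplot2::scale_x_discrete(labels = a$label) +
    ggplot2::coord_polar() +
    ggplot2::annotate(
      "text", x = 0.5, y = -1, label = format_total(object$total),
      size = 8, fontface = "bold",
      colour = unname(style$palette[object$overall])
    ) +
    ggplot2::ylim(-1, 1.05) +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = object$name,
      subtitle = sprintf(
        "total %s / 10 (%s)", format_total(object$total), object$overall
      ),
      fill = "band"
    )
}

#' @export
plot.igapp_scorecard <- function(x, ...) print(autoplot.igapp_scorecard(x, ...))
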