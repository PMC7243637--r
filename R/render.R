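# Deterministic SVG rendering of a nomogram geometry. Output is plain
# SVG 1.1 text assembled with fixed number formatting (3 decimals, mm
# units) and no timestamps, so identical inputs give byte-identical files.

fmt_mm <- function(x) sprintf("%.3f", x)

# compact numeric label: integers without decimals, otherwise trimmed
fmt_label <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, sprintf("%d", as.integer(round(x))),
         sub("0+$", "", sprintf("%.2f", x)))
}

#' Generate tick positions for a logarithmic axis
#'
#' Majors follow the 1-2-5 pattern per decade, minors sit at the integer
#' mantissas (1..9 per decade), both clipped to the axis range, sorted and
#' deduplicated (a value that qualifies as major is dropped from the
#' minors). The axis range endpoints are always included as majors.
#'
#' @param axis an [axis_scale()].
#' @param geom optional [build_geometry()]; unused here but accepted so
#'   callers can treat all tick generators uniformly.
#' @return data frame with columns `value`, `type` (`"major"`/`"minor"`),
#'   `label` (empty for minors).
#' @export
generate_ticks <- function(axis, geom = NULL) {
  stopifnot(inherits(axis, "axis_scale"))
  lo <- axis$range[1]; hi <- axis$range[2]
  decades <- seq(floor(log10(lo)), ceiling(log10(hi)))
  mant_major <- c(1, 2, 5)
  mant_minor <- 1:9
  cand_major <- sort(unique(as.vector(outer(mant_major, 10^decades))))
  cand_minor <- sort(unique(as.vector(outer(mant_minor, 10^decades))))
  eps <- 1e-9
  majors <- cand_major[cand_major >= lo * (1 - eps) & cand_major <= hi * (1 + eps)]
  majors <- sort(unique(c(majors, lo, hi)))
  minors <- cand_minor[cand_minor >= lo * (1 - eps) & cand_minor <= hi * (1 + eps)]
  minors <- minors[!minors %in% majors]
  rbind(
    data.frame(value = majors, type = "major", label = fmt_label(majors)),
    data.frame(value = minors, type = "minor", label = ""))
}

#' Weight ticks for the dual-labelled left axis
#'
#' Weight labels in kg placed at the chart height of `weight * bv_per_kg`
#' ml, so the weight tick `w` and the BV tick `75 w` coincide exactly.
#' Integer-kg majors for narrow (pediatric) ranges; 10-kg steps plus the
#' endpoints for wide (adult) ranges.
#'
#' @param geom a [build_geometry()] result.
#' @return data frame with columns `weight_kg`, `bv_ml`, `label`.
#' @export
weight_ticks <- function(geom) {
  stopifnot(inherits(geom, "nomogram_geometry"))
  wr <- geom$weight_range
  w <- if (diff(wr) <= 30) {
    seq(ceiling(wr[1]), floor(wr[2]))
  } else {
    sort(unique(c(wr, seq(ceiling(wr[1] / 10) * 10, floor(wr[2] / 10) * 10,
                          by = 10))))
  }
  data.frame(weight_kg = w, bv_ml = w * geom$bv_per_kg, label = fmt_label(w))
}

svg_text <- function(x, y, s, anchor = "start", size = 2.8, extra = "") {
  sprintf('<text x="%s" y="%s" font-size="%s" font-family="Helvetica" text-anchor="%s"%s>%s</text>',
          fmt_mm(x), fmt_mm(y), fmt_mm(size), anchor,
          if (nzchar(extra)) paste0(" ", extra) else "", s)
}

svg_line <- function(x1, y1, x2, y2, width = 0.2) {
  sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="%s"/>',
          fmt_mm(x1), fmt_mm(y1), fmt_mm(x2), fmt_mm(y2), fmt_mm(width))
}

# instruction summaries printed on the chart margin when requested
chart_instructions <- c(
  "After blood loss (equilibrated): subtract the loss on the BV scale, line to the initial Hct, mark RBC, pivot back to the original BV and read the new Hct.",
  "After fluid only: line from weight to the initial Hct, mark RBC, pivot to BV plus fluid given and read the new Hct.",
  "Loss plus fluids: subtract the blood loss, mark RBC at the initial Hct, add net fluid to the BV, pivot on RBC and read the final Hct.",
  "Dehydration: line from current weight to current Hct, mark RBC, pivot to the pre-loss Hct; the recovered weight difference in kg equals the water deficit in liters.")

#' Render a nomogram to SVG
#'
#' Writes a standalone SVG 1.1 document: three vertical log axes with
#' major/minor ticks and labels, dual weight/BV labels on the left axis,
#' axis titles, a chart title, and optionally pound labels and usage
#' instructions. Byte output is deterministic for fixed inputs.
#'
#' @param geom a [build_geometry()] result.
#' @param path output file path, or `NULL` to return the SVG string only.
#' @param title chart title; a default is derived from the population.
#' @param show_pounds also label major weight ticks in pounds.
#' @param show_instructions print the four usage step summaries in the
#'   bottom margin.
#' @param config a [model_config()]; supplies the lb/kg constant.
#' @return the SVG document as a single string (invisibly when written to
#'   `path`).
#' @export
render_svg <- function(geom, path = NULL, title = NULL,
                       show_pounds = FALSE, show_instructions = FALSE,
                       config = model_config()) {
  stopifnot(inherits(geom, "nomogram_geometry"))
  pw <- geom$page[1]; ph <- geom$page[2]; mar <- geom$margin
  if (is.null(title))
    title <- sprintf("Blood volume / RBC volume / hematocrit alignment chart (%s)",
                     geom$population)
  # chart mm (y up, origin bottom-left of drawing area) -> svg user units
  X <- function(x) mar + x
  Y <- function(y) ph - mar - y

  axis_titles <- c(bv_weight = "BV (ml) / weight (kg)",
                   rbc = "RBC volume (ml)", hct = "Hct (%)")
  body <- character(0)
  for (a in geom$axes) {
    g <- sprintf('<g id="axis-%s" class="axis">', a$name)
    ylo <- axis_value_to_y(a, a$range[1])
    yhi <- axis_value_to_y(a, a$range[2])
    g <- c(g, svg_line(X(a$x), Y(ylo), X(a$x), Y(yhi), width = 0.4))
    ticks <- generate_ticks(a)
    side <- if (a$name == "hct") -1 else 1   # hct ticks point left
    for (j in seq_len(nrow(ticks))) {
      v <- ticks$value[j]
      y <- axis_value_to_y(a, v)
      len <- if (ticks$type[j] == "major") 3 else 1.5
      g <- c(g, svg_line(X(a$x), Y(y), X(a$x + side * len), Y(y)))
      if (ticks$type[j] == "major") {
        tx <- a$x + side * (len + 1)
        g <- c(g, svg_text(X(tx), Y(y) + 1,
                           ticks$label[j],
                           anchor = if (side > 0) "start" else "end"))
      }
    }
    if (a$name == "bv_weight") {
      wt <- weight_ticks(geom)
      for (j in seq_len(nrow(wt))) {
        y <- axis_value_to_y(a, wt$bv_ml[j])
        g <- c(g, svg_line(X(a$x - 3), Y(y), X(a$x), Y(y)))
        g <- c(g, svg_text(X(a$x - 4), Y(y) + 1,
                           paste0(wt$label[j], " kg"), anchor = "end"))
        if (show_pounds)
          g <- c(g, svg_text(X(a$x - 12), Y(y) + 1,
                             paste0(sub("\\.0$", "",
                                        sprintf("%.1f", wt$weight_kg[j] * config$lb_per_kg)),
                                    " lb"),
                             anchor = "end", size = 2.2))
      }
    }
    g <- c(g, svg_text(X(a$x), Y(yhi) - 5, axis_titles[[a$name]],
                       anchor = "middle", size = 3.4,
                       extra = 'font-weight="bold"'))
    body <- c(body, g, "</g>")
  }
  body <- c(body, svg_text(pw / 2, mar / 2, title, anchor = "middle",
                           size = 4.2, extra = 'font-weight="bold"'))
  if (show_instructions) {
    for (k in seq_along(chart_instructions))
      body <- c(body, svg_text(mar / 2, ph - mar + 4 + 4 * k,
                               chart_instructions[k], size = 2.2))
  }
  doc <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%smm" height="%smm" viewBox="0 0 %s %s">',
            fmt_mm(pw), fmt_mm(ph), fmt_mm(pw), fmt_mm(ph)),
    body,
    "</svg>")
  svg <- paste(doc, collapse = "\n")
  if (!is.null(path)) {
    con <- tryCatch(suppressWarnings(file(path, open = "wb")),
                    error = function(e)
                      abort_validation("cannot write SVG to `%s`: %s", path,
                                       conditionMessage(e)))
    on.exit(close(con))
    writeBin(charToRaw(svg), con)
    return(invisible(svg))
  }
  svg
}
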