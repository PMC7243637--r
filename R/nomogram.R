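# Parallel-scale alignment chart for RBC = BV * Hct / 100.
#
# All three axes are logarithmic: the governing relation is multiplicative,
#   log(RBC) = log(BV) + log(Hct) - 2        (Hct in percent)
# and the classical parallel-scale construction makes straight-edge
# alignment exact for a sum of logs. With the outer axes at x = 0 and
# x = D carrying y = m1*log10(BV) + b1 and y = m2*log10(Hct) + b2, the
# middle axis sits at x = D*m1/(m1+m2) with modulus m3 = m1*m2/(m1+m2)
# and intercept b3 = (m2*b1 + m1*b2)/(m1+m2) + 2*m3. Chart coordinates
# are mm, y increasing upward, origin at the bottom-left of the drawing
# area.

#' Axis scale
#'
#' One vertical logarithmic scale of the chart: `y = modulus * log10(value)
#' + intercept` (mm). The modulus is mm per decade; larger values always
#' map to higher y.
#'
#' @param name one of `"bv_weight"`, `"rbc"`, `"hct"`.
#' @param x horizontal position of the axis line, mm.
#' @param modulus scale modulus, mm per decade, > 0.
#' @param intercept intercept of the scale map, mm.
#' @param range numeric length-2, `c(min, max)` in axis units, 0 < min < max.
#' @param unit display unit string.
#' @return object of class `axis_scale`.
#' @export
axis_scale <- function(name, x, modulus, intercept, range, unit = "") {
  name <- match.arg(name, c("bv_weight", "rbc", "hct"))
  check_scalar(x, "x"); check_scalar(modulus, "modulus")
  check_scalar(intercept, "intercept")
  if (length(range) != 2L || !is.numeric(range) || any(!is.finite(range)))
    abort_validation("axis `%s`: range must be two finite numbers", name)
  if (range[1] <= 0 || range[1] >= range[2])
    abort_validation("axis `%s`: need 0 < min < max, got [%g, %g]",
                     name, range[1], range[2])
  if (modulus <= 0)
    abort_validation("axis `%s`: modulus must be > 0 mm/decade", name)
  structure(list(name = name, x = x, modulus = modulus,
                 intercept = intercept, range = range, unit = unit),
            class = "axis_scale")
}

#' Map an axis value to its vertical chart coordinate
#' @param axis an [axis_scale()].
#' @param value value in axis units (vectorized).
#' @param check when `TRUE`, values outside the axis range are an error.
#' @return y coordinate(s) in mm.
#' @export
axis_value_to_y <- function(axis, value, check = TRUE) {
  stopifnot(inherits(axis, "axis_scale"))
  if (check) {
    bad <- value < axis$range[1] * (1 - 1e-9) | value > axis$range[2] * (1 + 1e-9)
    if (any(bad))
      abort_validation("value %g out of range [%g, %g] on the %s axis",
                       value[bad][1], axis$range[1], axis$range[2], axis$name)
  }
  axis$modulus * log10(value) + axis$intercept
}

#' Invert an axis scale: chart coordinate back to value
#' @inheritParams axis_value_to_y
#' @param y vertical coordinate(s), mm.
#' @return value(s) in axis units.
#' @export
axis_y_to_value <- function(axis, y) {
  stopifnot(inherits(axis, "axis_scale"))
  10^((y - axis$intercept) / axis$modulus)
}

#' Build a three-axis alignment-chart geometry
#'
#' Constructs the pediatric or adult chart: left axis blood volume (dual
#' labelled with weight via `bv_per_kg`), middle axis red-cell volume,
#' right axis hematocrit. The red-cell range is derived as
#' `[BVmin*Hctmin, BVmax*Hctmax] / 100` so that every in-range alignment
#' stays on-chart. By default the outer moduli are equal (middle axis
#' centered); `modulus_ratio` = m1/m2 supports asymmetric layouts.
#'
#' @param population `"pediatric"` (weight 1-20 kg) or `"adult"`
#'   (30-150 kg); sets the default weight range.
#' @param weight_range optional length-2 override, kg.
#' @param hct_range hematocrit range, percent, within (0, 100].
#' @param bv_per_kg blood-volume rule linking the dual weight/BV labels,
#'   ml/kg.
#' @param page page size `c(width, height)` in mm (default A4 portrait).
#' @param margin margin around the drawing area, mm.
#' @param modulus_ratio ratio m1/m2 of the outer moduli (default 1).
#' @return object of class `nomogram_geometry` with the three
#'   [axis_scale()] objects in `$axes`, plus `population`, `page`,
#'   `margin`, and `bv_per_kg`.
#' @examples
#' g <- build_geometry("pediatric")
#' isopleth_read(g, anchor("bv_weight", 900), anchor("hct", 35), "rbc")
#' @export
build_geometry <- function(population = c("pediatric", "adult"),
                           weight_range = NULL,
                           hct_range = c(10, 70),
                           bv_per_kg = 75,
                           page = c(210, 297),
                           margin = 25,
                           modulus_ratio = 1) {
  population <- match.arg(population)
  if (is.null(weight_range))
    weight_range <- switch(population, pediatric = c(1, 20),
                           adult = c(30, 150))
  if (length(weight_range) != 2L || weight_range[1] <= 0 ||
      weight_range[1] >= weight_range[2])
    abort_validation("weight_range must satisfy 0 < min < max, got [%g, %g]",
                     weight_range[1], weight_range[2])
  if (length(hct_range) != 2L || hct_range[1] <= 0 ||
      hct_range[1] >= hct_range[2] || hct_range[2] > 100)
    abort_validation("hct_range must satisfy 0 < min < max <= 100, got [%g, %g]",
                     hct_range[1], hct_range[2])
  check_scalar(bv_per_kg, "bv_per_kg")
  if (bv_per_kg <= 0)
    abort_validation("`bv_per_kg` must be > 0 ml/kg (got %g)", bv_per_kg)
  check_scalar(modulus_ratio, "modulus_ratio")
  if (modulus_ratio <= 0)
    abort_validation("`modulus_ratio` must be > 0 (got %g)", modulus_ratio)
  if (length(page) != 2L || any(page <= 2 * margin))
    abort_validation("page %s mm leaves no drawing area inside %g mm margins",
                     paste(page, collapse = "x"), margin)

  D <- page[1] - 2 * margin   # axis-to-axis horizontal span
  H <- page[2] - 2 * margin   # usable axis height

  bv_range <- weight_range * bv_per_kg
  span_bv <- log10(bv_range[2] / bv_range[1])
  span_hct <- log10(hct_range[2] / hct_range[1])

  # largest moduli with ratio r that keep both outer scales within H
  r <- modulus_ratio
  m2 <- min(H / (r * span_bv), H / span_hct)
  m1 <- r * m2

  # center each outer scale vertically: log-midpoint maps to H/2
  b1 <- H / 2 - m1 * mean(log10(bv_range))
  b2 <- H / 2 - m2 * mean(log10(hct_range))

  m3 <- m1 * m2 / (m1 + m2)
  b3 <- (m2 * b1 + m1 * b2) / (m1 + m2) + 2 * m3
  x3 <- D * m1 / (m1 + m2)
  rbc_range <- c(bv_range[1] * hct_range[1], bv_range[2] * hct_range[2]) / 100

  axes <- list(
    bv_weight = axis_scale("bv_weight", 0, m1, b1, bv_range, "ml"),
    rbc       = axis_scale("rbc", x3, m3, b3, rbc_range, "ml"),
    hct       = axis_scale("hct", D, m2, b2, hct_range, "%"))

  structure(list(population = population, axes = axes,
                 weight_range = weight_range, page = page, margin = margin,
                 bv_per_kg = bv_per_kg),
            class = "nomogram_geometry")
}

#' @export
print.nomogram_geometry <- function(x, ...) {
  cat(sprintf("<nomogram_geometry> %s chart, %g ml/kg\n",
              x$population, x$bv_per_kg))
  for (a in x$axes)
    cat(sprintf("  %-9s x=%6.2f mm  modulus=%6.2f mm/decade  range [%g, %g] %s\n",
                a$name, a$x, a$modulus, a$range[1], a$range[2], a$unit))
  invisible(x)
}

#' Anchor point for a straight-edge reading
#' @param axis axis name: `"bv_weight"`, `"rbc"`, or `"hct"`.
#' @param value value on that axis, in its units.
#' @return list usable as an anchor in [isopleth_read()].
#' @export
anchor <- function(axis, value) {
  axis <- match.arg(axis, c("bv_weight", "rbc", "hct"))
  check_scalar(value, "value")
  list(axis = axis, value = value)
}

#' Read the third axis with a virtual straight-edge
#'
#' Lays an exact straight line (isopleth) through the chart coordinates of
#' the two anchor values and intersects it with the target axis; the
#' intersection height is inverted through the target scale to a value.
#' Pure analytic geometry, no rasterization.
#'
#' @param geom a [build_geometry()] result.
#' @param anchor_a,anchor_b anchors from [anchor()] on two distinct axes.
#' @param target name of the third axis to read.
#' @return object of class `isopleth_reading` with `read_value`,
#'   `residual` (perpendicular distance, mm, between the snapped target
#'   point and the line; 0 up to floating point by construction), and the
#'   anchors.
#' @export
isopleth_read <- function(geom, anchor_a, anchor_b, target) {
  stopifnot(inherits(geom, "nomogram_geometry"))
  target <- match.arg(target, c("bv_weight", "rbc", "hct"))
  if (anchor_a$axis == anchor_b$axis)
    abort_validation("anchors must lie on two distinct axes (both on %s)",
                     anchor_a$axis)
  if (target %in% c(anchor_a$axis, anchor_b$axis))
    abort_validation("target axis %s must differ from both anchor axes", target)

  ax_a <- geom$axes[[anchor_a$axis]]
  ax_b <- geom$axes[[anchor_b$axis]]
  ax_t <- geom$axes[[target]]
  y_a <- axis_value_to_y(ax_a, anchor_a$value)
  y_b <- axis_value_to_y(ax_b, anchor_b$value)

  # line through (x_a, y_a), (x_b, y_b) evaluated at the target abscissa
  t <- (ax_t$x - ax_a$x) / (ax_b$x - ax_a$x)
  y_t <- y_a + t * (y_b - y_a)
  value <- axis_y_to_value(ax_t, y_t)
  if (value < ax_t$range[1] * (1 - 1e-9) || value > ax_t$range[2] * (1 + 1e-9))
    abort_validation("straight-edge reading %g %s falls outside the %s axis range [%g, %g]",
                     value, ax_t$unit, ax_t$name, ax_t$range[1], ax_t$range[2])

  # perpendicular distance from the snapped target point to the isopleth
  y_snap <- axis_value_to_y(ax_t, value, check = FALSE)
  dx <- ax_b$x - ax_a$x; dy <- y_b - y_a
  residual <- abs(dy * (ax_t$x - ax_a$x) - dx * (y_snap - y_a)) /
    sqrt(dx^2 + dy^2)

  structure(list(anchor_a = anchor_a, anchor_b = anchor_b,
                 target_axis = target, read_value = value,
                 residual = residual),
            class = "isopleth_reading")
}

#' @export
print.isopleth_reading <- function(x, ...) {
  cat(sprintf("<isopleth_reading> %s=%g & %s=%g -> %s = %g (residual %.2g mm)\n",
              x$anchor_a$axis, x$anchor_a$value,
              x$anchor_b$axis, x$anchor_b$value,
              x$target_axis, x$read_value, x$residual))
  invisible(x)
}

#' Collinearity residual of the chart construction
#'
#' Diagnostic: for a given (BV, Hct) pair, the vertical distance in mm,
#' measured on the middle axis line, between (a) the chart point of
#' `RBC = BV * Hct / 100` and (b) the intersection of the (BV, Hct)
#' isopleth with that axis. Exactly 0 (up to floating point) for a
#' correctly constructed geometry; nonzero if any modulus, position, or
#' intercept is corrupted.
#'
#' @param geom a [build_geometry()] result.
#' @param bv blood volume, ml, within the left axis range.
#' @param hct hematocrit, percent, within the right axis range.
#' @return distance in mm.
#' @export
collinearity_residual <- function(geom, bv, hct) {
  stopifnot(inherits(geom, "nomogram_geometry"))
  ax1 <- geom$axes$bv_weight; ax3 <- geom$axes$rbc; ax2 <- geom$axes$hct
  y1 <- axis_value_to_y(ax1, bv)
  y2 <- axis_value_to_y(ax2, hct)
  t <- (ax3$x - ax1$x) / (ax2$x - ax1$x)
  y_line <- y1 + t * (y2 - y1)
  y_true <- axis_value_to_y(ax3, bv * hct / 100)
  abs(y_line - y_true)
}

#' Replay a graphical chart procedure with the virtual straight-edge
#'
#' Executes one of the four published step lists purely through
#' [isopleth_read()] calls; value arithmetic (subtracting a loss from the
#' BV scale, adding infused fluid) is done on the value before mapping to
#' the scale, exactly as a clinician uses the printed chart.
#'
#' Procedures (scenario is a list, e.g. one entry of [figure_fixtures()]):
#' \describe{
#'   \item{blood_loss_equilibrated}{fields `weight_kg`, `initial_hct_pct`,
#'     `loss_ml`. Subtract the loss from the BV, read RBC against the
#'     initial Hct, pivot back to the original BV, read the final Hct.
#'     Returns percent.}
#'   \item{infusion}{fields `weight_kg`, `initial_hct_pct`, `infusion_ml`.
#'     Read RBC from weight and initial Hct, pivot to BV + infusion, read
#'     the final Hct. Returns percent.}
#'   \item{combined}{fields `weight_kg`, `initial_hct_pct`, `loss_ml`,
#'     `infusion_ml`. Blood-loss step, then net fluid added to the BV,
#'     pivot on the RBC mark, read the final Hct. Returns percent.}
#'   \item{dehydration}{fields `weight_kg`, `current_hct_pct`,
#'     `baseline_hct_pct`. Read RBC from current weight and Hct, pivot to
#'     the baseline Hct, read the recovered BV, convert to weight; the
#'     weight difference is the water deficit. Returns liters.}
#' }
#'
#' @param geom a [build_geometry()] result.
#' @param scenario scenario list as described above.
#' @return the value read on the final step: final hematocrit (percent),
#'   or water deficit (liters) for the dehydration procedure.
#' @export
run_graphical_procedure <- function(geom, scenario) {
  stopifnot(inherits(geom, "nomogram_geometry"))
  proc <- scenario$procedure
  if (is.null(proc))
    abort_validation("scenario has no `procedure` field")
  step <- function(label, expr) {
    tryCatch(expr, hctnomo_validation_error = function(e)
      abort_validation("procedure `%s`, %s: %s", proc, label,
                       conditionMessage(e)))
  }
  bv_of <- function(w) w * geom$bv_per_kg

  switch(proc,
    blood_loss_equilibrated = {
      bv0 <- bv_of(scenario$weight_kg)
      bv_corr <- bv0 - scenario$loss_ml           # step 1: subtract on BV scale
      rbc <- step("step 2 (read RBC)", isopleth_read(
        geom, anchor("bv_weight", bv_corr),
        anchor("hct", scenario$initial_hct_pct), "rbc"))$read_value
      step("step 3 (pivot to original BV)", isopleth_read(
        geom, anchor("rbc", rbc),
        anchor("bv_weight", bv0), "hct"))$read_value
    },
    infusion = {
      bv0 <- bv_of(scenario$weight_kg)
      rbc <- step("step 1 (read RBC)", isopleth_read(
        geom, anchor("bv_weight", bv0),
        anchor("hct", scenario$initial_hct_pct), "rbc"))$read_value
      step("step 2 (pivot to BV + infusion)", isopleth_read(
        geom, anchor("rbc", rbc),
        anchor("bv_weight", bv0 + scenario$infusion_ml), "hct"))$read_value
    },
    combined = {
      bv0 <- bv_of(scenario$weight_kg)
      bv_corr <- bv0 - scenario$loss_ml
      rbc <- step("step 2 (read RBC after loss)", isopleth_read(
        geom, anchor("bv_weight", bv_corr),
        anchor("hct", scenario$initial_hct_pct), "rbc"))$read_value
      bv_new <- bv_corr + scenario$infusion_ml    # step 3: net fluid onto BV
      step("step 4 (pivot to new BV)", isopleth_read(
        geom, anchor("rbc", rbc),
        anchor("bv_weight", bv_new), "hct"))$read_value
    },
    dehydration = {
      bv_now <- bv_of(scenario$weight_kg)
      rbc <- step("step 1 (read RBC)", isopleth_read(
        geom, anchor("bv_weight", bv_now),
        anchor("hct", scenario$current_hct_pct), "rbc"))$read_value
      bv_pre <- step("step 2 (pivot to baseline Hct)", isopleth_read(
        geom, anchor("rbc", rbc),
        anchor("hct", scenario$baseline_hct_pct), "bv_weight"))$read_value
      (bv_pre / geom$bv_per_kg) - scenario$weight_kg   # kg difference == liters
    },
    abort_validation("unknown procedure `%s`", proc))
}

#' Export a geometry description as JSON
#'
#' Writes the axis placements, moduli, intercepts, ranges, and tick values
#' so third parties can re-render the chart.
#'
#' @param geom a [build_geometry()] result.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
geometry_json <- function(geom, path = NULL) {
  stopifnot(inherits(geom, "nomogram_geometry"))
  axes <- lapply(geom$axes, function(a) {
    ticks <- generate_ticks(a, geom)
    list(name = a$name, x_mm = a$x, modulus_mm_per_decade = a$modulus,
         intercept_mm = a$intercept, range = a$range, unit = a$unit,
         major_ticks = ticks$value[ticks$type == "major"],
         minor_ticks = ticks$value[ticks$type == "minor"])
  })
  out <- list(population = geom$population, bv_per_kg = geom$bv_per_kg,
              page_mm = geom$page, margin_mm = geom$margin,
              weight_range_kg = geom$weight_range, axes = axes)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
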