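# Traffic-light pictogram: a central overall-score circle surrounded by 12
# criterion satellites. Color encodes score (red-yellow-green over 0-1);
# satellite size and proximity to the center encode weight. The outline
# echoes a MIP sorbent: small functional-monomer circles around the large
# template circle.

#' Pictogram theme: colors and geometry
#'
#' Bundles the traffic-light gradient stops and the layout constants.
#' Colors are conventional traffic-light RGB values; geometry constants are
#' presentation only — the layout contract (bigger weight means a bigger
#' satellite drawn closer to the center) holds for any theme whose
#' `radius_per_weight` is positive and `distance_per_weight` negative.
#'
#' @param red,yellow,green RGB triples (0-255) for the gradient stops at
#'   scores 0, 0.5, and 1.
#' @param canvas Canvas side length in abstract units.
#' @param center_radius Radius of the central overall-score circle.
#' @param satellite_radius Radius of a weight-1 satellite.
#' @param radius_per_weight Radius increase per weight step above 1.
#' @param ring_distance Center distance of a weight-1 satellite.
#' @param distance_per_weight Distance change per weight step (negative:
#'   heavier criteria sit closer to the center).
#' @return A `pictogram_theme` list.
#' @export
pictogram_theme <- function(red = c(204, 0, 0), yellow = c(255, 204, 0),
                            green = c(0, 153, 0),
                            canvas = 220, center_radius = 36,
                            satellite_radius = 9, radius_per_weight = 2,
                            ring_distance = 78, distance_per_weight = -4) {
  stops <- list(list(value = 0, color = red),
                list(value = 0.5, color = yellow),
                list(value = 1, color = green))
  structure(list(stops = stops, canvas = canvas, center_radius = center_radius,
                 satellite_radius = satellite_radius,
                 radius_per_weight = radius_per_weight,
                 ring_distance = ring_distance,
                 distance_per_weight = distance_per_weight),
            class = "pictogram_theme")
}

#' Map a score to a traffic-light color
#'
#' Piecewise-linear interpolation through the theme's gradient stops:
#' red at 0, yellow at 0.5, green at 1. Continuous and endpoint-exact.
#'
#' @param score Score in \[0, 1\].
#' @param theme A [pictogram_theme()].
#' @return Integer RGB triple (0-255 per channel).
#' @examples
#' score_to_color(0)    # the red stop
#' score_to_color(0.5)  # exactly the yellow stop
#' @export
score_to_color <- function(score, theme = pictogram_theme()) {
  if (!is.numeric(score) || length(score) != 1 || is.na(score) ||
      score < 0 || score > 1) {
    mip_error("score must be a single value in [0, 1]", "mipgreen_validation_error")
  }
  values <- vapply(theme$stops, `[[`, numeric(1), "value")
  channels <- vapply(1:3, function(ch) {
    ys <- vapply(theme$stops, function(s) s$color[[ch]], numeric(1))
    stats::approx(values, ys, xout = score, rule = 2)$y
  }, numeric(1))
  as.integer(round(channels))
}

#' @keywords internal
rgb_hex <- function(rgb) {
  sprintf("#%02X%02X%02X", rgb[1], rgb[2], rgb[3])
}

#' Resolve pictogram geometry for an assessment result
#'
#' Places the 12 criterion satellites at equal 30-degree spacing, criterion 1
#' at twelve o'clock and ids increasing clockwise. Satellite radius grows
#' affinely with weight while center distance shrinks, so a heavily weighted
#' criterion is drawn larger and closer to the central circle. Pure function
#' of the scores and weights — no randomness.
#'
#' @param result An `assessment_result` from [overall_score()] or [assess()].
#' @param theme A [pictogram_theme()].
#' @return A `pictogram_spec`: canvas size, central circle record, and a
#'   12-row satellite data frame (id, angle, distance, radius, color, label).
#' @export
pictogram_layout <- function(result, theme = pictogram_theme()) {
  stopifnot(inherits(result, "assessment_result"))
  w <- as.numeric(result$weights$weights)
  angle_deg <- (0:11) * 30                      # clockwise from twelve o'clock
  radius <- theme$satellite_radius + (w - 1) * theme$radius_per_weight
  distance <- theme$ring_distance + (w - 1) * theme$distance_per_weight
  cx <- theme$canvas / 2
  theta <- angle_deg * pi / 180
  satellites <- data.frame(
    criterion_id = 1:12,
    angle_deg = angle_deg,
    distance = distance,
    radius = radius,
    x = cx + distance * sin(theta),
    y = cx - distance * cos(theta),
    fill = vapply(result$scores, function(s) rgb_hex(score_to_color(s, theme)),
                  character(1)),
    label = as.character(1:12),
    score = as.numeric(result$scores),
    weight = w,
    stringsAsFactors = FALSE)
  structure(list(
    canvas = c(width = theme$canvas, height = theme$canvas),
    center = list(x = cx, y = cx, radius = theme$center_radius,
                  fill = rgb_hex(score_to_color(result$display_overall, theme)),
                  label = sprintf("%.2f", result$display_overall)),
    satellites = satellites),
    class = "pictogram_spec")
}

#' @keywords internal
svg_document <- function(spec) {
  num <- function(x) sprintf("%.2f", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            num(spec$canvas[["width"]]), num(spec$canvas[["height"]]),
            num(spec$canvas[["width"]]), num(spec$canvas[["height"]])),
    sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#333333" stroke-width="1.5"/>',
            num(spec$center$x), num(spec$center$y), num(spec$center$radius),
            spec$center$fill))
  for (i in seq_len(nrow(spec$satellites))) {
    s <- spec$satellites[i, ]
    lines <- c(lines,
      sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#333333" stroke-width="1"/>',
              num(s$x), num(s$y), num(s$radius), s$fill))
  }
  for (i in seq_len(nrow(spec$satellites))) {
    s <- spec$satellites[i, ]
    lines <- c(lines,
      sprintf('<text x="%s" y="%s" font-family="sans-serif" font-size="%s" text-anchor="middle" dominant-baseline="central" fill="#000000">%s</text>',
              num(s$x), num(s$y), num(s$radius), s$label))
  }
  lines <- c(lines,
    sprintf('<text x="%s" y="%s" font-family="sans-serif" font-size="%s" font-weight="bold" text-anchor="middle" dominant-baseline="central" fill="#000000">%s</text>',
            num(spec$center$x), num(spec$center$y),
            num(spec$center$radius * 0.5), spec$center$label),
    '</svg>')
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Render a pictogram to SVG or PNG
#'
#' The file extension selects the format. SVG output is deterministic,
#' byte-stable text: rendering the same result twice produces identical
#' files, and the document contains exactly 13 circle elements (the central
#' circle plus one satellite per criterion). PNG output rasterizes the same
#' geometry through the `grDevices` png device.
#'
#' @param x An `assessment_result` or a `pictogram_spec`.
#' @param path Output path ending in `.svg` or `.png`.
#' @param theme A [pictogram_theme()], used when `x` is a result.
#' @param scale Pixels per abstract canvas unit for PNG output.
#' @return `path`, invisibly.
#' @export
render_pictogram <- function(x, path, theme = pictogram_theme(), scale = 3) {
  spec <- if (inherits(x, "pictogram_spec")) x else pictogram_layout(x, theme)
  ext <- tolower(tools::file_ext(path))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    mip_error(sprintf("cannot write to '%s'", path), "mipgreen_io_error")
  }
  if (ext == "svg") {
    con <- file(path, open = "wb")            # binary mode: byte-stable EOLs
    on.exit(close(con))
    writeBin(charToRaw(svg_document(spec)), con)
  } else if (ext == "png") {
    px <- spec$canvas[["width"]] * scale
    grDevices::png(path, width = px, height = px, res = 72 * scale)
    on.exit(grDevices::dev.off())
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, spec$canvas[["width"]]),
                          ylim = c(spec$canvas[["height"]], 0), asp = 1)
    graphics::symbols(spec$center$x, spec$center$y,
                      circles = spec$center$radius, inches = FALSE,
                      bg = spec$center$fill, fg = "#333333", add = TRUE)
    graphics::symbols(spec$satellites$x, spec$satellites$y,
                      circles = spec$satellites$radius, inches = FALSE,
                      bg = spec$satellites$fill, fg = "#333333", add = TRUE)
    graphics::text(spec$satellites$x, spec$satellites$y,
                   spec$satellites$label, cex = 0.8)
    graphics::text(spec$center$x, spec$center$y, spec$center$label,
                   cex = 1.4, font = 2)
    graphics::par(op)
  } else {
    mip_error(sprintf("unsupported pictogram format '.%s' (use .svg or .png)", ext),
              "mipgreen_validation_error")
  }
  invisible(path)
}
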