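# Traffic-light colors, layout geometry, SVG/PNG rendering.

theme <- pictogram_theme()

test_that("score_to_color is endpoint-exact and hits the yellow stop", {
  expect_identical(score_to_color(0, theme), as.integer(theme$stops[[1]]$color))
  expect_identical(score_to_color(1, theme), as.integer(theme$stops[[3]]$color))
  expect_identical(score_to_color(0.5, theme), as.integer(theme$stops[[2]]$color))
  expect_error(score_to_color(1.2), class = "mipgreen_validation_error")
})

test_that("score_to_color is continuous and deterministic", {
  s <- seq(0, 1, by = 0.01)
  cols <- t(vapply(s, score_to_color, integer(3), theme = theme))
  # adjacent scores differ by at most a few counts per channel
  expect_lte(max(abs(diff(cols))), ceiling(255 / 50) + 1)
  expect_identical(score_to_color(0.37), score_to_color(0.37))
})

test_that("layout places 12 satellites clockwise from twelve o'clock", {
  res <- overall_score(rep(0.5, 12))
  spec <- pictogram_layout(res, theme)
  sat <- spec$satellites
  expect_equal(nrow(sat), 12)
  expect_setequal(sat$criterion_id, 1:12)
  # criterion 1 straight up from the center
  expect_equal(sat$x[1], spec$center$x)
  expect_lt(sat$y[1], spec$center$y)
  # criterion 4 sits a quarter turn clockwise, i.e. due right
  expect_equal(sat$y[4], spec$center$y)
  expect_gt(sat$x[4], spec$center$x)
  expect_equal(unique(diff(sat$angle_deg)), 30)
})

test_that("weight drives satellite size up and center distance down", {
  w <- c(4, rep(2, 10), 1)
  res <- overall_score(rep(0.5, 12), w)
  sat <- pictogram_layout(res, theme)$satellites
  expect_gt(sat$radius[1], sat$radius[12])      # weight 4 vs weight 1
  expect_lt(sat$distance[1], sat$distance[12])
  # nondecreasing radius / nonincreasing distance in weight overall
  ord <- order(sat$weight)
  expect_true(all(diff(sat$radius[ord]) >= 0))
  expect_true(all(diff(sat$distance[ord]) <= 0))
  # equal weights: full symmetry
  sat_eq <- pictogram_layout(overall_score(rep(0.5, 12), rep(3, 12)), theme)$satellites
  expect_equal(length(unique(sat_eq$radius)), 1)
  expect_equal(length(unique(sat_eq$distance)), 1)
})

test_that("rendered SVG is well-formed, has 13 circles, and is byte-stable", {
  res <- overall_score(round(stats::runif(12, 0, 1), 2))
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_pictogram(res, f1)
  render_pictogram(res, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  doc <- xml2::read_xml(f1)
  circles <- xml2::xml_find_all(doc, "//*[local-name() = 'circle']")
  expect_equal(length(circles), 13)
})

test_that("central fill follows the overall score's color", {
  f <- withr::local_tempfile(fileext = ".svg")
  render_pictogram(overall_score(rep(1, 12)), f)
  doc <- xml2::read_xml(f)
  first_circle <- xml2::xml_find_first(doc, "//*[local-name() = 'circle']")
  green_hex <- sprintf("#%02X%02X%02X", theme$stops[[3]]$color[1],
                       theme$stops[[3]]$color[2], theme$stops[[3]]$color[3])
  expect_identical(xml2::xml_attr(first_circle, "fill"), green_hex)
  render_pictogram(overall_score(rep(0, 12)), f)
  red_hex <- sprintf("#%02X%02X%02X", theme$stops[[1]]$color[1],
                     theme$stops[[1]]$color[2], theme$stops[[1]]$color[3])
  expect_identical(
    xml2::xml_attr(xml2::xml_find_first(xml2::read_xml(f),
                                        "//*[local-name() = 'circle']"), "fill"),
    red_hex)
})

test_that("PNG rendering writes a readable raster and bad paths error", {
  res <- overall_score(rep(0.5, 12))
  f <- withr::local_tempfile(fileext = ".png")
  render_pictogram(res, f)
  expect_true(file.size(f) > 0)
  expect_identical(readBin(f, "raw", 8),
                   as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
  expect_error(render_pictogram(res, "/no/such/dir/out.svg"),
               class = "mipgreen_io_error")
  expect_error(render_pictogram(res, withr::local_tempfile(fileext = ".bmp")),
               class = "mipgreen_validation_error")
})
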