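test_that("border fill is arc-length proportional, not angle proportional", {
  # circle: half fill is a semicircle
  arc <- glyph_border_fill(0.5, 0.3, 0.3)
  expect_equal(polyline_length(arc), pi * 0.3, tolerance = 0.01)
  # eccentric 2:1 ellipse: quarter fill covers a quarter of the perimeter
  a <- 0.4; b <- 0.2
  per <- oracle_ellipse_perimeter(a, b)
  arc <- glyph_border_fill(0.25, a, b)
  expect_equal(polyline_length(arc), per / 4, tolerance = 0.01)
  # an angle-proportional arc would be measurably different (quarter
  # sweeps coincide with quarter perimeters by symmetry, so compare at an
  # eighth): on a 3:1 ellipse the 45-degree sweep from 12 o'clock covers
  # flat top only, well short of an eighth of the perimeter
  a3 <- 0.45; b3 <- 0.15
  per3 <- oracle_ellipse_perimeter(a3, b3)
  t <- seq(pi / 2, pi / 4, length.out = 400)
  sweep_len <- sum(sqrt(diff(a3 * cos(t))^2 + diff(b3 * sin(t))^2))
  expect_gt(abs(sweep_len - per3 / 8) / (per3 / 8), 0.10)
  arc3 <- glyph_border_fill(0.125, a3, b3)
  expect_equal(polyline_length(arc3), per3 / 8, tolerance = 0.01)
  # endpoints
  expect_null(glyph_border_fill(0, a, b))
  full <- glyph_border_fill(1, a, b)
  expect_equal(polyline_length(full), per, tolerance = 0.01)
})

test_that("area fill places round(fraction * n_sites) symbols bottom-up", {
  af <- glyph_area_fill(0.5, 0.3, 0.2)
  ns <- attr(af, "n_sites")
  expect_equal(sum(af$type == "point"), round(0.5 * ns))
  expect_null(glyph_area_fill(0, 0.3, 0.2))
  full <- glyph_area_fill(1, 0.3, 0.2)
  expect_equal(sum(full$type == "point"), attr(full, "n_sites"))
  # bottom-up: placed symbols occupy the lowest lattice rows
  half <- glyph_area_fill(0.5, 0.3, 0.2)
  placed_y <- half$y[half$type == "point"]
  all_y <- glyph_area_fill(1, 0.3, 0.2)$y
  expect_lte(max(placed_y), sort(all_y)[round(0.5 * length(all_y)) + 1])
  # determinism
  expect_identical(glyph_area_fill(0.37, 0.3, 0.2),
                   glyph_area_fill(0.37, 0.3, 0.2))
})

test_that("spikes cover the requested perimeter fraction at scaled height", {
  a <- 0.3; b <- 0.2
  expect_null(glyph_spikes(0, 1, a, b))
  expect_null(glyph_spikes(1, 0, a, b))
  sp <- glyph_spikes(0.5, 1, a, b, n_max = 36L)
  expect_equal(dplyr::n_distinct(sp$prim), 18L)
  # each spike apex (middle triangle vertex) stands off its base midpoint
  # by the max spike height, outward from the ellipse
  h_max <- 0.25 * min(a, b)
  for (id in unique(sp$prim)) {
    tri <- sp[sp$prim == id, ]
    apex <- c(tri$x[2], tri$y[2])
    base_mid <- c(mean(tri$x[c(1, 3)]), mean(tri$y[c(1, 3)]))
    off <- sqrt(sum((apex - base_mid)^2))
    expect_lt(off, h_max * 1.1)
    expect_gt(off, h_max * 0.8)
    expect_gte((apex[1] / a)^2 + (apex[2] / b)^2, 1)   # outward
  }
  # full fraction at max height rings the whole perimeter
  full <- glyph_spikes(1, 1, a, b, n_max = 36L)
  expect_equal(dplyr::n_distinct(full$prim), 36L)
  ang <- atan2(full$y / b, full$x / a)
  expect_gt(diff(range(ang)), 2 * pi * 0.9)
})

test_that("sub-circles pack without overlap inside the inner ellipse", {
  expect_null(glyph_subcircles(0, 0.2, 0.12))
  one <- glyph_subcircles(1, 0.2, 0.12)
  expect_equal(dplyr::n_distinct(one$prim), 1L)
  expect_equal(mean(one$x), 0, tolerance = 1e-9)
  three <- glyph_subcircles(3, 0.2, 0.12)
  expect_equal(dplyr::n_distinct(three$prim), 3L)
  centres <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(three), prim),
                              cx = mean(x), cy = mean(y))
  radii <- vapply(split(tibble::as_tibble(three), three$prim), function(p) {
    max(sqrt((p$x - mean(p$x))^2 + (p$y - mean(p$y))^2))
  }, numeric(1))
  # pairwise non-intersecting
  d <- as.matrix(stats::dist(centres[, c("cx", "cy")]))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gt(d[i, j], radii[i] + radii[j])
  }
  # centres inside the ellipse
  expect_true(all((centres$cx / 0.2)^2 + (centres$cy / 0.12)^2 < 1))
  # determinism
  expect_identical(glyph_subcircles(2, 0.2, 0.12),
                   glyph_subcircles(2, 0.2, 0.12))
  expect_warning(glyph_subcircles(40, 0.2, 0.12), "packable")
})

test_that("protrusion half-ellipse width is proportional to the value", {
  a <- 0.3; b <- 0.2
  expect_null(glyph_protrusion(0, a, b))
  for (v in c(0.25, 0.5, 1)) {
    pr <- glyph_protrusion(v, a, b)
    expect_equal(diff(range(pr$x)), v * 2 * a, tolerance = 1e-6)
    expect_true(all(pr$y >= b - 1e-9))          # sits on top
    expect_equal(max(pr$y) - b, 0.5 * (v * 2 * a), tolerance = 1e-6)
  }
})

test_that("organelle fills are height-proportional with segment-area fill", {
  # rectangle: area proportional to height
  og <- glyph_organelle(0.5, "rectangle", h = 0.1, w = 0.06)
  fill <- og[!is.na(og$fill) & og$type == "polygon", ]
  expect_equal(polygon_area_oracle(fill$x, fill$y), 0.5 * 0.1 * 0.06,
               tolerance = 1e-9)
  # ellipse organelle at mid height fills half the area (segment symmetry)
  og <- glyph_organelle(0.5, "ellipse", h = 0.1, w = 0.06)
  fill <- og[!is.na(og$fill) & og$type == "polygon", ]
  outline_area <- pi * 0.03 * 0.05
  expect_equal(polygon_area_oracle(fill$x, fill$y), outline_area / 2,
               tolerance = 0.01)
  # endpoints: empty outline at 0, full fill at 1
  z <- glyph_organelle(0, "ellipse", h = 0.1, w = 0.06)
  expect_true(all(is.na(z$fill)))
  f <- glyph_organelle(1, "ellipse", h = 0.1, w = 0.06)
  fill <- f[!is.na(f$fill) & f$type == "polygon", ]
  expect_equal(polygon_area_oracle(fill$x, fill$y), outline_area,
               tolerance = 0.01)
  # monotone fill area in the value, all three shapes
  for (shape in c("line", "ellipse", "rectangle")) {
    measures <- vapply(seq(0.1, 1, by = 0.1), function(v) {
      og <- glyph_organelle(v, shape, h = 0.1, w = 0.06)
      fl <- og[og$linewidth > 1 | (!is.na(og$fill) & og$type == "polygon"), ]
      if (shape == "line") diff(range(fl$y)) else
        polygon_area_oracle(fl$x, fl$y)
    }, numeric(1))
    expect_true(all(diff(measures) > -1e-12))
  }
})

test_that("render_glyph emits one primitive group per bound element", {
  spec <- demo_spec_15()
  row <- scaled_row(spec, c(0.9, 0.6, 0.5, 0.5, 0.4, 0.3, 0.5, 0.5,
                            0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  sc <- render_glyph(row, spec)
  expect_equal(dplyr::n_distinct(sc$element), 15L)
  expect_setequal(unique(sc$element), spec$bindings$element)
  # determinism: byte-identical output
  expect_identical(sc, render_glyph(row, spec))
  # containment in the unit box around the anchor
  expect_true(all(abs(sc$x) <= 0.5 + 1e-9))
  expect_true(all(abs(sc$y) <= 0.5 + 1e-9))
  sc2 <- render_glyph(row, spec, anchor = c(3, -2), size = 0.5)
  expect_true(all(abs(sc2$x - 3) <= 0.25 + 1e-9))
  expect_true(all(abs(sc2$y + 2) <= 0.25 + 1e-9))
  # unscaled rows are rejected
  bad <- tibble::as_tibble(as.list(stats::setNames(
    c(45, 30, 0.5, 0.5, 20, 15, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    spec$bindings$feature)))
  expect_error(render_glyph(bad, spec), "unscaled")
})

test_that("proportional-fill encodings are monotone and endpoint-faithful", {
  grid <- seq(0, 1, by = 0.1)
  a <- 0.3; b <- 0.2
  arc_len <- vapply(grid, function(f) {
    p <- glyph_border_fill(f, a, b)
    if (is.null(p)) 0 else polyline_length(p)
  }, numeric(1))
  expect_true(all(diff(arc_len) > 0))
  n_sym <- vapply(grid, function(f) {
    p <- glyph_area_fill(f, a, b)
    if (is.null(p)) 0L else sum(p$type == "point")
  }, numeric(1))
  expect_true(all(diff(n_sym) >= 0))
  expect_equal(n_sym[1], 0)
  sp <- vapply(grid, function(f) {
    p <- glyph_spikes(f, 0.8, a, b)
    if (is.null(p)) 0L else dplyr::n_distinct(p$prim)
  }, numeric(1))
  expect_true(all(diff(sp) >= 0))
})

test_that("maximal and minimal glyphs hit the encoding endpoints", {
  spec <- demo_spec_15()
  hi <- scaled_row(spec, c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  sc <- suppressWarnings(render_glyph(hi, spec))  # inner ellipse refit
  border <- sc[sc$element == "main_ellipse_border_fill", ]
  per <- oracle_ellipse_perimeter(0.24, 0.24)
  expect_equal(polyline_length(border), per, tolerance = 0.02)
  lo_vals <- c(0.1, 0.1, 0, 0, 0.1, 0.1, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  sc0 <- suppressWarnings(render_glyph(scaled_row(spec, lo_vals), spec))
  expect_equal(sum(sc0$type == "point"), 0)              # no fill symbols
  expect_false("protrusion" %in% sc0$element)            # no protrusion
  expect_false("spikes_fraction" %in% sc0$element)       # no spikes
  # organelle outlines remain (visual closure), but empty
  expect_true("ellipse_organelle" %in% sc0$element)
  org <- sc0[sc0$element == "ellipse_organelle", ]
  expect_true(all(is.na(org$fill)))
})

test_that("legend has one entry per binding, in order", {
  spec <- demo_spec_15()
  leg <- render_legend(spec)
  expect_equal(dplyr::n_distinct(leg$element), 15L)
  expect_equal(sum(leg$type == "text"), 15L)
  texts <- leg[leg$type == "text", ]
  expect_identical(texts$label, spec$bindings$feature)
  small <- glyph_spec(c(u = "protrusion", v = "spikes_fraction"))
  expect_equal(sum(render_legend(small)$type == "text"), 2L)
  empty <- render_legend(glyph_spec(c(u = "protrusion")))
  expect_equal(sum(empty$type == "text"), 1L)
})

test_that("layouts place anchors on a grid or at rescaled coordinates", {
  g <- layout_glyphs(data.frame(x = 1:6), "grid")
  expect_equal(nrow(g), 6L)
  expect_equal(dplyr::n_distinct(g$x), 3L)   # 2 x 3 row-major
  expect_equal(dplyr::n_distinct(g$y), 2L)
  expect_identical(g$y[1], g$y[2])           # row-major: first row first

  co <- layout_glyphs(data.frame(x = 1:2), "coordinates",
                      coords = cbind(c(0, 1), c(0, 1)))
  expect_equal(co$x, c(0, 1)); expect_equal(co$y, c(0, 1))

  set.seed(7)
  pc <- cbind(rnorm(19), rnorm(19))
  an <- layout_glyphs(data.frame(i = 1:19), "coordinates", coords = pc)
  expect_equal(nrow(an), 19L)
  expect_true(all(an$x >= 0 & an$x <= 1 & an$y >= 0 & an$y <= 1))
  # overlap control: median nearest-neighbour distance >= 1.5 glyph sizes
  d <- as.matrix(stats::dist(an[, c("x", "y")])); diag(d) <- Inf
  expect_gte(stats::median(apply(d, 1, min)) / an$size[1], 1.5 - 1e-9)
  expect_error(layout_glyphs(data.frame(x = 1:3), "coordinates",
                             coords = cbind(1, 1)), "one xy")
})

test_that("scenes export to SVG and ggplot", {
  spec <- demo_spec_15()
  row <- scaled_row(spec, rep(0.5, 15))
  sc <- suppressWarnings(render_glyph(row, spec))
  f <- tempfile(fileext = ".svg")
  write_scene_svg(sc, f)
  svg <- readLines(f)
  expect_true(grepl("<svg", svg[1]))
  expect_gt(sum(grepl("<path", svg)), 10)
  p <- ggplot2::autoplot(sc)
  expect_s3_class(p, "ggplot")
})
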