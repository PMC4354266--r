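# Glyph rendering. A glyph lives in a unit box centred on its anchor; the
# main ellipse semi-axes are GEOM_C * scaled length/width, with GEOM_C chosen
# so that the worst-case glyph (maximal ellipse + protrusion + spikes +
# membrane process) still fits the box.
GEOM_C <- 0.24

ramp_colour <- function(v) {
  pal <- grDevices::hcl.colors(256, "viridis")
  pal[pmin(pmax(round(v * 255), 0), 255) + 1L]
}

#' Border-fill arc of an ellipse
#'
#' Encodes a \[0,1\] fraction as the thickened part of an ellipse border.
#' The thickened arc covers `fraction` of the total *perimeter* (arc length,
#' not sweep angle), starting at 12 o'clock and running clockwise, so the
#' encoding stays perceptually accurate on eccentric ellipses.
#'
#' @param fraction Fraction of the border to thicken, in \[0,1\].
#' @param a,b Ellipse semi-axes.
#' @param element Group tag for the emitted primitives.
#' @param colour Stroke colour.
#' @return A primitive tibble (empty when `fraction` is 0).
#' @export
glyph_border_fill <- function(fraction, a, b,
                              element = "main_ellipse_border_fill",
                              colour = "black") {
  fraction <- clip_unit(fraction, what = "border fraction")
  if (fraction <= 0) return(NULL)
  total <- ellipse_perimeter(a, b)
  pts <- ellipse_arc_points(a, b, 0, fraction * total)
  scene_prim(element, "polyline", pts$x, pts$y,
             colour = colour, linewidth = 2.4)
}

#' Area-fill symbol placement inside an ellipse
#'
#' Encodes a \[0,1\] fraction as the proportion of a region filled with
#' symbols. Symbols sit on a fixed hexagonal lattice inside the ellipse and
#' are placed bottom-up until `round(fraction * n_sites)` sites are covered,
#' so the covered-site fraction tracks the value to within half a site.
#' The region outline is drawn (closure) unless `outline = FALSE`.
#'
#' @param fraction Fill fraction in \[0,1\].
#' @param a,b Region ellipse semi-axes.
#' @param cx,cy Region centre.
#' @param exclude Optional inner ellipse `list(a=, b=, cx=, cy=)` whose
#'   interior is excluded from the lattice (perinuclear ring fills).
#' @param element Group tag.
#' @param colour Symbol/outline colour.
#' @param outline Draw the region outline as part of this group.
#' @return A primitive tibble; attribute `n_sites` carries the lattice size.
#' @export
glyph_area_fill <- function(fraction, a, b, cx = 0, cy = 0, exclude = NULL,
                            element = "main_ellipse_area_fill",
                            colour = "grey25", outline = FALSE) {
  fraction <- clip_unit(fraction, what = "fill fraction")
  lat <- hex_lattice_in_ellipse(a, b, cx, cy)
  keep <- rep(TRUE, length(lat$x))
  if (!is.null(exclude)) {
    keep <- ((lat$x - exclude$cx) / exclude$a)^2 +
            ((lat$y - exclude$cy) / exclude$b)^2 > 1
  }
  xs <- lat$x[keep]; ys <- lat$y[keep]
  n_sites <- length(xs)
  n_fill <- round(fraction * n_sites)
  parts <- list()
  if (outline) {
    ep <- ellipse_polygon(a, b, cx, cy)
    parts$outline <- scene_prim(element, "polyline",
                                c(ep$x, ep$x[1]), c(ep$y, ep$y[1]),
                                colour = colour, linewidth = 0.6)
  }
  if (n_fill > 0) {
    sym <- scene_prim(element, "point", xs[seq_len(n_fill)],
                      ys[seq_len(n_fill)],
                      colour = colour, size = lat$pitch * 0.42)
    sym$prim <- seq_len(n_fill)  # one point per primitive
    parts$symbols <- sym
  }
  if (!length(parts)) return(NULL)
  out <- new_scene(renumber_prims(dplyr::bind_rows(parts)))
  attr(out, "n_sites") <- n_sites
  out
}

#' Spikes along an ellipse border
#'
#' Triangular spikes placed outward along a contiguous clockwise arc starting
#' at 12 o'clock. The arc covers `fraction` of the perimeter (arc length);
#' spike height is `height` times the maximum spike height, fixed at 25% of
#' the minor semi-axis. A full-fraction border carries `n_max` spikes.
#'
#' @param fraction Perimeter fraction covered by spikes, \[0,1\].
#' @param height Relative spike height, \[0,1\].
#' @param a,b Ellipse semi-axes.
#' @param n_max Spike count at fraction 1.
#' @param element Group tag.
#' @param colour Colour.
#' @return A primitive tibble of triangles (empty if either value is 0).
#' @export
glyph_spikes <- function(fraction, height, a, b, n_max = 36L,
                         element = "spikes_fraction", colour = "black") {
  fraction <- clip_unit(fraction, what = "spike fraction")
  height <- clip_unit(height, what = "spike height")
  if (fraction <= 0 || height <= 0) return(NULL)
  total <- ellipse_perimeter(a, b)
  pitch <- total / n_max
  k <- round(fraction * n_max)
  if (k == 0) return(NULL)
  h <- height * 0.25 * min(a, b)
  tris <- vector("list", k)
  for (i in seq_len(k)) {
    s_mid <- (i - 0.5) * pitch
    p0 <- ellipse_point_normal(a, b, s_mid - pitch * 0.35)
    p1 <- ellipse_point_normal(a, b, s_mid + pitch * 0.35)
    pm <- ellipse_point_normal(a, b, s_mid)
    tri <- scene_prim(element, "polygon",
                      c(p0$x, pm$x + h * pm$nx, p1$x),
                      c(p0$y, pm$y + h * pm$ny, p1$y),
                      colour = colour, fill = colour, linewidth = 0.3)
    tri$prim <- i
    tris[[i]] <- tri
  }
  new_scene(dplyr::bind_rows(tris))
}

#' Sub-circles inside an ellipse
#'
#' Encodes a non-negative count (e.g. nuclei per cell) as that many
#' non-overlapping circles inside the inner ellipse, on a deterministic
#' centre-then-ring layout: one circle is centred, further circles sit on a
#' ring at 55% of the ellipse; the circle radius shrinks with the count.
#'
#' @param count Non-negative integer.
#' @param a,b Inner-ellipse semi-axes.
#' @param element Group tag.
#' @param colour Colour.
#' @return A primitive tibble of circle outlines (empty for count 0).
#' @export
glyph_subcircles <- function(count, a, b, element = "inner_subcircle_count",
                             colour = "black") {
  count <- as.integer(round(count))
  stopifnot(count >= 0)
  if (count == 0) return(NULL)
  centres_x <- numeric(0); centres_y <- numeric(0)
  if (count == 1L) {
    centres_x <- 0; centres_y <- 0
    r <- 0.4 * min(a, b)
  } else {
    on_ring <- count
    use_centre <- count >= 7L
    if (use_centre) { centres_x <- 0; centres_y <- 0; on_ring <- count - 1L }
    th <- pi / 2 + 2 * pi * (seq_len(on_ring) - 1L) / on_ring
    centres_x <- c(centres_x, 0.55 * a * cos(th))
    centres_y <- c(centres_y, 0.55 * b * sin(th))
    d <- stats::dist(cbind(centres_x, centres_y))
    r <- min(0.35 * min(a, b), 0.45 * min(d))
    r_floor <- 0.06 * min(a, b)
    if (r < r_floor) {
      warning("Sub-circle count ", count,
              " exceeds packable maximum; using radius floor.", call. = FALSE)
      r <- r_floor
    }
  }
  circ <- function(i) {
    cp <- ellipse_polygon(r, r, centres_x[i], centres_y[i], n = 64L)
    pr <- scene_prim(element, "polygon", cp$x, cp$y,
                     colour = colour, linewidth = 0.5)
    pr$prim <- i
    pr
  }
  new_scene(dplyr::bind_rows(lapply(seq_len(count), circ)))
}

#' Protrusion half-ellipse on top of the cell
#'
#' The relative protrusion area is encoded as a half-ellipse sitting on top
#' of the main ellipse whose major dimension is `rel_area` times the main
#' ellipse major dimension; its height is half its own major dimension.
#'
#' @param rel_area Relative protrusion area, \[0,1\].
#' @param a,b Main ellipse semi-axes.
#' @param element Group tag.
#' @param colour Colour.
#' @return A primitive tibble (empty at 0).
#' @export
glyph_protrusion <- function(rel_area, a, b, element = "protrusion",
                             colour = "black") {
  rel_area <- clip_unit(rel_area, what = "relative protrusion area")
  if (rel_area <= 0) return(NULL)
  w <- rel_area * 2 * a     # major dimension of the half-ellipse
  h <- 0.5 * w
  t <- seq(0, pi, length.out = 97L)   # odd count so the apex is on the grid
  scene_prim(element, "polygon", (w / 2) * cos(t), b + h * sin(t),
             colour = colour, fill = "grey85", linewidth = 0.6)
}

#' Membrane-process stalk
#'
#' A single stalk on the left side of the glyph whose length is proportional
#' to the bound value (up to half the major semi-axis).
#'
#' @param value Value in \[0,1\].
#' @param a,b Main ellipse semi-axes.
#' @param element Group tag.
#' @param colour Colour.
#' @return A primitive tibble (empty at 0).
#' @export
glyph_membrane_process <- function(value, a, b, element = "membrane_process",
                                   colour = "black") {
  value <- clip_unit(value, what = "membrane process value")
  if (value <= 0) return(NULL)
  scene_prim(element, "polyline",
             c(-a, -a - value * 0.5 * a), c(0, 0),
             colour = colour, linewidth = 1.6)
}

#' Fillable organelle glyphs
#'
#' Line, ellipse and rectangle organelles sit at fixed slots in the lower
#' cytoplasm. The outline is always drawn; the interior is filled from the
#' bottom up to `value` times the organelle height (height-proportional;
#' for the ellipse organelle the filled region is the segment below the cut,
#' so area follows the segment formula and equals half the area at value
#' 0.5 by symmetry).
#'
#' @param value Fill value in \[0,1\].
#' @param shape `"line"`, `"ellipse"` or `"rectangle"`.
#' @param cx,cy Slot centre.
#' @param h Organelle full height.
#' @param w Organelle width.
#' @param element Group tag.
#' @param colour Colour.
#' @return A primitive tibble (outline plus fill).
#' @export
glyph_organelle <- function(value, shape = c("line", "ellipse", "rectangle"),
                            cx = 0, cy = 0, h = 0.1, w = 0.05,
                            element = paste0(shape[1], "_organelle"),
                            colour = "black") {
  shape <- match.arg(shape)
  value <- clip_unit(value, what = "organelle value")
  y0 <- cy - h / 2; y1 <- cy + h / 2
  parts <- list()
  if (shape == "line") {
    parts$outline <- scene_prim(element, "polyline", c(cx, cx), c(y0, y1),
                                colour = colour, linewidth = 0.5)
    if (value > 0) {
      parts$fill <- scene_prim(element, "polyline", c(cx, cx),
                               c(y0, y0 + value * h),
                               colour = colour, linewidth = 2.2)
    }
  } else if (shape == "rectangle") {
    parts$outline <- scene_prim(
      element, "polygon", cx + c(-1, 1, 1, -1) * w / 2,
      c(y0, y0, y1, y1), colour = colour, linewidth = 0.5)
    if (value > 0) {
      yc <- y0 + value * h
      parts$fill <- scene_prim(
        element, "polygon", cx + c(-1, 1, 1, -1) * w / 2,
        c(y0, y0, yc, yc), colour = colour, fill = colour, linewidth = 0.3)
    }
  } else { # ellipse organelle: fill = segment below the cut height
    rx <- w / 2; ry <- h / 2
    ep <- ellipse_polygon(rx, ry, cx, cy, n = 128L)
    parts$outline <- scene_prim(element, "polygon", ep$x, ep$y,
                                colour = colour, linewidth = 0.5)
    if (value > 0) {
      q <- pmin(pmax(2 * value - 1, -1), 1)   # cut height in [-ry, ry]
      thc <- asin(q)
      t <- seq(pi - thc, 2 * pi + thc, length.out = 128L)
      parts$fill <- scene_prim(element, "polygon",
                               cx + rx * cos(t), cy + ry * sin(t),
                               colour = colour, fill = colour, linewidth = 0.3)
    }
  }
  scene_bind(parts$outline, parts$fill)
}

# Resolve the scaled value bound to an element, or `default` when unbound.
bound_value <- function(row, spec, element, default = NA_real_) {
  i <- match(element, spec$bindings$element)
  if (is.na(i)) return(default)
  as.numeric(row[[spec$bindings$feature[i]]])
}

is_bound <- function(spec, element) element %in% spec$bindings$element

elem_colour <- function(spec, element, default = "black") {
  pal <- spec$palette[[element]]
  if (is.null(pal) || is.null(pal$colour)) default else pal$colour
}

assert_scaled_row <- function(row, spec) {
  if (identical(attr(row, "scaling"), "scaled")) return(invisible(TRUE))
  for (i in seq_len(nrow(spec$bindings))) {
    v <- as.numeric(row[[spec$bindings$feature[i]]])
    dom <- spec$registry$domain[i]
    ok <- switch(dom,
      dimensional = v >= 0.1 - 1e-9 && v <= 1 + 1e-9,
      unit = v >= -1e-9 && v <= 1 + 1e-9,
      count = v >= 0)
    if (!isTRUE(ok)) {
      stop("Row appears unscaled: ", spec$bindings$feature[i], " = ", v,
           " is outside the ", dom, " domain. Run scale_features() first.",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Render one glyph
#'
#' Converts a scaled feature row plus a validated glyph spec into a scene of
#' drawing primitives, one primitive group per bound element (unbound
#' elements are absent). Ellipse outlines defined by a length/width pair are
#' split into right/left half-arcs so each of the two bindings owns a group.
#' Output is deterministic: identical inputs give identical primitive lists.
#'
#' @param row A single-row data frame (or coercible) of *scaled* feature
#'   values; a row of an unscaled table is rejected.
#' @param spec A validated `glyph_spec`.
#' @param anchor Length-2 numeric, glyph centre in canvas coordinates.
#' @param size Glyph box edge length in canvas units.
#' @return A `glyph_scene`; all geometry lies inside the unit box scaled by
#'   `size` and centred on `anchor`.
#' @export
render_glyph <- function(row, spec, anchor = c(0, 0), size = 1) {
  stopifnot(inherits(spec, "glyph_spec"))
  if (is.data.frame(row)) {
    stopifnot(nrow(row) == 1)
  } else {
    row <- tibble::as_tibble(as.list(row))
  }
  assert_scaled_row(row, spec)

  len <- bound_value(row, spec, "main_ellipse_length", 0.7)
  wid <- bound_value(row, spec, "main_ellipse_width", 0.5)
  a <- GEOM_C * len; b <- GEOM_C * wid

  # inner (nuclear) ellipse; shares the joint dimensional scale with the cell
  ilen <- bound_value(row, spec, "inner_ellipse_length", 0.45 * len)
  iwid <- bound_value(row, spec, "inner_ellipse_width", 0.45 * wid)
  ai <- GEOM_C * ilen; bi <- GEOM_C * iwid
  if (ai > 0.85 * a || bi > 0.85 * b) {
    sh <- min(0.85 * a / ai, 0.85 * b / bi)
    warning("Inner ellipse rescaled by ", signif(sh, 3),
            " to fit inside the main ellipse.", call. = FALSE)
    ai <- ai * sh; bi <- bi * sh
  }
  plen <- bound_value(row, spec, "perinuclear_ellipse_length", NA_real_)
  pwid <- bound_value(row, spec, "perinuclear_ellipse_width", NA_real_)
  ap <- GEOM_C * plen; bp <- GEOM_C * pwid
  if (!is.na(ap) && (ap > 0.92 * a || bp > 0.92 * b)) {
    sh <- min(0.92 * a / ap, 0.92 * b / bp)
    warning("Perinuclear ellipse rescaled by ", signif(sh, 3),
            " to fit inside the main ellipse.", call. = FALSE)
    ap <- ap * sh; bp <- bp * sh
  }

  half_arcs <- function(a, b, el_len, el_wid, colour, lwd = 0.8) {
    t_r <- seq(-pi / 2, pi / 2, length.out = 128L)
    t_l <- seq(pi / 2, 3 * pi / 2, length.out = 128L)
    list(
      scene_prim(el_len, "polyline", a * cos(t_r), b * sin(t_r),
                 colour = colour, linewidth = lwd),
      scene_prim(el_wid, "polyline", a * cos(t_l), b * sin(t_l),
                 colour = colour, linewidth = lwd)
    )
  }

  parts <- list()

  # colour washes first (underneath everything else)
  if (is_bound(spec, "main_ellipse_colour")) {
    v <- clip_unit(bound_value(row, spec, "main_ellipse_colour"))
    ep <- ellipse_polygon(a, b)
    parts <- c(parts, list(scene_prim("main_ellipse_colour", "polygon",
                                      ep$x, ep$y, colour = NA_character_,
                                      fill = ramp_colour(v), linewidth = 0)))
  }
  if (is_bound(spec, "perinuclear_ellipse_colour") && !is.na(ap)) {
    v <- clip_unit(bound_value(row, spec, "perinuclear_ellipse_colour"))
    ep <- ellipse_polygon(ap, bp)
    parts <- c(parts, list(scene_prim("perinuclear_ellipse_colour", "polygon",
                                      ep$x, ep$y, colour = NA_character_,
                                      fill = ramp_colour(v), linewidth = 0)))
  }
  if (is_bound(spec, "inner_ellipse_colour")) {
    v <- clip_unit(bound_value(row, spec, "inner_ellipse_colour"))
    ep <- ellipse_polygon(ai, bi)
    parts <- c(parts, list(scene_prim("inner_ellipse_colour", "polygon",
                                      ep$x, ep$y, colour = NA_character_,
                                      fill = ramp_colour(v), linewidth = 0)))
  }

  # outlines, owned by their dimension bindings
  if (is_bound(spec, "main_ellipse_length")) {
    parts <- c(parts, half_arcs(a, b, "main_ellipse_length",
                                "main_ellipse_width",
                                elem_colour(spec, "main_ellipse_length")))
  }
  if (is_bound(spec, "perinuclear_ellipse_length") && !is.na(ap)) {
    parts <- c(parts, half_arcs(ap, bp, "perinuclear_ellipse_length",
                                "perinuclear_ellipse_width",
                                elem_colour(spec, "perinuclear_ellipse_length",
                                            "grey40"), 0.6))
  }
  if (is_bound(spec, "inner_ellipse_length")) {
    parts <- c(parts, half_arcs(ai, bi, "inner_ellipse_length",
                                "inner_ellipse_width",
                                elem_colour(spec, "inner_ellipse_length")))
  }

  # proportional fills
  if (is_bound(spec, "main_ellipse_area_fill")) {
    v <- bound_value(row, spec, "main_ellipse_area_fill")
    parts <- c(parts, list(glyph_area_fill(
      v, a, b, exclude = list(a = ai, b = bi, cx = 0, cy = 0),
      element = "main_ellipse_area_fill",
      colour = elem_colour(spec, "main_ellipse_area_fill", "grey25"),
      outline = !is_bound(spec, "main_ellipse_length"))))
  }
  if (is_bound(spec, "inner_ellipse_area_fill")) {
    v <- bound_value(row, spec, "inner_ellipse_area_fill")
    parts <- c(parts, list(glyph_area_fill(
      v, ai, bi, element = "inner_ellipse_area_fill",
      colour = elem_colour(spec, "inner_ellipse_area_fill", "grey25"),
      outline = !is_bound(spec, "inner_ellipse_length"))))
  }
  if (is_bound(spec, "perinuclear_ellipse_area_fill") && !is.na(ap)) {
    v <- bound_value(row, spec, "perinuclear_ellipse_area_fill")
    parts <- c(parts, list(glyph_area_fill(
      v, ap, bp, exclude = list(a = ai, b = bi, cx = 0, cy = 0),
      element = "perinuclear_ellipse_area_fill",
      colour = elem_colour(spec, "perinuclear_ellipse_area_fill", "grey45"),
      outline = !is_bound(spec, "perinuclear_ellipse_length"))))
  }
  if (is_bound(spec, "main_ellipse_border_fill")) {
    v <- bound_value(row, spec, "main_ellipse_border_fill")
    parts <- c(parts, list(glyph_border_fill(
      v, a, b, colour = elem_colour(spec, "main_ellipse_border_fill"))))
  }

  if (is_bound(spec, "inner_subcircle_count")) {
    cnt <- bound_value(row, spec, "inner_subcircle_count", 0)
    parts <- c(parts, list(glyph_subcircles(
      cnt, ai, bi, colour = elem_colour(spec, "inner_subcircle_count"))))
  }
  if (is_bound(spec, "protrusion")) {
    v <- bound_value(row, spec, "protrusion")
    parts <- c(parts, list(glyph_protrusion(
      v, a, b, colour = elem_colour(spec, "protrusion"))))
  }
  if (is_bound(spec, "spikes_fraction") || is_bound(spec, "spikes_height")) {
    fr <- bound_value(row, spec, "spikes_fraction", 1)
    ht <- bound_value(row, spec, "spikes_height", 0.5)
    sp <- glyph_spikes(fr, ht, a, b,
                       colour = elem_colour(spec, "spikes_fraction"))
    if (!is.null(sp)) {
      # height binding owns every other spike so both bindings have a group
      if (is_bound(spec, "spikes_height") && is_bound(spec, "spikes_fraction")) {
        ids <- unique(sp$prim)
        sp$element[sp$prim %in% ids[seq_along(ids) %% 2L == 0L]] <-
          "spikes_height"
        if (length(ids) == 1L) {
          extra <- sp[sp$prim == ids[1], ]
          extra$element <- "spikes_height"
          sp <- new_scene(dplyr::bind_rows(sp, extra))
        }
      } else if (is_bound(spec, "spikes_height")) {
        sp$element <- "spikes_height"
      }
      parts <- c(parts, list(sp))
    }
  }
  if (is_bound(spec, "membrane_process")) {
    v <- bound_value(row, spec, "membrane_process")
    parts <- c(parts, list(glyph_membrane_process(
      v, a, b, colour = elem_colour(spec, "membrane_process"))))
  }

  # organelle slots, lower cytoplasm between inner ellipse and main border
  org_h <- 0.35 * b; org_w <- 0.16 * a
  slots <- list(line = c(-0.45 * a, -0.55 * b),
                ellipse = c(0, -0.62 * b),
                rectangle = c(0.45 * a, -0.55 * b))
  for (shp in names(slots)) {
    el <- paste0(shp, "_organelle")
    if (is_bound(spec, el)) {
      v <- bound_value(row, spec, el)
      parts <- c(parts, list(glyph_organelle(
        v, shp, cx = slots[[shp]][1], cy = slots[[shp]][2],
        h = org_h, w = org_w, element = el,
        colour = elem_colour(spec, el))))
    }
  }

  scene <- new_scene(renumber_prims(dplyr::bind_rows(purrr::compact(parts))))
  scene_place(scene, anchor, size)
}

# Renumber consecutive (element, prim) runs into globally unique prim ids.
renumber_prims <- function(df) {
  if (!nrow(df)) return(df)
  key <- paste(df$element, df$prim)
  run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  df$prim <- run
  df
}

#' Render the automatic legend for a glyph spec
#'
#' One entry per binding, in binding order: a miniature of the element drawn
#' at mid-value next to the feature's display label.
#'
#' @param spec A validated `glyph_spec`.
#' @return A `glyph_scene` with one `element` group plus text per binding.
#' @export
render_legend <- function(spec) {
  stopifnot(inherits(spec, "glyph_spec"))
  n <- nrow(spec$bindings)
  if (n == 0) return(new_scene())
  a0 <- 0.05; b0 <- 0.035   # reference mini-ellipse
  parts <- list()
  for (i in seq_len(n)) {
    el <- spec$bindings$element[i]
    fam <- spec$registry$family[i]
    cy <- -(i - 1) * 0.12
    mini <- switch(
      fam,
      "main-ellipse-dim" = ,
      "inner-ellipse-dim" = ,
      "perinuclear-ellipse-dim" = {
        ep <- ellipse_polygon(a0, b0, 0, cy)
        scene_prim(el, "polyline", c(ep$x, ep$x[1]), c(ep$y, ep$y[1]),
                   linewidth = 0.6)
      },
      "colour" = {
        ep <- ellipse_polygon(a0, b0, 0, cy)
        scene_prim(el, "polygon", ep$x, ep$y, colour = NA_character_,
                   fill = ramp_colour(0.5))
      },
      "area-fill" = {
        sc <- glyph_area_fill(0.5, a0, b0, cy = cy, element = el,
                              outline = TRUE)
        sc
      },
      "border-fill" = {
        sc <- glyph_border_fill(0.5, a0, b0, element = el)
        sc$y <- sc$y + cy
        sc
      },
      "spikes-fraction" = ,
      "spikes-height" = {
        sc <- glyph_spikes(0.5, 0.8, a0, b0, n_max = 12L, element = el)
        sc$y <- sc$y + cy
        sc
      },
      "subcircle-count" = {
        sc <- glyph_subcircles(2, a0, b0, element = el)
        sc$y <- sc$y + cy
        sc
      },
      "protrusion" = {
        sc <- glyph_protrusion(0.6, a0, b0, element = el)
        sc$y <- sc$y + cy - b0
        sc
      },
      "membrane-process" = {
        scene_prim(el, "polyline", c(-a0, a0), c(cy, cy), linewidth = 1.6)
      },
      "organelle-line" = glyph_organelle(0.5, "line", cx = 0, cy = cy,
                                         h = 0.07, w = 0.04, element = el),
      "organelle-ellipse" = glyph_organelle(0.5, "ellipse", cx = 0, cy = cy,
                                            h = 0.07, w = 0.05, element = el),
      "organelle-rectangle" = glyph_organelle(0.5, "rectangle", cx = 0,
                                              cy = cy, h = 0.07, w = 0.05,
                                              element = el)
    )
    label <- scene_prim(el, "text", 0.12, cy,
                        label = spec$bindings$label[i], size = 0.03)
    parts <- c(parts, list(mini, label))
  }
  new_scene(renumber_prims(dplyr::bind_rows(purrr::compact(parts))))
}

#' Compute glyph anchors for a set of rows
#'
#' Grid mode lays glyphs out row-major on a near-square grid with uniform
#' spacing. Coordinate mode (e.g. positions from the first two principal
#' components) rescales the supplied xy to the unit canvas and chooses the
#' glyph size so that the median nearest-neighbour distance is at least 1.5
#' glyph widths, trading size for legibility in crowded layouts.
#'
#' @param data Data frame of glyph rows (only the row count is used in grid
#'   mode).
#' @param mode `"grid"` or `"coordinates"`.
#' @param coords Two-column matrix/data frame of xy positions, one per row;
#'   required in coordinate mode.
#' @return A tibble with columns `x`, `y` (anchor) and `size`.
#' @export
layout_glyphs <- function(data, mode = c("grid", "coordinates"),
                          coords = NULL) {
  mode <- match.arg(mode)
  n <- nrow(data)
  if (mode == "grid") {
    nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
    idx <- seq_len(n) - 1L
    return(tibble::tibble(
      x = (idx %% nc) + 0.5,
      y = nr - (idx %/% nc) - 0.5,
      size = 0.9
    ))
  }
  if (is.null(coords)) stop("Coordinate mode requires `coords`.", call. = FALSE)
  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 2) {
    stop("`coords` must have one xy pair per data row.", call. = FALSE)
  }
  rescale01 <- function(v) {
    r <- range(v); if (diff(r) == 0) rep(0.5, length(v))
    else (v - r[1]) / diff(r)
  }
  x <- rescale01(coords[, 1]); y <- rescale01(coords[, 2])
  size <- 0.18
  if (n >= 2) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    diag(d) <- Inf
    nn <- apply(d, 1, min)
    size <- min(size, stats::median(nn) / 1.5)
  }
  tibble::tibble(x = x, y = y, size = max(size, 1e-3))
}

#' Render a whole table of glyphs as one scene
#'
#' Scales nothing itself: pass a table already processed by
#' [scale_features()]. Each row becomes one glyph at its layout anchor.
#'
#' @param data Scaled feature table.
#' @param spec A validated `glyph_spec`.
#' @inheritParams layout_glyphs
#' @param labels Optional character vector of per-glyph labels drawn under
#'   each glyph.
#' @return A `glyph_scene`.
#' @export
render_glyph_panel <- function(data, spec, mode = c("grid", "coordinates"),
                               coords = NULL, labels = NULL) {
  anchors <- layout_glyphs(data, mode, coords)
  scenes <- purrr::map(seq_len(nrow(data)), function(i) {
    row <- data[i, , drop = FALSE]
    attr(row, "scaling") <- attr(data, "scaling")
    sc <- render_glyph(row, spec, anchor = c(anchors$x[i], anchors$y[i]),
                       size = anchors$size[i])
    if (!is.null(labels)) {
      lab <- scene_prim("glyph_label", "text",
                        anchors$x[i] - anchors$size[i] * 0.3,
                        anchors$y[i] - anchors$size[i] * 0.55,
                        label = labels[i], size = anchors$size[i] * 0.08)
      sc <- new_scene(renumber_prims(dplyr::bind_rows(sc, lab)))
    }
    sc
  })
  new_scene(renumber_prims(dplyr::bind_rows(scenes)))
}
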