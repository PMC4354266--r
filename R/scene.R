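#' Drawing-primitive scenes
#'
#' A scene is a resolution-independent, ordered list of drawing primitives:
#' a tibble with one row per vertex (points and text occupy a single row),
#' grouped into primitives by `prim` and into logical groups by `element`.
#' Columns: `element`, `prim` (integer, unique per primitive), `type`
#' (`"polygon"`, `"polyline"`, `"point"`, `"text"`), `x`, `y`, `label`,
#' `colour`, `fill`, `linewidth`, `size`. Scenes compose with
#' [scene_bind()] and export via [autoplot.glyph_scene()] or
#' [write_scene_svg()].
#'
#' @name glyph_scene
NULL

scene_cols <- c("element", "prim", "type", "x", "y", "label",
                "colour", "fill", "linewidth", "size")

new_scene <- function(df = NULL) {
  if (is.null(df)) {
    df <- tibble::tibble(
      element = character(), prim = integer(), type = character(),
      x = numeric(), y = numeric(), label = NA_character_,
      colour = character(), fill = NA_character_,
      linewidth = numeric(), size = NA_real_
    )[0, ]
  }
  df <- tibble::as_tibble(df)[, scene_cols]
  class(df) <- c("glyph_scene", class(df))
  df
}

scene_prim <- function(element, type, x, y, label = NA_character_,
                       colour = "black", fill = NA_character_,
                       linewidth = 0.5, size = NA_real_) {
  n <- max(length(x), 1L)
  tibble::tibble(
    element = element, prim = 1L, type = type,
    x = if (length(x)) x else NA_real_, y = if (length(y)) y else NA_real_,
    label = label, colour = colour, fill = fill,
    linewidth = linewidth, size = size
  )
}

# Bind primitive tibbles into one scene, renumbering prim ids consecutively
# in input order so primitive order is deterministic.
scene_bind <- function(...) {
  parts <- purrr::compact(list(...))
  parts <- parts[vapply(parts, nrow, 1L) > 0]
  if (!length(parts)) return(new_scene())
  renumbered <- list(); next_id <- 0L
  for (p in parts) {
    ids <- cumsum(!duplicated(p$prim) &
                    c(TRUE, p$prim[-1] != p$prim[-nrow(p)]))
    # stable renumber: consecutive runs of the same prim id form one primitive
    run <- cumsum(c(TRUE, p$prim[-1] != p$prim[-nrow(p)]))
    p$prim <- next_id + run
    next_id <- max(p$prim)
    renumbered[[length(renumbered) + 1L]] <- p
  }
  new_scene(dplyr::bind_rows(renumbered))
}

# Affine-place a scene: local coordinates scaled by `size`, shifted to anchor.
scene_place <- function(scene, anchor = c(0, 0), size = 1) {
  scene$x <- scene$x * size + anchor[1]
  scene$y <- scene$y * size + anchor[2]
  scene$size <- scene$size * size
  scene$linewidth <- scene$linewidth * size
  scene
}

#' @export
print.glyph_scene <- function(x, ...) {
  cat("<glyph_scene> ", dplyr::n_distinct(x$prim), " primitive(s), ",
      dplyr::n_distinct(x$element), " element group(s)\n", sep = "")
  NextMethod()
}

#' Plot a scene with ggplot2
#'
#' @param object A `glyph_scene`.
#' @param ... Unused.
#' @return A ggplot object with fixed aspect ratio and no axes.
#' @export
autoplot.glyph_scene <- function(object, ...) {
  df <- tibble::as_tibble(object)
  pg <- df[df$type == "polygon", ]
  pl <- df[df$type == "polyline", ]
  pt <- df[df$type == "point", ]
  tx <- df[df$type == "text", ]
  p <- ggplot2::ggplot()
  if (nrow(pg)) {
    p <- p + ggplot2::geom_polygon(
      data = pg,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$prim),
      fill = pg$fill[!duplicated(pg$prim)] %|NA|% NA,
      colour = pg$colour[!duplicated(pg$prim)],
      linewidth = pg$linewidth[!duplicated(pg$prim)] * 2
    )
  }
  if (nrow(pl)) {
    p <- p + ggplot2::geom_path(
      data = pl,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$prim),
      colour = pl$colour[!duplicated(pl$prim)],
      linewidth = pl$linewidth[!duplicated(pl$prim)] * 2,
      lineend = "round"
    )
  }
  if (nrow(pt)) {
    p <- p + ggplot2::geom_point(
      data = pt, ggplot2::aes(x = .data$x, y = .data$y),
      colour = pt$colour, size = pt$size * 8, shape = 16
    )
  }
  if (nrow(tx)) {
    p <- p + ggplot2::geom_text(
      data = tx, ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      colour = tx$colour, size = tx$size * 28, hjust = 0
    )
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void()
}

`%|NA|%` <- function(x, y) { x[is.na(x)] <- y; x }

#' Export a scene as an SVG 1.1 file
#'
#' Primitives are written as SVG paths (polygons/polylines), circles
#' (points) and text elements. Coordinates are mapped so that the scene
#' bounding box fills the canvas with a 2% margin; SVG y runs downward, so
#' the y axis is flipped.
#'
#' @param scene A `glyph_scene`.
#' @param path Output file path.
#' @param width,height Canvas size in SVG user units (pixels).
#' @return `path`, invisibly.
#' @export
write_scene_svg <- function(scene, path, width = 800, height = 800) {
  df <- tibble::as_tibble(scene)
  if (!nrow(df)) {
    writeLines(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d"/>',
      round(width), round(height)), path)
    return(invisible(path))
  }
  xr <- range(df$x, na.rm = TRUE); yr <- range(df$y, na.rm = TRUE)
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  sc <- min(width * 0.96 / diff(xr), height * 0.96 / diff(yr))
  tx <- function(x) (x - xr[1]) * sc + (width - diff(xr) * sc) / 2
  ty <- function(y) height - ((y - yr[1]) * sc + (height - diff(yr) * sc) / 2)
  fmt <- function(v) formatC(v, format = "f", digits = 2)
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
    round(width), round(height), round(width), round(height)))
  for (id in unique(df$prim)) {
    p <- df[df$prim == id, ]
    type <- p$type[1]
    col <- p$colour[1]; fill <- p$fill[1]
    lw <- fmt(max(p$linewidth[1] * sc * 0.004, 0.4))
    if (type %in% c("polygon", "polyline")) {
      d <- paste0("M", paste(paste0(fmt(tx(p$x)), ",", fmt(ty(p$y))),
                             collapse = " L"),
                  if (type == "polygon") " Z" else "")
      lines <- c(lines, sprintf(
        '<path d="%s" fill="%s" stroke="%s" stroke-width="%s" stroke-linecap="round"/>',
        d, if (is.na(fill)) "none" else fill, col, lw))
    } else if (type == "point") {
      lines <- c(lines, sprintf(
        '<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
        fmt(tx(p$x[1])), fmt(ty(p$y[1])), fmt(max(p$size[1] * sc * 0.5, 0.8)),
        col))
    } else if (type == "text") {
      lines <- c(lines, sprintf(
        '<text x="%s" y="%s" font-size="%s" font-family="sans-serif" fill="%s">%s</text>',
        fmt(tx(p$x[1])), fmt(ty(p$y[1])), fmt(max(p$size[1] * sc, 8)), col,
        esc(p$label[1])))
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}
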