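#' The glyph element registry
#'
#' The fixed set of 21 visual elements that features can be mapped to. Each
#' element encodes one variable through a distinct visual channel: ellipse
#' dimensions for the cell body, nucleus and perinuclear region; colour hues
#' for marker intensities; proportional filling (partial filling of a closed
#' outline, read off by visual closure) for bounded fractions such as texture
#' indices or the neighbour fraction; spikes, a protrusion half-ellipse, a
#' membrane process, sub-circle counts, and three fillable organelle glyphs.
#'
#' Exactly 8 of the 21 elements use proportional filling: the area fills of
#' the main, inner and perinuclear ellipses, the main-ellipse border fill,
#' the spikes fraction, and the three organelles.
#'
#' @return A tibble with one row per element and columns
#'   `element` (unique identifier), `family` (geometry family),
#'   `proportional_fill` (logical), `colour_dependent` (logical),
#'   `domain` (`"unit"` for values in \[0,1\], `"dimensional"` for jointly
#'   scaled lengths/widths in \[0.1,1\], `"count"` for non-negative integers).
#' @examples
#' reg <- element_registry()
#' nrow(reg)                        # 21
#' sum(reg$proportional_fill)       # 8
#' @export
element_registry <- function() {
  reg <- tibble::tribble(
    ~element,                       ~family,                   ~proportional_fill, ~colour_dependent, ~domain,
    "main_ellipse_length",          "main-ellipse-dim",        FALSE, FALSE, "dimensional",
    "main_ellipse_width",           "main-ellipse-dim",        FALSE, FALSE, "dimensional",
    "main_ellipse_colour",          "colour",                  FALSE, TRUE,  "unit",
    "main_ellipse_area_fill",       "area-fill",               TRUE,  FALSE, "unit",
    "main_ellipse_border_fill",     "border-fill",             TRUE,  FALSE, "unit",
    "inner_ellipse_length",         "inner-ellipse-dim",       FALSE, FALSE, "dimensional",
    "inner_ellipse_width",          "inner-ellipse-dim",       FALSE, FALSE, "dimensional",
    "inner_ellipse_colour",         "colour",                  FALSE, TRUE,  "unit",
    "inner_ellipse_area_fill",      "area-fill",               TRUE,  FALSE, "unit",
    "inner_subcircle_count",        "subcircle-count",         FALSE, FALSE, "count",
    "perinuclear_ellipse_length",   "perinuclear-ellipse-dim", FALSE, FALSE, "dimensional",
    "perinuclear_ellipse_width",    "perinuclear-ellipse-dim", FALSE, FALSE, "dimensional",
    "perinuclear_ellipse_colour",   "colour",                  FALSE, TRUE,  "unit",
    "perinuclear_ellipse_area_fill","area-fill",               TRUE,  FALSE, "unit",
    "protrusion",                   "protrusion",              FALSE, FALSE, "unit",
    "spikes_fraction",              "spikes-fraction",         TRUE,  FALSE, "unit",
    "spikes_height",                "spikes-height",           FALSE, FALSE, "unit",
    "membrane_process",             "membrane-process",        FALSE, FALSE, "unit",
    "line_organelle",               "organelle-line",          TRUE,  FALSE, "unit",
    "ellipse_organelle",            "organelle-ellipse",       TRUE,  FALSE, "unit",
    "rectangle_organelle",          "organelle-rectangle",     TRUE,  FALSE, "unit"
  )
  reg
}

# Dimensional families come in length/width pairs that must be bound together
# so that the joint 0.1-1 scaling can preserve aspect ratios.
dimensional_pairs <- function() {
  list(
    c("main_ellipse_length", "main_ellipse_width"),
    c("inner_ellipse_length", "inner_ellipse_width"),
    c("perinuclear_ellipse_length", "perinuclear_ellipse_width")
  )
}
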