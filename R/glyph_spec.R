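#' Build and validate a glyph specification
#'
#' A glyph spec maps feature names (columns of a feature table) to visual
#' elements of the registry (see [element_registry()]). Validation enforces:
#' every binding references a known element and a known feature; no element is
#' bound twice; no feature is bound to two elements; and the length/width of
#' each ellipse are bound together or not at all (they are scaled jointly, so
#' one without the other is meaningless).
#'
#' @param bindings Named character vector or named list: names are feature
#'   names, values are element names.
#' @param data Optional data frame whose columns the bindings must reference.
#'   Unbound columns are ignored with a warning.
#' @param palette Optional named list of style overrides per element
#'   (e.g. `list(main_ellipse_area_fill = list(colour = "grey30"))`).
#' @param legend_labels Optional named character vector mapping feature names
#'   to display labels for the automatic legend; defaults to feature names.
#' @return An object of class `glyph_spec`: a list with a `bindings` tibble
#'   (columns `feature`, `element`, `label`), `palette`, and the registry rows
#'   of the bound elements.
#' @examples
#' spec <- glyph_spec(c(len = "main_ellipse_length", wid = "main_ellipse_width"))
#' spec
#' @export
glyph_spec <- function(bindings, data = NULL, palette = list(),
                       legend_labels = NULL) {
  bindings <- unlist(bindings)
  if (is.null(names(bindings)) || any(!nzchar(names(bindings)))) {
    stop("`bindings` must be named: names are feature names, values element names.",
         call. = FALSE)
  }
  reg <- element_registry()
  feats <- names(bindings)
  elems <- unname(bindings)

  unknown_elem <- setdiff(elems, reg$element)
  if (length(unknown_elem)) {
    stop("Unknown element name(s): ", paste(unknown_elem, collapse = ", "),
         ". See element_registry().", call. = FALSE)
  }
  dup_elem <- unique(elems[duplicated(elems)])
  if (length(dup_elem)) {
    offenders <- vapply(dup_elem, function(e)
      paste0(e, " <- {", paste(feats[elems == e], collapse = ", "), "}"), "")
    stop("Element(s) bound more than once: ",
         paste(offenders, collapse = "; "), call. = FALSE)
  }
  dup_feat <- unique(feats[duplicated(feats)])
  if (length(dup_feat)) {
    stop("Feature(s) bound to more than one element: ",
         paste(dup_feat, collapse = ", "), call. = FALSE)
  }
  for (pair in dimensional_pairs()) {
    have <- pair %in% elems
    if (xor(have[1], have[2])) {
      stop("Dimensional elements must be bound as a length/width pair: ",
           pair[which(have)], " is bound but ", pair[which(!have)],
           " is not.", call. = FALSE)
    }
  }
  if (!is.null(data)) {
    missing_feat <- setdiff(feats, names(data))
    if (length(missing_feat)) {
      stop("Bound feature(s) not present in `data`: ",
           paste(missing_feat, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(data), c(feats, attr(data, "id_col"), "row_id"))
    if (length(extra)) {
      warning("Ignoring unbound column(s): ", paste(extra, collapse = ", "),
              call. = FALSE)
    }
  }
  labels <- feats
  if (!is.null(legend_labels)) {
    idx <- match(names(legend_labels), feats)
    labels[idx[!is.na(idx)]] <- unname(legend_labels)[!is.na(idx)]
  }
  structure(
    list(
      bindings = tibble::tibble(feature = feats, element = elems, label = labels),
      palette = palette,
      registry = reg[match(elems, reg$element), ]
    ),
    class = "glyph_spec"
  )
}

#' @export
print.glyph_spec <- function(x, ...) {
  cat("<glyph_spec> ", nrow(x$bindings), " binding(s)\n", sep = "")
  print(x$bindings, n = Inf)
  invisible(x)
}

#' Feature names bound to dimensional (jointly scaled) elements
#' @param spec A `glyph_spec`.
#' @return Character vector of feature names.
#' @export
dimensional_features <- function(spec) {
  stopifnot(inherits(spec, "glyph_spec"))
  spec$bindings$feature[spec$registry$domain == "dimensional"]
}

#' Read a glyph spec from a YAML config file
#'
#' The config maps feature names to element names, with optional `palette`
#' and `legend_labels` blocks:
#' ```yaml
#' bindings:
#'   cell_length: main_ellipse_length
#'   cell_width:  main_ellipse_width
#' palette:
#'   main_ellipse_area_fill: {colour: grey30}
#' legend_labels:
#'   cell_length: "Cell length"
#' ```
#' A flat file without a `bindings:` block is read as bindings only.
#'
#' @param path Path to the YAML file.
#' @param data Optional data frame for validation, as in [glyph_spec()].
#' @return A validated `glyph_spec`.
#' @export
read_glyph_spec <- function(path, data = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("Malformed glyph-spec config: ", path, call. = FALSE)
  if (is.null(cfg$bindings)) {
    bindings <- cfg
    palette <- list(); labels <- NULL
  } else {
    bindings <- cfg$bindings
    palette <- cfg$palette %||% list()
    labels <- if (is.null(cfg$legend_labels)) NULL else unlist(cfg$legend_labels)
  }
  glyph_spec(unlist(bindings), data = data, palette = palette,
             legend_labels = labels)
}

#' Write a glyph spec to a YAML config file
#' @param spec A `glyph_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_glyph_spec <- function(spec, path) {
  stopifnot(inherits(spec, "glyph_spec"))
  cfg <- list(
    bindings = as.list(stats::setNames(spec$bindings$element, spec$bindings$feature)),
    palette = spec$palette,
    legend_labels = as.list(stats::setNames(spec$bindings$label, spec$bindings$feature))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' The 15-variable demonstration configuration
#'
#' A ready-made spec binding 15 features to 15 elements: the main ellipse
#' (length, width, area fill, border fill), the inner sub-ellipse (length,
#' width, area fill, colour), the relative protrusion area, spikes (fraction
#' and height), the membrane process, and the three organelle glyphs. Feature
#' names follow the per-cell extraction schema where one exists.
#'
#' @return A validated `glyph_spec` with 15 bindings.
#' @export
demo_spec_15 <- function() {
  glyph_spec(c(
    cell_length         = "main_ellipse_length",
    cell_width          = "main_ellipse_width",
    cell_texture_index  = "main_ellipse_area_fill",
    neighbour_fraction  = "main_ellipse_border_fill",
    nucleus_length      = "inner_ellipse_length",
    nucleus_width       = "inner_ellipse_width",
    nucleus_texture_index = "inner_ellipse_area_fill",
    nucleus_intensity   = "inner_ellipse_colour",
    protrusion_area_rel = "protrusion",
    ruffliness          = "spikes_fraction",
    ruffle_height       = "spikes_height",
    process_length      = "membrane_process",
    marker_a            = "line_organelle",
    marker_b            = "ellipse_organelle",
    marker_c            = "rectangle_organelle"
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
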