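#' The 52-feature per-cell schema
#'
#' Column order of the extraction output: 4 cell morphology + 4 nucleus
#' morphology + neighbour fraction + protrusion area (absolute and
#' relative) + ruffliness, then 20 nuclear-channel texture features on the
#' nucleus region and 20 cell-channel texture features on the cell core
#' (8 SER + 8 Gabor + 4 Haralick each).
#'
#' @return Character vector of the 52 feature names, in order.
#' @export
feature_schema <- function() {
  tex <- c(paste0("ser_", ser_names),
           paste0("gabor_", c(outer(c(0, 45, 90, 135), c(4, 8),
                                    function(o, w) sprintf("o%d_w%d", o, w)))),
           paste0("haralick_", c("asm", "contrast", "correlation", "entropy")))
  c("cell_length", "cell_width", "cell_area", "cell_form_factor",
    "nucleus_length", "nucleus_width", "nucleus_area", "nucleus_form_factor",
    "neighbour_fraction", "protrusion_area", "protrusion_area_rel",
    "ruffliness",
    paste0("nuc_", tex), paste0("cell_", tex))
}

#' Quality-control filter on per-cell records
#'
#' Removes (1) mitotic cells, flagged by mean nuclear intensity above a
#' per-image threshold (default: median + `mitotic_k` times the MAD over
#' the image's cells), (2) small objects below `min_area_px` cell pixels,
#' and (3) cells whose mask touches the image border.
#'
#' @param records Tibble carrying at least `qc_nucleus_intensity`,
#'   `qc_cell_area_px` and `qc_border` columns (as produced by
#'   [extract_feature_table()] with `qc = FALSE`).
#' @param mitotic_k MAD multiplier for the mitotic-intensity threshold; set
#'   `Inf` to disable.
#' @param min_area_px Minimum cell area in pixels.
#' @return The surviving rows, with a `qc_removed` attribute tabulating the
#'   removal reasons.
#' @export
qc_filter <- function(records, mitotic_k = 3, min_area_px = 100) {
  if (nrow(records) == 0) return(records)
  stopifnot(all(c("qc_nucleus_intensity", "qc_cell_area_px", "qc_border")
                %in% names(records)))
  med <- stats::median(records$qc_nucleus_intensity)
  mad <- stats::mad(records$qc_nucleus_intensity)
  mitotic <- if (is.infinite(mitotic_k)) rep(FALSE, nrow(records))
             else records$qc_nucleus_intensity > med + mitotic_k * mad
  small <- records$qc_cell_area_px < min_area_px
  border <- records$qc_border
  keep <- !(mitotic | small | border)
  out <- records[keep, , drop = FALSE]
  attr(out, "qc_removed") <- c(mitotic = sum(mitotic), small = sum(small),
                               border = sum(border))
  out
}

region_textures <- function(mask, channel, ser_maps, gabor_maps) {
  ser <- ser_features(mask, maps = ser_maps)
  gab <- gabor_features(mask, maps = gabor_maps)
  har <- haralick_features(mask, channel)
  c(stats::setNames(ser, paste0("ser_", names(ser))),
    stats::setNames(gab, paste0("gabor_", names(gab))),
    stats::setNames(har, paste0("haralick_", names(har))))
}

prefixed <- function(x, prefix) {
  stats::setNames(as.list(x), paste0(prefix, names(x)))
}

#' Extract the 52-feature table from a two-channel image
#'
#' Runs the full chain: nucleus segmentation on the nuclear channel, seeded
#' cell segmentation on the cell-body channel, per-cell morphology,
#' neighbour fraction, 70%-rule core/protrusion split, ruffliness, and the
#' 20-feature texture suites on the nuclear channel in the nucleus region
#' and on the cell channel in the cell core region, followed by the QC
#' filter. Cells whose feature computation fails (e.g. a nucleus too small
#' for texture) are dropped with a warning rather than aborting the image.
#'
#' @param nuclear Nuclear-stain channel (matrix or EBImage `Image`).
#' @param cell Cell-body channel, same shape.
#' @param pixel_size Pixel edge length in micrometres.
#' @param sigma Smoothing/texture scale in pixels.
#' @param band_width Membrane band width for ruffliness.
#' @param qc Apply [qc_filter()] (mitotic / small / border removal).
#' @param mitotic_k,min_area_px QC parameters, see [qc_filter()].
#' @return A tibble: `cell_id` plus the 52 columns of [feature_schema()]
#'   (and the `qc_*` columns when `qc = FALSE`).
#' @export
extract_feature_table <- function(nuclear, cell, pixel_size = 1, sigma = 2,
                                  band_width = 3L, qc = TRUE, mitotic_k = 3,
                                  min_area_px = 100) {
  nuclear <- as_img_matrix(nuclear)
  cell <- as_img_matrix(cell)
  stopifnot(all(dim(nuclear) == dim(cell)))
  nuc_lab <- segment_nuclei(nuclear)
  cell_lab <- segment_cells(cell, nuc_lab, sigma = sigma)
  ids <- sort(unique(cell_lab[cell_lab > 0]))
  if (!length(ids)) {
    empty <- tibble::as_tibble(stats::setNames(
      as.list(rep(list(numeric(0)), 52)), feature_schema()))
    return(tibble::add_column(empty, cell_id = integer(), .before = 1))
  }
  nf <- neighbour_fraction(cell_lab)
  ser_nuc <- ser_response_maps(nuclear, sigma)
  ser_cell <- ser_response_maps(cell, sigma)
  gab_nuc <- gabor_response_maps(nuclear)
  gab_cell <- gabor_response_maps(cell)
  nr <- nrow(cell_lab); nc <- ncol(cell_lab)

  rows <- list()
  for (id in ids) {
    rec <- tryCatch({
      cmask <- cell_lab == id
      nmask <- nuc_lab == id & cmask
      if (!any(nmask)) stop("cell ", id, " has no matching nucleus")
      cm <- morphology_features(cmask, pixel_size)
      nm <- morphology_features(nmask, pixel_size)
      sp <- split_core_protrusion(cmask, cell)
      ridx <- which(cmask, arr.ind = TRUE)
      border <- any(ridx[, 1] %in% c(1L, nr)) || any(ridx[, 2] %in% c(1L, nc))
      tibble::tibble(
        cell_id = as.integer(id),
        cell_length = cm$length, cell_width = cm$width,
        cell_area = cm$area, cell_form_factor = cm$form_factor,
        nucleus_length = nm$length, nucleus_width = nm$width,
        nucleus_area = nm$area, nucleus_form_factor = nm$form_factor,
        neighbour_fraction =
          nf$neighbour_fraction[match(id, nf$cell_id)],
        protrusion_area = sp$protrusion_area_px * pixel_size^2,
        protrusion_area_rel = sp$protrusion_area_rel,
        ruffliness = ruffliness(cmask, band_width = band_width,
                                maps = ser_cell),
        !!!prefixed(region_textures(nmask, nuclear, ser_nuc, gab_nuc), "nuc_"),
        !!!prefixed(region_textures(sp$core, cell, ser_cell, gab_cell),
                    "cell_"),
        qc_nucleus_intensity = mean(nuclear[nmask]),
        qc_cell_area_px = sum(cmask),
        qc_border = border
      )
    }, error = function(e) {
      warning("Dropping cell ", id, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(out)
  if (qc) {
    out <- qc_filter(out, mitotic_k = mitotic_k, min_area_px = min_area_px)
    out <- out[, c("cell_id", feature_schema())]
  }
  out
}
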