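# Ground-truth generators: synthetic two-channel images with known masks and
# planted feature values, and archetype feature tables with planted cluster
# labels. Both are pure functions of their spec (seed included), so every
# pipeline stage can be tested without external data.

#' Blueprint for one synthetic cell
#'
#' @param centre Length-2 (row, col) centre in pixels.
#' @param cell_axes Length-2 (row, col) semi-axes of the cell ellipse.
#' @param nucleus_axes Length-2 semi-axes of the nucleus ellipse.
#' @param protrusion_rel Planted relative protrusion area in \[0, 1): the
#'   trailing fraction of cell pixels (by column) is rendered at the dim
#'   protrusion intensity, the rest at the core intensity.
#' @param intensity_core,intensity_protrusion Cell-channel plateau
#'   intensities (the protrusion plateau must stay below 70% of the cell
#'   mean for the planted value to be recoverable).
#' @param nucleus_intensity Nuclear-channel plateau.
#' @param texture `"none"`, `"speckle"` (multiplicative uniform speckle) or
#'   `"grating"` (sinusoidal modulation) applied to the cell core.
#' @param texture_amp Texture modulation amplitude.
#' @param touching Allow this cell to share a border with an earlier one.
#' @return A `cell_blueprint` list.
#' @export
cell_blueprint <- function(centre, cell_axes, nucleus_axes,
                           protrusion_rel = 0, intensity_core = 1,
                           intensity_protrusion = 0.25,
                           nucleus_intensity = 1,
                           texture = c("none", "speckle", "grating"),
                           texture_amp = 0.3, touching = FALSE) {
  structure(list(centre = centre, cell_axes = cell_axes,
                 nucleus_axes = nucleus_axes,
                 protrusion_rel = protrusion_rel,
                 intensity_core = intensity_core,
                 intensity_protrusion = intensity_protrusion,
                 nucleus_intensity = nucleus_intensity,
                 texture = match.arg(texture), texture_amp = texture_amp,
                 touching = touching),
            class = "cell_blueprint")
}

ellipse_mask <- function(dim, centre, axes) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c_ <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ((r - centre[1]) / axes[1])^2 + ((c_ - centre[2]) / axes[2])^2 <= 1
}

#' Render a synthetic two-channel cell image with ground truth
#'
#' Cells are axis-aligned ellipses with a bright core plateau and an
#' optional dim protrusion plateau occupying a planted fraction of the cell
#' area (split along the column axis); nuclei are interior ellipses on the
#' nuclear channel. Optional core texture and Gaussian pixel noise are
#' seeded and fully reproducible.
#'
#' @param cells List of [cell_blueprint()]s.
#' @param canvas Length-2 (rows, cols) canvas size in pixels.
#' @param noise_sd Gaussian noise sd added to both channels.
#' @param seed Integer seed; the same spec always renders identical pixels.
#' @return A list with `nuclear` and `cell` intensity matrices, `cell_labels`
#'   and `nucleus_labels` ground-truth label matrices, and `truth`, a tibble
#'   of per-cell planted values (`cell_id`, `protrusion_area_rel`,
#'   `neighbour_fraction`, `cell_area_px`, `nucleus_area_px`, `border`).
#' @export
synth_cell_image <- function(cells, canvas = c(256, 256), noise_sd = 0,
                             seed = 1) {
  stopifnot(length(canvas) == 2, length(cells) >= 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  nuclear <- matrix(0, canvas[1], canvas[2])
  chan <- matrix(0, canvas[1], canvas[2])
  cell_lab <- matrix(0L, canvas[1], canvas[2])
  nuc_lab <- matrix(0L, canvas[1], canvas[2])
  truth <- list()
  for (i in seq_along(cells)) {
    bp <- cells[[i]]
    m <- ellipse_mask(canvas, bp$centre, bp$cell_axes)
    overlap <- m & cell_lab > 0
    if (any(overlap)) {
      if (!bp$touching) {
        stop("Blueprint ", i, " overlaps an earlier cell without ",
             "`touching = TRUE`.", call. = FALSE)
      }
      m <- m & !(cell_lab > 0)   # first cell keeps contested pixels
    }
    # protrusion = trailing fraction of the cell, split along the column
    # axis, exact to one pixel: order pixels by column (then row) and peel
    # off the last round(p * n) as protrusion
    core <- m
    if (bp$protrusion_rel > 0) {
      idx <- which(m, arr.ind = TRUE)
      ord <- order(idx[, 2], idx[, 1])
      n_prot <- round(bp$protrusion_rel * nrow(idx))
      if (n_prot > 0) {
        tail_idx <- idx[ord[(nrow(idx) - n_prot + 1):nrow(idx)], ,
                        drop = FALSE]
        core[cbind(tail_idx[, 1], tail_idx[, 2])] <- FALSE
      }
    }
    intens <- matrix(0, canvas[1], canvas[2])
    intens[m] <- bp$intensity_protrusion
    intens[core] <- bp$intensity_core
    if (bp$texture == "speckle") {
      sp <- matrix(stats::runif(prod(canvas), -1, 1), canvas[1], canvas[2])
      intens[core] <- intens[core] * (1 + bp$texture_amp * sp[core])
    } else if (bp$texture == "grating") {
      gr <- sin(2 * pi * matrix(seq_len(canvas[2]), canvas[1], canvas[2],
                                byrow = TRUE) / 8)
      intens[core] <- intens[core] * (1 + bp$texture_amp * gr[core])
    }
    chan <- pmax(chan, intens)
    nm <- ellipse_mask(canvas, bp$centre, bp$nucleus_axes) & core
    nuclear[nm] <- bp$nucleus_intensity
    cell_lab[m] <- i
    nuc_lab[nm] <- i
    ridx <- which(m, arr.ind = TRUE)
    truth[[i]] <- tibble::tibble(
      cell_id = i,
      protrusion_area_rel = sum(m & !core) / sum(m),
      cell_area_px = sum(m), nucleus_area_px = sum(nm),
      border = any(ridx[, 1] %in% c(1L, canvas[1])) ||
               any(ridx[, 2] %in% c(1L, canvas[2]))
    )
  }
  nf <- neighbour_fraction(cell_lab)
  truth <- dplyr::bind_rows(truth)
  if (nrow(truth)) {
    truth$neighbour_fraction <-
      nf$neighbour_fraction[match(truth$cell_id, nf$cell_id)]
    truth$neighbour_fraction[is.na(truth$neighbour_fraction)] <- 0
  }
  if (noise_sd > 0) {
    nuclear <- pmax(nuclear + matrix(stats::rnorm(prod(canvas), 0, noise_sd),
                                     canvas[1]), 0)
    chan <- pmax(chan + matrix(stats::rnorm(prod(canvas), 0, noise_sd),
                               canvas[1]), 0)
  }
  list(nuclear = nuclear, cell = chan, cell_labels = cell_lab,
       nucleus_labels = nuc_lab, truth = truth)
}

#' A standard 5-cell demonstration image
#'
#' Five well-separated cells on a 256x256 canvas covering the main
#' phenotype axes: a plain round cell, a protrusive cell (planted relative
#' protrusion area 0.2), a speckle-textured cell, a grating-textured cell,
#' and an elongated cell. Used by the examples and the demonstration run.
#'
#' @param seed Integer seed.
#' @param noise_sd Gaussian pixel noise sd.
#' @return As [synth_cell_image()].
#' @export
demo_image_5 <- function(seed = 1, noise_sd = 0.01) {
  synth_cell_image(
    cells = list(
      cell_blueprint(c(48, 52), c(22, 24), c(10, 11)),
      cell_blueprint(c(52, 150), c(20, 42), c(9, 12), protrusion_rel = 0.2),
      cell_blueprint(c(150, 48), c(26, 26), c(11, 11), texture = "speckle",
                     texture_amp = 0.2),
      cell_blueprint(c(208, 150), c(24, 30), c(10, 12), texture = "grating",
                     texture_amp = 0.2),
      cell_blueprint(c(140, 208), c(34, 14), c(12, 8))
    ),
    canvas = c(256, 256), noise_sd = noise_sd, seed = seed
  )
}

#' The five morphology archetypes
#'
#' Mean vectors over the nine plotted features for five synthetic phenotype
#' archetypes: (1) round, poorly spread, high neighbour fraction, low
#' texture, no protrusions; (2) spread, ruffly, protrusive, highly
#' textured, low NF; (3) spread and smooth with moderate NF; (4)
#' intermediate between 1 and 2 but the most textured; (5) like 3 but more
#' compact. Lengths/widths are in micrometres; fractions and indices on
#' \[0,1\].
#'
#' @return A tibble: `archetype` plus the 9 feature columns.
#' @export
archetype_means <- function() {
  tibble::tribble(
    ~archetype, ~cell_length, ~cell_width, ~nucleus_length, ~nucleus_width,
    ~protrusion_area_rel, ~neighbour_fraction, ~ruffliness,
    ~cell_texture_index, ~nucleus_texture_index,
    1L, 28, 24, 14, 12, 0.03, 0.60, 0.15, 0.25, 0.15,
    2L, 85, 45, 22, 16, 0.45, 0.10, 0.90, 0.80, 0.80,
    3L, 80, 50, 22, 17, 0.15, 0.35, 0.30, 0.40, 0.40,
    4L, 55, 35, 18, 14, 0.25, 0.30, 0.55, 0.95, 0.90,
    5L, 60, 38, 19, 15, 0.12, 0.42, 0.28, 0.35, 0.35
  )
}

#' Draw a synthetic feature table around the archetype means
#'
#' Independent Gaussian draws per feature around each archetype mean, with
#' per-feature sd equal to `sd_frac` times that feature's range across the
#' archetypes, clipped to valid domains (positive lengths, \[0,1\]
#' fractions). Planted labels are returned for clustering benchmarks.
#'
#' @param n_per Samples per archetype.
#' @param sd_frac Noise sd as a fraction of the across-archetype range of
#'   each feature.
#' @param seed Integer seed.
#' @param means Archetype mean table, defaults to [archetype_means()].
#' @return A tibble with `sample_id`, `archetype` (planted label) and the 9
#'   feature columns.
#' @export
synth_feature_table <- function(n_per = 20, sd_frac = 0.10, seed = 1,
                                means = archetype_means()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  feats <- setdiff(names(means), "archetype")
  rngs <- vapply(means[feats], function(v) diff(range(v)), numeric(1))
  unit_feats <- c("protrusion_area_rel", "neighbour_fraction",
                  "cell_texture_index", "nucleus_texture_index")
  rows <- purrr::map(seq_len(nrow(means)), function(i) {
    draws <- purrr::map(feats, function(f) {
      v <- stats::rnorm(n_per, means[[f]][i], sd_frac * rngs[[f]])
      v <- pmax(v, 0)
      if (f %in% unit_feats) v <- pmin(v, 1)
      v
    })
    tibble::as_tibble(stats::setNames(draws, feats)) |>
      tibble::add_column(archetype = means$archetype[i], .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  tibble::add_column(out, sample_id = seq_len(nrow(out)), .before = 1)
}
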