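# Segmentation and per-object morphology. EBImage provides the standard
# primitives (Gaussian blur, Otsu threshold, distance-map watershed, seeded
# Voronoi propagation); the quantities layered on top — neighbour fraction,
# the 70%-of-mean core/protrusion split, ruffliness — are computed here.

as_img_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Segment nuclei from the nuclear-stain channel
#'
#' Global Otsu threshold (class-mean midpoint), morphological opening and
#' hole filling, then a distance-transform watershed to split touching
#' nuclei.
#'
#' @param img 2D numeric matrix (or EBImage `Image`) of nuclear-stain
#'   intensities.
#' @param min_px Connected components smaller than this are discarded as
#'   debris before watershed.
#' @return Integer label matrix (0 = background, labels contiguous from 1).
#' @export
segment_nuclei <- function(img, min_px = 9L) {
  img <- as_img_matrix(img)
  if (length(img) == 0 || max(img) == min(img)) {
    return(matrix(0L, nrow(img), ncol(img)))
  }
  # Threshold the raw channel at the Otsu class-mean midpoint (the correct
  # edge position for a step profile); a morphological opening absorbs
  # noise that smoothing would otherwise be needed for, without the
  # boundary shift blurring causes on small nuclei.
  bw <- img > otsu_vec(as.vector(img))
  bw <- EBImage::opening(EBImage::Image(bw * 1), EBImage::makeBrush(3, "box"))
  bw <- as_img_matrix(EBImage::fillHull(bw)) > 0
  cc <- as_img_matrix(EBImage::bwlabel(EBImage::Image(bw)))
  sizes <- tabulate(cc[cc > 0])
  small <- which(sizes < min_px)
  bw[cc %in% small & cc > 0] <- FALSE
  if (!any(bw)) return(matrix(0L, nrow(img), ncol(img)))
  dm <- EBImage::distmap(EBImage::Image(bw))
  lab <- as_img_matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  relabel_contiguous(lab)
}

#' Segment cell bodies seeded by nuclei
#'
#' Seeded region growing (Voronoi propagation on the intensity landscape) on
#' the cell-body channel, constrained to the foreground mask and seeded by
#' the nucleus labels, so every cell contains its nucleus and touching cells
#' partition the shared foreground.
#'
#' @param img Cell-body channel (matrix or `Image`).
#' @param nuclei Integer label matrix from [segment_nuclei()], same shape.
#' @param sigma Smoothing scale in pixels.
#' @return Integer label matrix; labels match the seeding nucleus labels.
#' @export
segment_cells <- function(img, nuclei, sigma = 2) {
  img <- as_img_matrix(img)
  nuclei <- as_img_matrix(nuclei)
  stopifnot(all(dim(img) == dim(nuclei)))
  if (max(nuclei) == 0) return(matrix(0L, nrow(img), ncol(img)))
  sm <- as_img_matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  # Foreground mask by hysteresis thresholding of the unsmoothed image:
  # the strong (Otsu) cut finds bright cell cores, a weak cut (Otsu of the
  # sub-threshold population, separating dim cytoplasm from background)
  # extends each core into its dim protrusions, and weak pixels are kept
  # only in components that contain strong pixels, so background noise is
  # not promoted. Thresholding the raw image keeps plateau boundaries in
  # place; a morphological opening removes speckle noise.
  rng <- range(img)
  mask <- if (diff(rng) == 0) nuclei > 0 else {
    x <- (img - rng[1]) / diff(rng)
    t_hi <- otsu_vec(as.vector(x))
    strong <- x > t_hi
    sub <- x[x <= t_hi]
    t_lo <- if (length(unique(sub)) > 1) otsu_vec(sub) else t_hi
    weak <- x > min(t_lo, t_hi)
    cc <- as_img_matrix(EBImage::bwlabel(EBImage::Image(weak)))
    keep_ids <- unique(cc[strong & cc > 0])
    raw <- matrix(cc %in% keep_ids & cc > 0, nrow(x), ncol(x))
    raw <- EBImage::opening(EBImage::Image(raw * 1),
                            EBImage::makeBrush(3, "box"))
    raw <- as_img_matrix(EBImage::fillHull(raw)) > 0
    raw | nuclei > 0
  }
  lab <- EBImage::propagate(EBImage::Image(sm), seeds = EBImage::Image(nuclei),
                            mask = mask, lambda = 1e-4)
  lab <- as_img_matrix(lab)
  storage.mode(lab) <- "integer"
  lab
}

# Otsu threshold of a numeric vector on a 256-bin histogram; returns the
# cut maximising between-class variance, at the class-mean midpoint.
otsu_vec <- function(v, bins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  x <- (v - rng[1]) / diff(rng)
  h <- tabulate(pmin(as.integer(x * bins) + 1L, bins), bins)
  p <- h / sum(h)
  mids <- (seq_len(bins) - 0.5) / bins
  cw <- cumsum(p); cm <- cumsum(p * mids)
  total_m <- cm[bins]
  w0 <- cw[-bins]; m0 <- cm[-bins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, bins - 1L)
  bc[ok] <- (total_m * w0[ok] - m0[ok])^2 / (w0[ok] * w1[ok])
  t <- which.max(bc)
  mu0 <- cm[t] / cw[t]; mu1 <- (total_m - cm[t]) / (1 - cw[t])
  rng[1] + (mu0 + mu1) / 2 * diff(rng)
}

relabel_contiguous <- function(lab) {
  lab <- as_img_matrix(lab)
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

#' Morphology of a single object mask
#'
#' Length and width are the major and minor axes of the second-moment
#' best-fit ellipse (4 times the square roots of the coordinate-covariance
#' eigenvalues). The perimeter is the length of the outer-contour polygon
#' (subsampled to suppress pixel staircase), and the form factor is
#' `4 * pi * area / perimeter^2` — 1 for a circle, smaller for irregular
#' shapes.
#'
#' @param mask Logical matrix, one object.
#' @param pixel_size Pixel edge length in micrometres.
#' @return A tibble with columns `length`, `width`, `area`, `form_factor`
#'   (lengths in micrometres, area in square micrometres).
#' @export
morphology_features <- function(mask, pixel_size = 1) {
  mask <- as_img_matrix(mask) > 0
  n <- sum(mask)
  if (n == 0) stop("Empty mask.", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  if (n < 3) {
    return(tibble::tibble(length = pixel_size, width = pixel_size,
                          area = n * pixel_size^2, form_factor = 1))
  }
  cv <- stats::cov(idx)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 1e-12)
  tibble::tibble(
    length = 4 * sqrt(ev[1]) * pixel_size,
    width = 4 * sqrt(ev[2]) * pixel_size,
    area = n * pixel_size^2,
    form_factor = 4 * pi * n / mask_perimeter(mask)^2
  )
}

# Outer-contour perimeter in pixels. The 8-connected contour through pixel
# centres overestimates smooth boundaries (staircase); subsampling every
# third vertex before measuring the polygon recovers smooth perimeters to
# within a few percent.
mask_perimeter <- function(mask, step = 3L) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) return(4)
  per <- 0
  for (ct in oc) {
    if (nrow(ct) < 4) { per <- per + max(nrow(ct), 1); next }
    keep <- seq(1, nrow(ct), by = step)
    pts <- ct[keep, , drop = FALSE]
    per <- per + sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)))
  }
  max(per, 4)
}

#' Neighbour fraction per cell
#'
#' The fraction of a cell's border pixels whose 8-neighbourhood contains a
#' different positive label — i.e. the fraction of the cell border in
#' contact with other cells. Border pixels are object pixels with at least
#' one 8-neighbour outside the object (background, another cell, or off the
#' image).
#'
#' @param labels Integer label matrix of segmented cells.
#' @return A tibble with columns `cell_id`, `neighbour_fraction`.
#' @export
neighbour_fraction <- function(labels) {
  labels <- as_img_matrix(labels)
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    return(tibble::tibble(cell_id = integer(), neighbour_fraction = numeric()))
  }
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  is_border <- matrix(FALSE, nr, nc)
  touches_other <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
    is_border <- is_border | (nb != ctr)
    touches_other <- touches_other | (nb != ctr & nb > 0)
  }
  obj <- ctr > 0
  border_n <- tapply(is_border[obj], ctr[obj], sum)
  contact_n <- tapply((is_border & touches_other)[obj], ctr[obj], sum)
  tibble::tibble(
    cell_id = as.integer(names(border_n)),
    neighbour_fraction = as.numeric(contact_n) / pmax(as.numeric(border_n), 1)
  )
}

#' Split a cell into core and protrusion by the 70%-of-mean rule
#'
#' The threshold is 70% of the mean cell-body intensity over the cell mask.
#' The cell core is the largest connected component of above-threshold
#' pixels; everything else in the cell is protrusion. The relative
#' protrusion area is the protrusion pixel count over the cell pixel count.
#'
#' @param mask Logical matrix, the cell mask.
#' @param channel Cell-body intensity matrix.
#' @param core_fraction Threshold as a fraction of the mean intensity.
#' @return List with `core` and `protrusion` logical masks,
#'   `protrusion_area_px`, and `protrusion_area_rel` in \[0,1\].
#' @export
split_core_protrusion <- function(mask, channel, core_fraction = 0.7) {
  mask <- as_img_matrix(mask) > 0
  channel <- as_img_matrix(channel)
  stopifnot(all(dim(mask) == dim(channel)))
  n <- sum(mask)
  if (n == 0) stop("Empty cell mask.", call. = FALSE)
  thr <- core_fraction * mean(channel[mask])
  above <- mask & (channel > thr)
  if (!any(above)) {
    warning("No pixels above the core threshold; treating the whole cell ",
            "as core.", call. = FALSE)
    core <- mask
  } else {
    cc <- as_img_matrix(EBImage::bwlabel(EBImage::Image(above)))
    sizes <- tabulate(cc[cc > 0])
    core <- cc == which.max(sizes)
  }
  protrusion <- mask & !core
  list(core = core, protrusion = protrusion,
       protrusion_area_px = sum(protrusion),
       protrusion_area_rel = sum(protrusion) / n)
}
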