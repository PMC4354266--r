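# Texture suites. 20 features per region-channel: 8 SER (spots/edges/ridges
# family, from scale-normalized Gaussian-derivative responses), 8 Gabor
# (4 orientations x 2 wavelengths), 4 Haralick (GLCM statistics).

MIN_TEXTURE_PX <- 25L

gauss_kernels_1d <- function(sigma) {
  r <- ceiling(4 * sigma)
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -x / sigma^2 * g                       # d/dx
  g2 <- (x^2 / sigma^2 - 1) / sigma^2 * g      # d2/dx2
  g2 <- g2 - sum(g2) / length(g2)              # truncation leaves a DC leak
  list(g = g, g1 = g1, g2 = g2)
}

conv_sep <- function(img, krow, kcol) {
  k <- outer(krow, kcol)
  as_img_matrix(EBImage::filter2(EBImage::Image(img), k,
                                 boundary = "replicate"))
}

# Pixelwise scale-normalized derivative responses at a single scale sigma.
# Rows are y, columns are x.
ser_response_maps <- function(channel, sigma = 2) {
  img <- as_img_matrix(channel)
  kk <- gauss_kernels_1d(sigma)
  Ls  <- conv_sep(img, kk$g, kk$g)
  Lx  <- conv_sep(img, kk$g, kk$g1)
  Ly  <- conv_sep(img, kk$g1, kk$g)
  Lxx <- conv_sep(img, kk$g, kk$g2)
  Lyy <- conv_sep(img, kk$g2, kk$g)
  Lxy <- conv_sep(img, kk$g1, kk$g1)
  grad <- sqrt(Lx^2 + Ly^2)
  tr2 <- (Lxx + Lyy) / 2
  dsc <- sqrt(((Lxx - Lyy) / 2)^2 + Lxy^2)
  l1 <- tr2 + dsc   # larger Hessian eigenvalue
  l2 <- tr2 - dsc   # smaller
  s2 <- sigma^2
  lap <- Lxx + Lyy
  list(
    smooth = Ls,
    edge   = sigma * grad,
    # scale-normalized Laplacian (the classic blob detector) gated to
    # pixels where the Hessian is negative/positive definite
    spot   = s2 * pmax(0, -lap) * (l1 < 0),
    hole   = s2 * pmax(0, lap) * (l2 > 0),
    ridge  = s2 * pmax(0, -l2 - pmax(0, -l1)),       # bright line beyond blob
    valley = s2 * pmax(0, l1 - pmax(0, l2)),         # dark line beyond blob
    saddle = s2 * pmax(0, pmin(l1, -l2))             # mixed-sign curvature
  )
}

ser_names <- c("spot", "hole", "edge", "ridge", "valley", "saddle",
               "bright", "dark")

#' SER texture features of a region
#'
#' Eight spot/edge/ridge-family texture features from Gaussian-derivative
#' filter responses at a single scale, averaged over the region: `spot`,
#' `hole` (dark spot), `edge` (gradient magnitude), `ridge` (bright line),
#' `valley` (dark line), `saddle` (mixed curvature), and `bright`/`dark`
#' (mean positive/negative deviation of the smoothed intensity from the
#' region mean). Derivatives are scale-normalized (gradient by sigma,
#' curvature by sigma squared), so responses are comparable across feature
#' types; all eight vanish on a constant region.
#'
#' @param mask Logical matrix, the region.
#' @param channel Intensity matrix, same shape.
#' @param sigma Filter scale in pixels.
#' @param maps Precomputed [ser_response_maps] output (internal fast path).
#' @return Named numeric vector of the 8 features.
#' @export
ser_features <- function(mask, channel = NULL, sigma = 2, maps = NULL) {
  mask <- as_img_matrix(mask) > 0
  if (sum(mask) < MIN_TEXTURE_PX) {
    stop("Region too small for texture features (", sum(mask), " px < ",
         MIN_TEXTURE_PX, ").", call. = FALSE)
  }
  if (is.null(maps)) maps <- ser_response_maps(channel, sigma)
  dev <- maps$smooth[mask] - mean(maps$smooth[mask])
  c(spot   = mean(maps$spot[mask]),
    hole   = mean(maps$hole[mask]),
    edge   = mean(maps$edge[mask]),
    ridge  = mean(maps$ridge[mask]),
    valley = mean(maps$valley[mask]),
    saddle = mean(maps$saddle[mask]),
    bright = mean(pmax(0, dev)),
    dark   = mean(pmax(0, -dev)))
}

gabor_kernel <- function(wavelength, theta_deg, sigma = 0.56 * wavelength,
                         gamma = 1) {
  r <- ceiling(3 * sigma)
  # first grid index = image rows, second = columns; theta 0 puts the
  # carrier along the column (x) axis
  xy <- expand.grid(y = (-r):r, x = (-r):r)
  th <- theta_deg * pi / 180
  xp <- xy$x * cos(th) + xy$y * sin(th)
  yp <- -xy$x * sin(th) + xy$y * cos(th)
  env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
  re <- env * cos(2 * pi * xp / wavelength)
  im <- env * sin(2 * pi * xp / wavelength)
  re <- re - env * sum(re) / sum(env)   # remove DC so constant regions -> 0
  nrm <- sqrt(sum(re^2 + im^2))
  side <- 2 * r + 1
  list(re = matrix(re / nrm, side, side),
       im = matrix(im / nrm, side, side))
}

gabor_response_maps <- function(channel, wavelengths = c(4, 8),
                                orientations = c(0, 45, 90, 135)) {
  img <- as_img_matrix(channel)
  maps <- list()
  for (w in wavelengths) for (o in orientations) {
    k <- gabor_kernel(w, o)
    re <- as_img_matrix(EBImage::filter2(EBImage::Image(img), k$re,
                                         boundary = "replicate"))
    im <- as_img_matrix(EBImage::filter2(EBImage::Image(img), k$im,
                                         boundary = "replicate"))
    maps[[sprintf("o%d_w%d", o, w)]] <- re^2 + im^2
  }
  maps
}

#' Gabor texture features of a region
#'
#' Mean squared response magnitude of a DC-free Gabor filter bank (4
#' orientations at 0/45/90/135 degrees, 2 wavelengths of 4 and 8 px),
#' averaged over the region: 8 features. Rotating the image by 90 degrees
#' permutes the orientation features and leaves the wavelength pairing
#' intact.
#'
#' @inheritParams ser_features
#' @param wavelengths,orientations Filter-bank parameters.
#' @return Named numeric vector of the 8 features (`o<deg>_w<px>`).
#' @export
gabor_features <- function(mask, channel = NULL, wavelengths = c(4, 8),
                           orientations = c(0, 45, 90, 135), maps = NULL) {
  mask <- as_img_matrix(mask) > 0
  if (sum(mask) < MIN_TEXTURE_PX) {
    stop("Region too small for texture features (", sum(mask), " px < ",
         MIN_TEXTURE_PX, ").", call. = FALSE)
  }
  if (is.null(maps)) maps <- gabor_response_maps(channel, wavelengths,
                                                 orientations)
  vapply(maps, function(m) mean(m[mask]), numeric(1))
}

#' Haralick texture features of a region
#'
#' Grey-level co-occurrence statistics: the region's intensities are min-max
#' binned into `levels` grey levels, co-occurrences are counted at distance
#' 1 in each of the 4 directions (symmetrically), and the four features —
#' angular second moment, contrast, correlation, entropy (base-2) — are
#' computed per direction and averaged. A constant region yields ASM 1,
#' contrast 0, entropy 0 (correlation is defined as 0 there).
#'
#' @inheritParams ser_features
#' @param levels Number of grey levels for binning.
#' @return Named numeric vector: `asm`, `contrast`, `correlation`, `entropy`.
#' @export
haralick_features <- function(mask, channel, levels = 32L) {
  mask <- as_img_matrix(mask) > 0
  channel <- as_img_matrix(channel)
  if (sum(mask) < MIN_TEXTURE_PX) {
    stop("Region too small for texture features (", sum(mask), " px < ",
         MIN_TEXTURE_PX, ").", call. = FALSE)
  }
  vals <- channel[mask]
  rng <- range(vals)
  lev <- matrix(NA_integer_, nrow(channel), ncol(channel))
  lev[mask] <- if (diff(rng) == 0) 0L else {
    pmin(as.integer(floor((vals - rng[1]) / diff(rng) * levels)), levels - 1L)
  }
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  feats <- matrix(0, length(offsets), 4)
  for (oi in seq_along(offsets)) {
    dr <- offsets[[oi]][1]; dc <- offsets[[oi]][2]
    nr <- nrow(lev); nc <- ncol(lev)
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- lev[r1, c1, drop = FALSE]
    b <- lev[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) { feats[oi, ] <- c(NA, NA, NA, NA); next }
    i <- c(a[ok], b[ok]); j <- c(b[ok], a[ok])   # symmetric counts
    p <- as.vector(table(factor(i, 0:(levels - 1L)),
                         factor(j, 0:(levels - 1L))))
    p <- p / sum(p)
    gl <- as.matrix(expand.grid(i = 0:(levels - 1L), j = 0:(levels - 1L)))
    asm <- sum(p^2)
    contrast <- sum((gl[, 1] - gl[, 2])^2 * p)
    mu_i <- sum(gl[, 1] * p); sd_i <- sqrt(sum((gl[, 1] - mu_i)^2 * p))
    correlation <- if (sd_i < 1e-12) 0 else
      sum((gl[, 1] - mu_i) * (gl[, 2] - mu_i) * p) / sd_i^2
    entropy <- -sum(ifelse(p > 0, p * log2(p), 0))
    feats[oi, ] <- c(asm, contrast, correlation, entropy)
  }
  out <- colMeans(feats, na.rm = TRUE)
  names(out) <- c("asm", "contrast", "correlation", "entropy")
  out
}

#' Membrane ruffliness of a cell
#'
#' The SER edge response in the cell membrane — a morphological band of
#' `band_width` pixels inside the cell boundary — divided by the cell form
#' factor. Irregular borders raise the edge response and lower the form
#' factor, so both terms push ruffliness up for ruffled cells.
#'
#' @param mask Logical matrix, the cell mask.
#' @param channel Cell-body intensity matrix.
#' @param band_width Membrane band width in pixels.
#' @param sigma SER filter scale.
#' @param maps Precomputed SER maps (internal fast path).
#' @return Non-negative scalar.
#' @export
ruffliness <- function(mask, channel = NULL, band_width = 3L, sigma = 2,
                       maps = NULL) {
  mask <- as_img_matrix(mask) > 0
  brush <- EBImage::makeBrush(2L * band_width + 1L, shape = "disc")
  eroded <- as_img_matrix(EBImage::erode(EBImage::Image(mask * 1), brush)) > 0
  if (!any(eroded)) {
    warning("Cell thinner than the membrane band; using the whole cell.",
            call. = FALSE)
    band <- mask
  } else {
    band <- mask & !eroded
  }
  if (is.null(maps)) maps <- ser_response_maps(channel, sigma)
  edge <- mean(maps$edge[band])
  ff <- morphology_features(mask)$form_factor
  edge / ff
}
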