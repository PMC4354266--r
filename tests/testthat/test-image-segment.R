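test_that("nucleus segmentation recovers planted blobs", {
  blank <- matrix(0, 64, 64)
  expect_equal(max(segment_nuclei(blank)), 0)

  img <- synth_cell_image(
    cells = list(
      cell_blueprint(c(20, 20), c(9, 9), c(5, 5)),
      cell_blueprint(c(20, 48), c(9, 9), c(5, 5)),
      cell_blueprint(c(48, 34), c(9, 9), c(5, 5))
    ), canvas = c(68, 68), seed = 1)
  lab <- segment_nuclei(img$nuclear)
  expect_equal(max(lab), 3L)
  m <- match_labels(lab, img$nucleus_labels)
  for (j in seq_along(m)) {
    expect_gt(jaccard(lab == j, img$nucleus_labels == m[j]), 0.95)
  }
})

test_that("touching nuclei with distinct cores are split by watershed", {
  img <- matrix(0, 60, 60)
  r <- matrix(1:60, 60, 60); cc <- matrix(1:60, 60, 60, byrow = TRUE)
  blob <- function(cy, cx, rad) (r - cy)^2 + (cc - cx)^2 <= rad^2
  img[blob(30, 22, 9) | blob(30, 40, 9)] <- 1   # overlapping pair of discs
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 2L)
})

test_that("seeded cell segmentation contains nuclei and partitions contact", {
  img <- synth_cell_image(
    cells = list(cell_blueprint(c(32, 32), c(14, 16), c(6, 7))),
    canvas = c(64, 64), seed = 1)
  nl <- segment_nuclei(img$nuclear)
  cl <- segment_cells(img$cell, nl)
  expect_equal(max(cl), 1L)
  expect_true(all(cl[nl > 0] == nl[nl > 0]))   # cell mask contains nucleus
  expect_gt(jaccard(cl == 1, img$cell_labels == 1), 0.95)

  # two nuclei in one connected bright region are partitioned into 2 cells
  touching <- synth_cell_image(
    cells = list(
      cell_blueprint(c(32, 24), c(12, 12), c(5, 5)),
      cell_blueprint(c(32, 46), c(12, 12), c(5, 5), touching = TRUE)
    ), canvas = c(64, 72), seed = 1)
  nl <- segment_nuclei(touching$nuclear)
  cl <- segment_cells(touching$cell, nl)
  expect_equal(max(cl), 2L)
  expect_true(all(cl[nl > 0] == nl[nl > 0]))
  # the full bright region is assigned
  expect_gt(jaccard(cl > 0, touching$cell_labels > 0), 0.95)
  expect_equal(max(segment_cells(touching$cell, matrix(0L, 64, 72))), 0)
})

test_that("morphology matches closed-form shapes", {
  r <- matrix(1:64, 64, 64); cc <- matrix(1:64, 64, 64, byrow = TRUE)
  disc <- (r - 32)^2 + (cc - 32)^2 <= 20^2
  mf <- morphology_features(disc)
  expect_equal(mf$form_factor, 1, tolerance = 0.05)
  expect_equal(mf$length, 40, tolerance = 0.05 * 40)
  expect_equal(mf$area, sum(disc))

  rect <- matrix(FALSE, 60, 60); rect[11:50, 26:35] <- TRUE
  mf <- morphology_features(rect)
  expect_equal(mf$length / mf$width, 4, tolerance = 0.02)

  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  expect_equal(morphology_features(sq, pixel_size = 0.5)$area, 25)
  expect_error(morphology_features(matrix(FALSE, 5, 5)), "Empty")
})

test_that("neighbour fraction matches direct pixel counting", {
  lone <- matrix(0L, 30, 30); lone[10:20, 10:20] <- 1L
  expect_equal(neighbour_fraction(lone)$neighbour_fraction, 0)

  # enclosed object: every border pixel touches the surrounding label
  enc <- matrix(0L, 30, 30); enc[5:25, 5:25] <- 2L; enc[12:18, 12:18] <- 1L
  nf <- neighbour_fraction(enc)
  expect_equal(nf$neighbour_fraction[nf$cell_id == 1], 1)

  # two equal squares sharing one full edge: direct oracle count
  lab <- matrix(0L, 40, 50); lab[11:30, 6:25] <- 1L; lab[11:30, 26:45] <- 2L
  nf <- neighbour_fraction(lab)
  # oracle: border = 4*20-4 = 76 px; contact = 20 edge px + nothing else
  expect_equal(nf$neighbour_fraction, rep(20 / 76, 2))
  expect_equal(nf$neighbour_fraction, rep(0.25, 2), tolerance = 0.06)
})

test_that("the 70% rule splits the two-plateau cell exactly", {
  cell <- two_plateau_cell()
  # mean = (80*100 + 20*10)/100 = 82; threshold 57.4; core = 80 bright px
  sp <- split_core_protrusion(cell$mask, cell$channel)
  expect_equal(sum(sp$core), 80)
  expect_equal(sp$protrusion_area_rel, 0.2)

  # uniform cell has no protrusion
  uni <- two_plateau_cell(n_core = 100, n_prot = 0)
  expect_equal(split_core_protrusion(uni$mask,
                                     uni$channel)$protrusion_area_rel, 0)

  # largest-component rule: two disjoint bright plateaus, 60 vs 20 px
  mask <- matrix(FALSE, 20, 20); channel <- matrix(0, 20, 20)
  mask[1:100] <- TRUE
  channel[1:60] <- 100        # big plateau (cols 1-3)
  channel[61:80] <- 5         # dim gap (col 4)
  channel[81:100] <- 100      # small plateau (col 5)
  sp <- split_core_protrusion(mask, channel)
  expect_equal(sum(sp$core), 60)
  expect_equal(sp$protrusion_area_rel, 0.4)

  # all pixels below threshold falls back to whole-cell core, with warning
  neg <- matrix(-1, 5, 6); m <- matrix(TRUE, 5, 6)
  expect_warning(sp <- split_core_protrusion(m, neg), "whole cell")
  expect_equal(sp$protrusion_area_rel, 0)
})

test_that("70% rule agrees with the brute-force oracle on random cells", {
  set.seed(11)
  for (i in 1:5) {
    mask <- matrix(FALSE, 32, 32)
    mask[sample(1024, 400)] <- TRUE
    # keep a single connected blob: take largest component of the sample
    lab <- oracle_components(mask)
    mask <- lab == which.max(tabulate(lab[lab > 0]))
    channel <- matrix(runif(1024, 0, 100), 32, 32)
    sp <- split_core_protrusion(mask, channel)
    or <- oracle_core_protrusion(mask, channel)
    expect_identical(sp$core, or$core)
    expect_equal(sp$protrusion_area_rel, or$rel)
  }
})

test_that("QC filter removes mitotic, small and border cells", {
  rec <- tibble::tibble(
    cell_id = 1:10,
    qc_nucleus_intensity = c(rep(1, 8), 8, 9),   # 2 mitotic outliers
    qc_cell_area_px = c(50, rep(500, 9)),        # 1 small
    qc_border = c(FALSE, TRUE, rep(FALSE, 8))    # 1 border
  )
  out <- qc_filter(rec)
  expect_equal(nrow(out), 6L)
  expect_false(any(out$cell_id %in% c(1, 2, 9, 10)))
  removed <- attr(out, "qc_removed")
  expect_equal(unname(removed["mitotic"]), 2)
  expect_equal(unname(removed["small"]), 1)
  expect_equal(unname(removed["border"]), 1)
  empty <- rec[0, ]
  expect_equal(nrow(qc_filter(empty)), 0L)
})
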