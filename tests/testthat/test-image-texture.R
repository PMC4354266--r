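make_grid <- function(n = 64) {
  list(r = matrix(1:n, n, n), c = matrix(1:n, n, n, byrow = TRUE))
}

test_that("SER features vanish on constant regions and rank structures", {
  g <- make_grid()
  mask <- (g$r - 32)^2 + (g$c - 32)^2 <= 8^2
  const <- matrix(0.5, 64, 64)
  expect_equal(unname(ser_features(mask, const)), rep(0, 8), tolerance = 1e-10)

  # bright Gaussian blob, mask tight to the blob: spot dominates every
  # other feature, in particular the gradient (edge) response
  blob <- exp(-((g$r - 32)^2 + (g$c - 32)^2) / (2 * 3^2))
  tight <- (g$r - 32)^2 + (g$c - 32)^2 <= 3^2
  f <- ser_features(tight, blob)
  expect_equal(unname(which.max(f)), 1L)  # spot
  expect_gt(f["spot"], 1.5 * f["edge"])
  expect_equal(unname(f["hole"]), 0, tolerance = 1e-8)
  # dark blob: hole dominates spot
  fd <- ser_features(tight, 1 - blob)
  expect_gt(fd["hole"], fd["spot"])

  # vertical step edge: edge is the largest Gaussian-derivative feature
  step <- matrix(0, 64, 64); step[, 33:64] <- 1
  mask8 <- (g$r - 32)^2 + (g$c - 32)^2 <= 8^2
  fs <- ser_features(mask8, step)
  deriv <- fs[c("spot", "hole", "edge", "ridge", "valley", "saddle")]
  expect_equal(names(which.max(deriv)), "edge")

  expect_error(ser_features(mask8[1:4, 1:4] & FALSE, const), "too small")
})

test_that("SER responses are linear in intensity and translation invariant", {
  g <- make_grid()
  set.seed(5)
  tex <- matrix(runif(64 * 64), 64, 64)
  mask <- (g$r - 24)^2 + (g$c - 24)^2 <= 7^2
  f1 <- ser_features(mask, tex)
  f3 <- ser_features(mask, 3 * tex)
  expect_equal(unname(f3[1:6]), unname(3 * f1[1:6]), tolerance = 1e-9)

  # translate region + image content together: derivative features move with
  # them (interior translation, away from boundary effects)
  sh <- 10L
  tex2 <- matrix(0, 64, 64); tex2[, (1 + sh):64] <- tex[, 1:(64 - sh)]
  mask2 <- (g$r - 24)^2 + (g$c - 24 - sh)^2 <= 7^2
  f2 <- ser_features(mask2, tex2)
  expect_equal(unname(f2), unname(f1), tolerance = 1e-6)
})

test_that("Gabor bank is tuned to wavelength and orientation", {
  g <- make_grid()
  mask <- (g$r - 32)^2 + (g$c - 32)^2 <= 10^2
  const <- matrix(0.7, 64, 64)
  expect_equal(unname(gabor_features(mask, const)), rep(0, 8),
               tolerance = 1e-10)

  # grating varying along columns at wavelength 4 -> o0_w4 dominates
  grat <- sin(2 * pi * g$c / 4)
  f <- gabor_features(mask, grat)
  expect_equal(names(which.max(f)), "o0_w4")
  expect_gt(f["o0_w4"], 100 * max(f[names(f) != "o0_w4"]))

  # 90-degree rotation permutes the orientation features
  f90 <- gabor_features(mask, t(grat))
  expect_equal(names(which.max(f90)), "o90_w4")
  expect_equal(unname(f90["o90_w4"]), unname(f["o0_w4"]), tolerance = 1e-6)
  expect_equal(unname(f90["o45_w8"]), unname(f["o135_w8"]), tolerance = 1e-6)

  # wavelength-8 grating pairs with the w8 filters
  f8 <- gabor_features(mask, sin(2 * pi * g$c / 8))
  expect_equal(names(which.max(f8)), "o0_w8")
})

test_that("Haralick features match closed-form co-occurrence cases", {
  g <- make_grid()
  mask <- matrix(TRUE, 64, 64)
  const <- matrix(0.3, 64, 64)
  f <- haralick_features(mask, const)
  expect_equal(unname(f["asm"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["entropy"]), 0)

  # 1-px checkerboard of two levels, 32-level binning: levels 0 and 31.
  # Horizontal/vertical offsets always cross: contrast 31^2; diagonal
  # offsets never do: contrast 0. ASM per direction 0.5 (two cells) or
  # 0.5 (two diagonal cells); entropy 1 bit each.
  cb <- (g$r + g$c) %% 2
  f <- haralick_features(mask, cb)
  # tiny deviations from the closed forms come from the odd pair counts of
  # the finite board (3969 diagonal pairs cannot split exactly in half)
  expect_equal(unname(f["contrast"]), (31^2 + 31^2 + 0 + 0) / 4,
               tolerance = 1e-6)
  expect_equal(unname(f["asm"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(f["entropy"]), 1, tolerance = 1e-6)
  expect_equal(unname(f["correlation"]), 0, tolerance = 1e-6)

  # entropy is invariant to affine intensity rescaling (binning preserved)
  set.seed(9)
  tex <- matrix(runif(64 * 64), 64, 64)
  f1 <- haralick_features(mask, tex)
  f2 <- haralick_features(mask, 5 * tex + 2)
  expect_equal(unname(f1["entropy"]), unname(f2["entropy"]), tolerance = 1e-9)
  expect_equal(unname(f1["contrast"]), unname(f2["contrast"]),
               tolerance = 1e-9)
})

test_that("ruffliness responds to border irregularity and scales linearly", {
  g <- make_grid()
  disc <- (g$r - 32)^2 + (g$c - 32)^2 <= 18^2
  flat <- matrix(0, 64, 64); flat[disc] <- 1
  # uniform disc: near-zero edge response on the interior membrane band
  r_disc <- ruffliness(disc, flat)
  # star-shaped mask with the same channel values: lower form factor, so
  # ruffliness is larger for the same membrane edge response
  th <- atan2(g$r - 32, g$c - 32)
  rad <- sqrt((g$r - 32)^2 + (g$c - 32)^2)
  star <- rad <= 14 + 6 * cos(8 * th)
  ff_star <- morphology_features(star)$form_factor
  ff_disc <- morphology_features(disc)$form_factor
  expect_lt(ff_star, ff_disc)
  chan <- matrix(0, 64, 64); chan[star] <- 1
  expect_gt(ruffliness(star, chan), r_disc)

  # linear in intensity
  set.seed(3)
  tex <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ruffliness(disc, 4 * tex), 4 * ruffliness(disc, tex),
               tolerance = 1e-9)

  # degenerate: mask thinner than the band uses the whole cell, with warning
  thin <- matrix(FALSE, 20, 40); thin[10:11, 5:35] <- TRUE
  expect_warning(ruffliness(thin, matrix(1, 20, 40)), "thinner")
})
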