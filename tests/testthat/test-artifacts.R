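# --- grayscale conversion -------------------------------------------------

test_that("NTSC grayscale conversion evaluates the luma weights", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(rgb_to_gray(px(255, 255, 255))[1, 1], 1)
  expect_equal(rgb_to_gray(px(0, 0, 0))[1, 1], 0)
  expect_equal(rgb_to_gray(px(255, 0, 0))[1, 1] * 255, 76.245)
  # unit-scale input uses the same weights without rescaling
  expect_equal(rgb_to_gray(px(1, 0, 0))[1, 1], 0.299)
  expect_error(rgb_to_gray(array(0, dim = c(2, 2, 4))), "H x W x 3")
})

# --- Otsu thresholding ----------------------------------------------------

test_that("two-point histogram: smallest maximizing threshold is returned", {
  p <- rep(0, 256)
  p[51 + 1] <- 0.5
  p[204 + 1] <- 0.5
  hist <- structure(list(p = p, levels = 0:255), class = "gray_histogram")
  t <- otsu_threshold(hist)
  # every t in [51, 203] maximizes the between-class variance; the stated
  # tie-break picks the smallest
  expect_gte(t, 51)
  expect_lte(t, 203)
  expect_identical(t, oracle_otsu(p, 0:255))
  expect_identical(t, 51L)
})

test_that("Otsu binarization of a two-level phantom recovers the mask", {
  spec <- phantom_spec(height = 64, width = 64, noise_sd = 0, cavities = list(),
                       tissue_intensity = 0.2, bone_intensity = 0.8,
                       shell_thickness = 0.9)
  img <- generate_phantom(spec)
  # collapse to two levels: background 0 vs bone 0.8 (tissue ~ none with a
  # thick shell); then binarize
  img[img == 0.2] <- 0
  t <- otsu_threshold(img) / 255
  expect_identical(img > t, img == 0.8)
})

test_that("Otsu equals exhaustive search on random images", {
  for (seed in 1:25) {
    img <- random_image(64, 64, seed)
    h <- gray_histogram(img)
    expect_identical(otsu_threshold(h), as.integer(oracle_otsu(h$p, h$levels)))
  }
})

test_that("Otsu threshold tracks an independent implementation", {
  # EBImage bins the unit range slightly differently, so agreement is to
  # within a couple of gray levels, not exact
  for (seed in 1:5) {
    img <- random_image(64, 64, seed)
    t_mine <- otsu_threshold(img) / 255
    t_ref <- EBImage::otsu(img, range = c(0, 1), levels = 256)
    expect_lt(abs(t_mine - t_ref), 2 / 255)
  }
})

test_that("degenerate single-level histograms are rejected", {
  expect_error(otsu_threshold(matrix(0.5, 8, 8)), "degenerate")
})

# --- motion (rotation) ----------------------------------------------------

test_that("zero rotation is the identity", {
  img <- random_image(32, 40, 1)
  expect_equal(simulate_motion(img, motion_spec(0)), img)
  expect_equal(simulate_motion(img, motion_spec(0, "nearest")), img)
})

test_that("90-degree nearest rotation is an exact index permutation", {
  img <- random_image(33, 33, 2)
  out <- simulate_motion(img, motion_spec(90, "nearest"))
  expect_identical(out, oracle_rot90_ccw(img))
  img_even <- random_image(32, 32, 3)
  expect_identical(simulate_motion(img_even, motion_spec(90, "nearest")),
                   oracle_rot90_ccw(img_even))
})

test_that("rotating by theta then -theta recovers the original exactly", {
  img <- random_image(32, 32, 4)
  for (theta in c(90, 180, 270)) {
    fwd <- simulate_motion(img, motion_spec(theta, "nearest"))
    back <- simulate_motion(fwd, motion_spec(-theta, "nearest"))
    expect_identical(back, img)
  }
})

test_that("bilinear 45-degree rotation matches the slow resampling oracle", {
  img <- random_image(32, 32, 5)
  out <- simulate_motion(img, motion_spec(45))
  ref <- oracle_rotate_bilinear(img, 45)
  expect_equal(out, ref, tolerance = 1e-12)
  # interior (non-fill) intensity conserved within 2% of the oracle
  interior <- ref > 0
  expect_lt(abs(sum(out[interior]) - sum(ref[interior])) /
              sum(ref[interior]), 0.02)
})

test_that("rotation preserves dimensions and the unit range", {
  img <- random_image(24, 36, 6)
  for (theta in c(-17.3, 7, 133)) {
    out <- simulate_motion(img, motion_spec(theta))
    expect_equal(dim(out), dim(img))
    expect_true(min(out) >= 0 && max(out) <= 1)
  }
})

# --- concentric rings -----------------------------------------------------

test_that("zero-amplitude additive rings leave the image unchanged", {
  img <- random_image(64, 64, 7)
  spec <- ring_spec(radii = c(10, 20), amplitude = 0)
  expect_equal(simulate_rings(img, spec), img)
})

test_that("changed pixels match the brute-force annulus inequality", {
  img <- matrix(0.5, 64, 64)
  spec <- ring_spec(radii = 20, ring_width = 2, amplitude = 0.25)
  out <- simulate_rings(img, spec)
  changed <- out != img
  center <- c(31.5, 31.5)
  expect_identical(changed, oracle_annulus_mask(64, 64, center, 20, 2))
})

test_that("multiple rings are disjoint and compose from single rings", {
  img <- random_image(80, 80, 8)
  radii <- c(10, 20, 30)
  all_out <- simulate_rings(img, ring_spec(radii, amplitude = 0.2))
  masks <- lapply(radii, function(r) {
    simulate_rings(img, ring_spec(r, amplitude = 0.2)) != img
  })
  # pairwise disjoint
  expect_true(all(masks[[1]] + masks[[2]] + masks[[3]] <= 1))
  union_mask <- masks[[1]] | masks[[2]] | masks[[3]]
  expect_identical(all_out != img, union_mask)
  # outside the annuli nothing changes
  expect_identical(all_out[!union_mask], img[!union_mask])
})

test_that("replace mode sets the annulus to the given intensity", {
  img <- random_image(64, 64, 9)
  out <- simulate_rings(img, ring_spec(15, amplitude = 0.9, mode = "replace"))
  mask <- out != img
  expect_true(all(out[mask] == 0.9))
})

test_that("overlapping ring layouts are rejected", {
  expect_error(ring_spec(radii = c(10, 11), ring_width = 2), "overlap")
  expect_error(ring_spec(radii = c(20, 10)), "increasing")
  expect_error(ring_spec(radii = -5), "positive")
})

# --- beam hardening -------------------------------------------------------

test_that("images with nothing above the threshold are unchanged", {
  expect_equal(
    simulate_beam_hardening(matrix(0, 16, 16), beam_hardening_spec()),
    matrix(0, 16, 16)
  )
  img <- matrix(0.3, 16, 16)
  expect_equal(simulate_beam_hardening(img, beam_hardening_spec()), img)
})

test_that("full attenuation maps every bright pixel to the threshold", {
  img <- random_image(32, 32, 10)
  spec <- beam_hardening_spec(attenuation_threshold = 0.4,
                              attenuation_strength = 1,
                              use_otsu_mask = FALSE)
  out <- simulate_beam_hardening(img, spec)
  expect_true(all(out[img > 0.4] == 0.4))
  expect_lte(max(out), max(0.4, max(img[img <= 0.4])))
})

test_that("soft-knee law darkens bone and leaves tissue on a phantom", {
  spec_ph <- phantom_spec(height = 64, width = 64, noise_sd = 0,
                          cavities = list(), bone_intensity = 0.9,
                          tissue_intensity = 0.3)
  img <- generate_phantom(spec_ph)
  out <- simulate_beam_hardening(
    img, beam_hardening_spec(attenuation_threshold = 0.4,
                             attenuation_strength = 0.5)
  )
  expect_true(all(out[img == 0.9] == 0.65))
  expect_identical(out[img == 0.3], img[img == 0.3])
  expect_identical(out[img == 0], img[img == 0])
})

test_that("beam hardening is monotone and never brightens", {
  img <- random_image(48, 48, 11)
  spec <- beam_hardening_spec(attenuation_strength = 0.7)
  out <- simulate_beam_hardening(img, spec)
  expect_true(all(out <= img + 1e-12))
  # pixel-wise monotone: ordering of intensities is preserved under the
  # unmasked law
  spec2 <- beam_hardening_spec(attenuation_strength = 0.7,
                               use_otsu_mask = FALSE)
  v <- sort(as.vector(img))
  mapped <- as.vector(simulate_beam_hardening(matrix(v, 48, 48), spec2))
  expect_true(all(diff(mapped) >= -1e-12))
})
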