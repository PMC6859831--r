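# Choriocapillaris flow-void pipeline: overlay binarization, artifact
# suppression, registration, cropping, thresholding, measurement.

test_that("scp overlay binarization separates two-level slabs", {
  img <- two_level_image(32, 40, 200, frac_hi = 0.4, seed = 1)
  mask <- binarize_scp_for_overlay(img)
  expect_identical(mask[, ], img$pixels == 200)
  # single bright pixel
  px <- matrix(40, 32, 32); px[5, 7] <- 250
  m2 <- binarize_scp_for_overlay(enface_image(px, 3, "SCP"))
  expect_equal(sum(m2), 1)
  expect_true(m2[5, 7])
  # inverted polarity: brighter class is always vessel
  inv <- enface_image(255 - img$pixels, 3, "SCP")
  expect_identical(binarize_scp_for_overlay(inv)[, ], !mask[, ])
  expect_error(binarize_scp_for_overlay(enface_image(matrix(7, 8, 8), 3, "SCP")),
               "constant")
})

test_that("projection-artifact suppression mean-matches the overlay region", {
  set.seed(2)
  px <- matrix(rnorm(64^2, 120, 10), 64, 64)
  mask <- matrix(FALSE, 64, 64); mask[1:20, ] <- TRUE
  px[mask] <- rnorm(sum(mask), 60, 5)
  cc <- enface_image(octarep:::clip255(px), 6, "CC")
  out <- remove_projection_artifacts(cc, mask)
  expect_lt(abs(mean(out$pixels[mask]) - mean(cc$pixels[!mask])), 1)
  expect_identical(out$pixels[!mask], cc$pixels[!mask])
  # empty mask and constant image: no-ops
  expect_warning(same <- remove_projection_artifacts(cc, matrix(FALSE, 64, 64)),
                 "overlay mask")
  expect_identical(same$pixels, cc$pixels)
  flat <- enface_image(matrix(100, 16, 16), 6, "CC")
  out2 <- remove_projection_artifacts(flat, matrix(c(TRUE, FALSE), 16, 16))
  expect_equal(out2$pixels, flat$pixels, tolerance = 1e-12)
})

test_that("registration matches the direct NCC oracle on small images", {
  set.seed(3)
  a <- matrix(runif(144, 0, 255), 12, 12)
  b <- octarep:::translate_matrix(a, 2, -1, fill = mean(a))
  m <- 3
  fft_ncc <- local({
    ones <- matrix(1, 12, 12)
    N <- round(octarep:::xcorr_window(ones, ones, m))
    Sx <- octarep:::xcorr_window(a, ones, m)
    Sy <- octarep:::xcorr_window(ones, b, m)
    Sxx <- octarep:::xcorr_window(a * a, ones, m)
    Syy <- octarep:::xcorr_window(ones, b * b, m)
    Sxy <- octarep:::xcorr_window(a, b, m)
    (Sxy - Sx * Sy / N) / sqrt((Sxx - Sx^2 / N) * (Syy - Sy^2 / N))
  })
  expect_equal(fft_ncc, ncc_direct(a, b, m), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("registration recovers translations and applies tie-breaking", {
  img <- render_slab(generate_vessel_network(96, 0.3, seed = 4),
                     noise_sd = 0, seed = 1)
  expect_equal(register_translation(img, img), c(dx = 0L, dy = 0L))
  shifted <- octarep:::translate_matrix(img$pixels, 3, -2, fill = 40)
  img2 <- enface_image(shifted, 3, "SCP")
  expect_equal(register_translation(img, img2, 6), c(dx = 3L, dy = -2L))
  # constant images: every shift ties; the zero offset wins
  flat <- enface_image(matrix(50, 64, 64), 3, "SCP")
  expect_equal(register_translation(flat, flat, 5), c(dx = 0L, dy = 0L))
})

test_that("cropping keeps only the overlap with correct dimensions and area", {
  img <- random_image(64, extent_mm = 6, seed = 5)
  p0 <- crop_to_overlap(img, img, c(dx = 0, dy = 0))
  expect_equal(dim(p0$image1$pixels), c(64, 64))
  expect_equal(p0$analyzed_area_mm2, 36)
  p3 <- crop_to_overlap(img, img, c(dx = 3, dy = 0))
  expect_equal(dim(p3$image1$pixels), c(64, 61))
  expect_equal(p3$analyzed_area_mm2, 64 * 61 * (6 / 64)^2)
  # a noise-free shifted pair crops to pixel-identical views
  shifted <- enface_image(octarep:::translate_matrix(img$pixels, -4, 5, fill = 0), 6, "CC")
  pair <- crop_to_overlap(img, shifted, c(dx = -4, dy = 5))
  expect_identical(pair$image1$pixels, pair$image2$pixels)
  expect_error(crop_to_overlap(img, img, c(dx = 64, dy = 0)), "overlap")
})

test_that("flow-void threshold equals mean + 1.96 population SD", {
  flat <- enface_image(matrix(100, 16, 16), 6, "avascular")
  expect_equal(flow_void_threshold(flat), 100)
  set.seed(6)
  v <- rnorm(10000, 50, 10)
  v <- octarep:::clip255(50 + (v - mean(v)) * 10 / sd(v) * sqrt(9999 / 10000))
  img <- enface_image(matrix(v, 100, 100), 6, "avascular")
  mu <- mean(v); sd_pop <- sqrt(mean((v - mu)^2))
  expect_equal(flow_void_threshold(img), mu + 1.96 * sd_pop, tolerance = 1e-12)
})

test_that("flow-void measurement counts pixels at or below the threshold", {
  img <- random_image(32, extent_mm = 6, seed = 7)
  none <- measure_flow_void(img, -1)
  expect_equal(none$void_area_mm2, 0)
  all_void <- measure_flow_void(img, 256)
  expect_equal(all_void$void_area_mm2, all_void$analyzed_area_mm2)
  T0 <- 100
  k <- sum(img$pixels <= T0)
  res <- measure_flow_void(img, T0)
  expect_equal(res$void_area_mm2, k * (6 / 32)^2)
  # inclusivity at the threshold
  px <- matrix(c(100, 101), 8, 8)
  r2 <- measure_flow_void(enface_image(px, 6, "CC"), 100)
  expect_equal(sum(r2$void_mask), sum(px == 100))
})

test_that("threshold and measurement are invariant to pixel permutation", {
  img <- random_image(32, extent_mm = 6, seed = 8)
  set.seed(9)
  perm <- matrix(sample(img$pixels), 32, 32)
  pimg <- enface_image(perm, 6, "CC")
  expect_equal(flow_void_threshold(img), flow_void_threshold(pimg))
  expect_equal(measure_flow_void(img, 120)$void_area_mm2,
               measure_flow_void(pimg, 120)$void_area_mm2)
})

test_that("void area is non-decreasing in the threshold", {
  img <- random_image(32, extent_mm = 6, seed = 10)
  areas <- vapply(seq(0, 255, by = 15),
                  function(T0) measure_flow_void(img, T0)$void_area_mm2, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("the pipeline gives equal areas for duplicate and shifted noise-free scans", {
  scene <- octarep:::make_cc_scene(96, 0.2, seed = 11)
  dup <- generate_intravisit_pair(scene, shift_px = c(0, 0), noise_sd = 0, seed = 1)
  res <- ccfv_pipeline(dup$scan1, dup$scan2, max_shift_px = 5)
  expect_equal(res$result1$void_area_mm2, res$result2$void_area_mm2)
  sh <- generate_intravisit_pair(scene, shift_px = c(4, 3), noise_sd = 0, seed = 1)
  res2 <- ccfv_pipeline(sh$scan1, sh$scan2, max_shift_px = 6)
  expect_equal(res2$offset_px, c(dx = 4L, dy = 3L))
  expect_equal(res2$result1$analyzed_area_mm2, res2$result2$analyzed_area_mm2)
  expect_equal(res2$result1$void_area_mm2, res2$result2$void_area_mm2,
               tolerance = 0.02)
})

test_that("the pipeline recovers the true void fraction under mild noise", {
  scene <- octarep:::make_cc_scene(128, 0.3, seed = 12)
  pair <- generate_intravisit_pair(scene, shift_px = c(3, -4), noise_sd = 5, seed = 2)
  res <- ccfv_pipeline(pair$scan1, pair$scan2, max_shift_px = 8)
  for (r in list(res$result1, res$result2)) {
    frac <- r$void_area_mm2 / r$analyzed_area_mm2
    expect_lt(abs(frac - 0.3) / 0.3, 0.1)
  }
})

test_that("artifact removal reduces the impact of projection artifacts", {
  scene <- octarep:::make_cc_scene(128, 0.2, seed = 13)
  pair <- generate_intravisit_pair(scene, shift_px = c(2, 2), noise_sd = 5, seed = 3)
  with_rm <- ccfv_pipeline(pair$scan1, pair$scan2, max_shift_px = 5)
  without <- ccfv_pipeline(pair$scan1, pair$scan2, max_shift_px = 5,
                           artifact_removal = FALSE)
  err <- function(res) {
    mean(abs(c(res$result1$void_area_mm2, res$result2$void_area_mm2) /
               res$result1$analyzed_area_mm2 - 0.2))
  }
  expect_lt(err(with_rm), err(without))
  d_with <- abs(with_rm$result1$void_area_mm2 - with_rm$result2$void_area_mm2)
  d_without <- abs(without$result1$void_area_mm2 - without$result2$void_area_mm2)
  expect_lt(d_with, d_without)
})

test_that("pipeline errors identify the failing stage", {
  scene <- octarep:::make_cc_scene(96, 0.2, seed = 14)
  pair <- generate_intravisit_pair(scene, shift_px = c(0, 0), noise_sd = 5, seed = 4)
  bad <- pair$scan1
  bad$slabs$SCP <- enface_image(matrix(100, 96, 96), 6, "SCP")
  # the constant SCP slab first triggers the degenerate-standardization
  # warning, then fails at binarization with the stage named
  expect_error(suppressWarnings(ccfv_pipeline(bad, pair$scan2)), "scp_binarize")
  noslab <- pair$scan1
  noslab$slabs$CC <- NULL
  expect_error(ccfv_pipeline(noslab, pair$scan2), "CC, SCP and avascular")
})
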