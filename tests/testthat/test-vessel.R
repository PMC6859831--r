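# Vessel-density and FAZ pipeline: Otsu binarization, area arithmetic,
# delineation modes.

test_that("otsu threshold matches the exhaustive brute-force oracle", {
  for (s in 1:25) {
    img <- random_image(24, seed = s)
    mask <- binarize_otsu(img)
    expect_equal(attr(mask, "threshold"), otsu_brute(img$pixels), info = paste("seed", s))
  }
  # structured bimodal cases
  for (s in 1:5) {
    img <- two_level_image(24, 50, 200, frac_hi = 0.3, seed = s)
    set.seed(s)
    px <- octarep:::clip255(img$pixels + rnorm(24^2, 0, 12))
    img <- enface_image(px, 3, "SCP")
    expect_equal(attr(binarize_otsu(img), "threshold"), otsu_brute(img$pixels))
  }
})

test_that("otsu separates a two-point histogram and is offset-invariant", {
  px <- matrix(rep(c(50, 200), each = 128), 16, 16)
  img <- enface_image(px, 3, "SCP")
  mask <- binarize_otsu(img)
  expect_identical(mask[, ], px == 200)
  shifted <- enface_image(px + 30, 3, "SCP")
  expect_identical(binarize_otsu(shifted)[, ], mask[, ])
  expect_equal(attr(binarize_otsu(shifted), "threshold"),
               otsu_brute(px + 30))
  expect_error(binarize_otsu(enface_image(matrix(5, 8, 8), 3, "SCP")), "constant")
})

test_that("vessel area and density arithmetic is exact", {
  expect_equal(total_vessel_area(matrix(FALSE, 8, 8), 3 / 512), 0)
  expect_equal(total_vessel_area(matrix(TRUE, 512, 512), 3 / 512), 9)
  expect_equal(total_vessel_area(matrix(c(rep(TRUE, 26214), rep(FALSE, 512^2 - 26214)),
                                        512, 512), 3 / 512),
               26214 * (3 / 512)^2)
  expect_equal(vessel_density(4.5, 9), 0.5)
  expect_equal(vessel_density(0, 9), 0)
  expect_equal(vessel_density(9, 9), 1)
  expect_error(vessel_density(1, 0), "positive")
  expect_error(vessel_density(10, 9), "within")
})

test_that("pixel-count conservation: vessel + background area = total", {
  mask <- generate_vessel_network(128, 0.3, seed = 1)
  mpp <- 3 / 128
  expect_equal(total_vessel_area(mask, mpp) + total_vessel_area(!mask, mpp),
               128^2 * mpp^2)
})

test_that("manual FAZ area follows the shoelace formula", {
  mpp <- 3 / 512
  sq <- faz_manual(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
  expect_equal(faz_area(matrix(FALSE, 4, 4), sq, mpp), 100^2 * mpp^2)
  tri <- faz_manual(cbind(c(0, 10, 0), c(0, 0, 10)))
  expect_equal(faz_area(matrix(FALSE, 4, 4), tri, mpp), 50 * mpp^2)
  # closed-ring vertex lists are accepted; degenerate/self-intersecting are not
  closed <- faz_manual(cbind(c(0, 10, 0, 0), c(0, 0, 10, 0)))
  expect_equal(faz_area(matrix(FALSE, 4, 4), closed, mpp), 50 * mpp^2)
  expect_error(faz_manual(cbind(c(0, 1), c(0, 1))), "3 vertices")
  expect_error(faz_manual(cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))), "self-intersecting")
})

test_that("seeded-auto FAZ recovers a known disc area", {
  mask <- generate_vessel_network(256, 0.3, faz_radius_mm = 0.25,
                                  extent_mm = 3, seed = 2)
  area <- faz_area(mask, faz_auto(c(128, 128)), 3 / 256)
  expect_lt(abs(area - pi * 0.25^2) / (pi * 0.25^2), 0.1)
  # seed on a vessel pixel errors
  ring_px <- which(mask, arr.ind = TRUE)[1, ]
  expect_error(faz_area(mask, faz_auto(c(ring_px[2], ring_px[1])), 3 / 256),
               "vessel pixel")
})

test_that("auto FAZ discretization error shrinks with resolution", {
  # a 4x resolution step, so discretization dominates the fixed 2-px
  # closing-radius interaction with the boundary ring
  true_area <- pi * 0.25^2
  err <- vapply(c(64, 256), function(n) {
    mask <- generate_vessel_network(n, 0.3, faz_radius_mm = 0.25,
                                    extent_mm = 3, seed = 3)
    abs(faz_area(mask, faz_auto(c(n / 2, n / 2)), 3 / n) - true_area)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("morphological closing agrees with the reference implementation", {
  skip_if_not_installed("EBImage")
  set.seed(4)
  mask <- matrix(runif(64^2) < 0.3, 64, 64)
  ours <- octarep:::close_disc(mask, 2)
  off <- expand.grid(-2:2, -2:2)
  brush <- matrix(as.numeric(off[[1]]^2 + off[[2]]^2 <= 4), 5, 5)
  ref <- EBImage::closing(EBImage::Image(mask * 1), brush)
  # interior comparison: EBImage pads borders differently
  expect_equal(ours[4:61, 4:61], EBImage::imageData(ref)[4:61, 4:61] > 0.5)
})

test_that("vessel pipeline recovers constructed densities", {
  # noise-free two-level slab: density is exact
  mask <- generate_vessel_network(128, 0.25, seed = 5)
  rec <- scan_record("A", list(SCP = render_slab(mask, noise_sd = 0, seed = 1)))
  res <- vessel_pipeline(rec, "SCP")
  expect_equal(res$vd_fraction, mean(mask))
  expect_equal(res$tva_mm2, sum(mask) * (3 / 128)^2)
  expect_equal(res$vd_fraction, res$tva_mm2 / res$total_area_mm2)
  # noisy slab: within the recovery band
  recn <- scan_record("A", list(SCP = render_slab(mask, noise_sd = 5, seed = 2)))
  resn <- vessel_pipeline(recn, "SCP")
  expect_lt(abs(resn$vd_fraction - 0.25), 0.05)
  # duplicate scans are bit-identical
  res2 <- vessel_pipeline(rec, "SCP")
  expect_identical(res, res2)
  expect_error(vessel_pipeline(rec, "DCP"), "no DCP slab")
})

test_that("vessel density is invariant to intensity inversion under the polarity rule", {
  mask <- generate_vessel_network(96, 0.3, seed = 6)
  img <- render_slab(mask, noise_sd = 0, seed = 1)
  inv <- enface_image(255 - img$pixels, 3, "SCP")
  vd <- function(im) {
    m <- binarize_otsu(im)
    mean(m)
  }
  # inversion flips which class is brighter, so the vessel set inverts;
  # composing with the inversion recovers the same density
  expect_equal(1 - vd(inv), vd(img))
})

test_that("operator retracing jitter perturbs the manual FAZ area", {
  poly <- faz_manual(cbind(c(10, 40, 40, 10), c(10, 10, 40, 40)))
  j1 <- jitter_polygon(poly, sd_px = 1, seed = 1)
  a0 <- faz_area(matrix(FALSE, 4, 4), poly, 1)
  a1 <- faz_area(matrix(FALSE, 4, 4), j1, 1)
  expect_false(isTRUE(all.equal(a0, a1)))
  expect_lt(abs(a1 - a0) / a0, 0.25)
})
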