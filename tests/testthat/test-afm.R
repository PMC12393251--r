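# AFM flattening, segmentation, classification and offset distance.

test_that("per-row flattening removes polynomial bow exactly", {
  u <- seq(0, 1, length.out = 80)
  bow <- matrix(0, 60, 80)
  for (r in 1:60) bow[r, ] <- 1.5 - 2 * u + 3 * u^2 + 0.01 * r
  img <- height_map(bow, 1)
  flat <- flatten(img)
  expect_lt(max(abs(flat)), 1e-9)
  # idempotence in the presence of molecules
  sc <- random_afm_scene(2, 2, 2, image_px = 150, seed = 4,
                         background_coef = c(0.4, -0.8, 1.2))
  f1 <- flatten(sc$image)
  f2 <- flatten(f1)
  expect_lt(max(abs(f2 - f1)), 0.1)
  expect_lt(abs(stats::median(f1)), 0.05)   # background median ~ 0
  expect_error(flatten(img, order = 3), "order")
})

test_that("flattening preserves feature heights over a bowed background", {
  sc0 <- random_afm_scene(3, 0, 0, image_px = 150, seed = 8, noise_sd = 0)
  scb <- random_afm_scene(3, 0, 0, image_px = 150, seed = 8, noise_sd = 0,
                          background_coef = c(1, -2, 2.5))
  flat <- flatten(scb$image)
  expect_lt(abs(max(flat) - max(sc0$image)) / max(sc0$image), 0.05)
})

test_that("segmentation labels connected components and fills holes", {
  expect_identical(segment_molecules(height_map(matrix(0, 50, 50), 1), 0.3),
                   list())
  sc <- random_afm_scene(0, 2, 0, image_px = 120, pixel_nm = 0.5,
                         noise_sd = 0, seed = 2)
  regs <- segment_molecules(sc$image, 0.35)
  expect_length(regs, 2)
  # an annulus segments as one region whose filled mask covers the centre
  z <- matrix(0, 60, 60)
  for (r in 1:60) for (cc in 1:60) {
    d <- sqrt((r - 30)^2 + (cc - 30)^2)
    if (d >= 8 && d <= 12) z[r, cc] <- 1
  }
  ring <- segment_molecules(height_map(z, 1), 0.5)
  expect_length(ring, 1)
  expect_true(any(ring[[1]]$pixels[, "row"] == 29 &
                    ring[[1]]$pixels[, "col"] == 29))
  expect_equal(ring[[1]]$area_nm2, sum(
    outer(1:60, 1:60, function(r, cc) sqrt((r - 30)^2 + (cc - 30)^2) <= 12)),
    tolerance = 0.05)
})

test_that("classification thresholds separate the molecule classes", {
  sc <- random_afm_scene(4, 4, 4, seed = 6)
  img <- flatten(sc$image)
  tab <- region_table(segment_molecules(img, 0.35), img,
                      default_afm_thresholds())
  expect_identical(sum(tab$class == "dna"), 4L)
  expect_identical(sum(tab$class == "protein"), 4L)
  expect_identical(sum(tab$class == "complex"), 4L)
  # a merged aggregate exceeds area_max
  feats <- data.frame(molecule = 1, type = "ring",
                      x_nm = c(20, 24, 28, 23), y_nm = c(20, 23, 20, 17),
                      height_nm = 1.2, radius_nm = 3, width_nm = 2)
  agg <- make_afm_scene(afm_scene_spec(90, 0.5, feats))
  r <- segment_molecules(agg$image, 0.35)
  expect_identical(classify_region(r[[1]], default_afm_thresholds()),
                   "aggregate")
  expect_identical(classify_region(r[[1]], default_afm_thresholds(),
                                   confirmed = FALSE), "rejected")
  expect_error(classify_region(r[[1]], list(area_min = 1)),
               "missing classification threshold")
})

test_that("offset distance vanishes for uniform disks and centred blobs", {
  img <- disk_image()
  reg <- segment_molecules(img, 0.5)[[1]]
  expect_equal(offset_distance(reg, img)$delta_nm, 0, tolerance = 1e-12)
  sc <- random_afm_scene(0, 0, 1, image_px = 120, pixel_nm = 0.5,
                         blob_offset_frac = 0, noise_sd = 0, seed = 3)
  reg2 <- segment_molecules(sc$image, 0.35)[[1]]
  expect_lt(offset_distance(reg2, sc$image)$delta_nm, 0.5)  # < 1 px
})

test_that("offset distance grows monotonically with the blob offset", {
  fr <- seq(0, 1, 0.2)
  ds <- vapply(fr, function(f) {
    sc <- random_afm_scene(0, 0, 1, image_px = 120, pixel_nm = 0.5,
                           blob_offset_frac = f, noise_sd = 0, seed = 2)
    reg <- segment_molecules(sc$image, 0.35)[[1]]
    offset_distance(reg, sc$image)$delta_nm
  }, numeric(1))
  expect_true(all(diff(ds) > -0.25))   # non-decreasing within half a pixel
  expect_gt(ds[length(ds)] - ds[1], 0.4)
})

test_that("offset distance is invariant to translation and 90-degree turns", {
  mk <- function(x, y) {
    feats <- data.frame(molecule = 1, type = c("ring", "blob"),
                        x_nm = c(x, x + 2), y_nm = c(y, y),
                        height_nm = c(0.7, 4), radius_nm = c(2, 1.2),
                        width_nm = c(1.2, NA))
    make_afm_scene(afm_scene_spec(100, 0.5, feats))$image
  }
  d <- function(img) {
    reg <- segment_molecules(img, 0.35)[[1]]
    offset_distance(reg, img)$delta_nm
  }
  d0 <- d(mk(20, 25))
  expect_equal(d(mk(31.5, 14)), d0, tolerance = 1e-6)   # pure translation
  img <- mk(20, 25)
  rot <- height_map(t(unclass(img))[ncol(img):1, ], attr(img, "pixel_nm"))
  expect_equal(d(rot), d0, tolerance = 1e-6)
  # delta scales linearly with the pixel-size metadata
  img2 <- height_map(unclass(img), 1.0)
  expect_equal(d(img2), 2 * d0, tolerance = 1e-9)
})

test_that("relative affinity follows the counting definition", {
  expect_equal(relative_affinity(list(N_D = 10, N_P = 10, N_DP = 10)), 0.1)
  expect_equal(relative_affinity(list(N_D = 5, N_P = 4, N_DP = 0)), 0)
  expect_error(relative_affinity(list(N_D = 0, N_P = 4, N_DP = 1)),
               "undefined affinity")
  # duplicating a scan halves alpha (concentration dependence)
  a1 <- relative_affinity(list(N_D = 7, N_P = 9, N_DP = 4))
  a2 <- relative_affinity(list(N_D = 14, N_P = 18, N_DP = 8))
  expect_equal(a2, a1 / 2)
  cnt <- affinity_counts(c("dna", "dna", "protein", "complex", "aggregate"))
  expect_identical(unclass(cnt)[c("N_D", "N_P", "N_DP")],
                   list(N_D = 2L, N_P = 1L, N_DP = 1L))
})
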