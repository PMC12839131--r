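test_that("reference shapes score their analytic descriptor values", {
  disc <- make_spheroid_image(image_spec(radius = 50, seed = 1))
  f <- shape_features(segment_spheroid(disc$image))
  expect_lt(abs(f$area - pi * 50^2) / (pi * 50^2), 0.02)
  expect_gt(f$form_factor, 0.95); expect_lt(f$form_factor, 1.05)
  expect_gte(f$solidity, 0.98); expect_lte(f$solidity, 1.0)
  expect_gt(f$compactness, 0.95); expect_lt(f$compactness, 1.05)
  # median of the distance transform of a disc of radius r is r(1 - 1/sqrt(2))
  expect_equal(f$median_radius, 50 * (1 - 1 / sqrt(2)), tolerance = 0.05)

  sq <- matrix(0.05, 300, 300)
  sq[51:250, 51:250] <- 0.9
  fs <- shape_features(segment_spheroid(sq))
  expect_equal(fs$area, 200^2)
  expect_lt(abs(fs$form_factor - pi / 4) / (pi / 4), 0.05)
  expect_equal(fs$solidity, 1, tolerance = 1e-9)
  expect_equal(fs$compactness, pi / 3, tolerance = 0.01)
  expect_equal(fs$median_radius, 50, tolerance = 1)
})

test_that("segmentation keeps the largest object and rejects empty frames", {
  img <- matrix(0.05, 220, 220)
  yy <- matrix(rep(1:220, times = 220), 220)
  xx <- matrix(rep(1:220, each = 220), 220)
  img[(xx - 60)^2 + (yy - 60)^2 <= 30^2] <- 0.9
  img[(xx - 150)^2 + (yy - 150)^2 <= 50^2] <- 0.9
  msk <- segment_spheroid(img)
  expect_lt(abs(sum(msk$mask) - pi * 50^2) / (pi * 50^2), 0.02)

  expect_error(segment_spheroid(matrix(0.5, 50, 50)), "empty segmentation")
  expect_error(segment_spheroid(matrix(c(0.5, NA), 10, 10)), "finite")
})

test_that("all six descriptors match the brute-force oracle on random blobs", {
  for (s in c(3, 7, 12, 21, 33, 48)) {
    msk <- random_blob_mask(s)
    f <- shape_features(msk)
    o <- oracle_shape_features(msk$mask)
    expect_equal(f$area, o$area)
    expect_equal(f$perimeter, o$perimeter, tolerance = 1e-6)
    expect_equal(f$form_factor, o$form_factor, tolerance = 1e-6)
    expect_equal(f$compactness, o$compactness, tolerance = 1e-6)
    expect_equal(f$solidity, o$solidity, tolerance = 1e-6)
    expect_equal(f$median_radius, o$median_radius, tolerance = 1e-6)
  }
})

test_that("descriptors are scale- and rotation-stable where they should be", {
  msk <- random_blob_mask(5)
  f1 <- shape_features(msk)

  # doubling the acquisition resolution: same boundary function rendered on
  # a grid twice as fine (same seed draws the same boundary harmonics)
  up <- random_blob_mask(5, size = 144, radius = 36)
  f2 <- shape_features(up)
  expect_equal(f2$area / f1$area, 4, tolerance = 0.03)
  expect_equal(f2$perimeter / f1$perimeter, 2, tolerance = 0.03)
  for (d in c("form_factor", "solidity", "compactness")) {
    expect_equal(f2[[d]], f1[[d]], tolerance = 0.03)
  }

  rot <- structure(list(mask = t(msk$mask)[ncol(msk$mask):1, ], pixel_size = 1),
                   class = "spheroid_mask")
  f3 <- shape_features(rot)
  for (d in c("form_factor", "solidity", "compactness")) {
    expect_equal(f3[[d]], f1[[d]], tolerance = 0.03)
  }
})

test_that("granulometry matches brute-force successive openings", {
  im <- make_spheroid_image(image_spec(width = 64, height = 64, radius = 20,
                                       texture_grain = 3, seed = 4))
  msk <- segment_spheroid(im$image)
  gs <- granularity_spectrum(im$image, msk, n_scales = 3)
  expect_equal(gs$values, oracle_granularity(im$image, msk$mask, 3),
               tolerance = 1e-9)
  expect_true(all(gs$values >= 0))
})

test_that("uniform objects carry no small-scale granularity signal", {
  im <- make_spheroid_image(image_spec(width = 96, height = 96, radius = 30,
                                       texture_grain = 0, seed = 2))
  msk <- segment_spheroid(im$image)
  gs <- granularity_spectrum(im$image, msk, n_scales = 4)
  expect_true(all(gs$values < 1))
})

test_that("speckle grain size sets the dominant granulometry scale", {
  for (g in c(2, 4)) {
    im <- make_spheroid_image(image_spec(width = 128, height = 128, radius = 45,
                                         texture_grain = g, seed = 40 + g))
    msk <- segment_spheroid(im$image)
    gs <- granularity_spectrum(im$image, msk, n_scales = 8)
    expect_lte(abs(which.max(gs$values) - g), 1)
  }
})

test_that("the relative 5% rule keeps the right scales", {
  spec <- structure(list(scales = 1:5, values = c(40, 10, 3, 1.5, 1),
                         kept_indices = 1:5), class = "granularity_spectrum")
  expect_equal(filter_granularity(spec, 0.05)$kept_indices, 1:3)

  one <- structure(list(scales = 1, values = 7, kept_indices = 1),
                   class = "granularity_spectrum")
  expect_equal(filter_granularity(one)$kept_indices, 1L)

  flat <- structure(list(scales = 1:4, values = rep(2, 4), kept_indices = 1:4),
                    class = "granularity_spectrum")
  expect_equal(filter_granularity(flat)$kept_indices, 1:4)

  zero <- structure(list(scales = 1:3, values = rep(0, 3), kept_indices = 1:3),
                    class = "granularity_spectrum")
  expect_warning(out <- filter_granularity(zero), "no scales kept")
  expect_length(out$kept_indices, 0)
})

test_that("image feature extraction produces CellProfiler-style columns", {
  im <- make_spheroid_image(image_spec(width = 96, height = 96, radius = 30,
                                       texture_grain = 3, seed = 6))
  row <- extract_image_features(im$image, n_scales = 4)
  expect_true(all(c("AreaShape_Area", "AreaShape_FormFactor",
                    "AreaShape_Solidity") %in% names(row)))
  expect_true(any(startsWith(names(row), "Granularity_")))
  expect_equal(nrow(row), 1)
})
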