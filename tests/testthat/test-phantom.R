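# Digital phantom construction and two-view HMR calibration.

test_that("default phantom satisfies the layer and mask invariants", {
  ph <- default_phantom()
  expect_true(all(vapply(ph$activity_layers,
                         function(m) all(m >= 0), logical(1))))
  # lateral extent 380 mm within one pixel of matrix * pixel_size
  expect_equal(ph$config$footprint_mm, 380)
  expect_lte(ph$config$footprint_mm, prod(ph$grid_shape[1], ph$pixel_size))
  expect_equal(sum(ph$layer_thicknesses), 50)
  # background confined to the basal layer
  bg <- ph$compartment_masks == 7L
  expect_true(all(ph$activity_layers$basal[bg] > 0))
  expect_true(all(ph$activity_layers$layer1[bg] == 0))
  expect_true(all(ph$activity_layers$layer2[bg] == 0))
  # organ activity confined to layers 1 and 2
  heart <- ph$compartment_masks == 1L
  expect_gt(sum(heart), 0)
  expect_true(all(ph$activity_layers$basal[heart] ==
                    ph$config$background_activity))
  # mediastinum sits between the lungs
  med <- which(ph$compartment_masks == 2L, arr.ind = TRUE)
  ll <- which(ph$compartment_masks == 4L, arr.ind = TRUE)
  lr <- which(ph$compartment_masks == 5L, arr.ind = TRUE)
  expect_gt(min(med[, 2]), max(ll[, 2]))
  expect_lt(max(med[, 2]), min(lr[, 2]))
})

test_that("invalid geometry is rejected", {
  cfg <- phantom_config(heart = list(centre = c(0, 70), radius = 45))
  expect_error(build_phantom(cfg), "overlap")
  cfg2 <- phantom_config(thyroid = list(centre = c(0, 185), radius = 18))
  expect_error(build_phantom(cfg2), "outside the phantom footprint")
})

test_that("zero thyroid activity zeroes its layer contribution", {
  ph <- build_phantom(phantom_config(thyroid_ratio = 0))
  thy <- ph$compartment_masks == 6L
  expect_true(all(ph$activity_layers$layer1[thy] == 0))
  expect_true(all(ph$activity_layers$layer2[thy] == 0))
})

test_that("calibration recovers the designated HMRs exactly", {
  cal <- calibrated_phantom()
  h <- ideal_hmr(cal)
  expect_equal(unname(h), c(2.6, 3.5), tolerance = 1e-6)
  expect_lt(abs(h[["anterior"]] - 2.6), 1e-4)
  expect_lt(abs(h[["posterior"]] - 3.5), 1e-4)
  # depth-asymmetric heart placement is required
  expect_false(isTRUE(all.equal(cal$config$heart_layer1,
                                cal$config$heart_layer2)))
})

test_that("HMR is invariant under global activity scaling", {
  cal <- calibrated_phantom()
  scaled <- cal
  scaled$activity_layers <- lapply(cal$activity_layers, function(m) m * 10)
  expect_equal(ideal_hmr(scaled), ideal_hmr(cal), tolerance = 1e-12)
})

test_that("calibration is idempotent", {
  cal <- calibrated_phantom()
  again <- calibrate_phantom(cal)
  expect_lt(abs(again$config$heart_layer1 - cal$config$heart_layer1) /
              cal$config$heart_layer1, 1e-6)
  expect_lt(abs(again$config$heart_layer2 - cal$config$heart_layer2) /
              max(cal$config$heart_layer2, 1e-12), 1e-6)
})

test_that("heart at background level gives unit HMRs", {
  ph <- build_phantom(phantom_config(heart_layer1 = 0, heart_layer2 = 0,
                                     lung_ratio = 0, liver_ratio = 0,
                                     thyroid_ratio = 0))
  expect_equal(unname(ideal_hmr(ph)), c(1, 1), tolerance = 1e-10)
})

test_that("an unattainable designated pair raises a calibration error", {
  # reversed designated pair needs the heart anterior of the background
  expect_error(calibrate_phantom(default_phantom(), 3.5, 2.6),
               "infeasible.*attainable")
})

test_that("phantom configuration round-trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(matrix = 128, pixel_size = 4.42,
                            heart_layer1 = 2.1, heart_layer2 = 0.2,
                            layer_thicknesses = list(basal = 10, layer1 = 14,
                                                     layer2 = 26)),
                       path, auto_unbox = TRUE)
  cfg <- phantom_config_from_json(path)
  expect_equal(cfg$matrix, 128L)
  expect_equal(cfg$heart_layer1, 2.1)
  ph <- build_phantom(cfg)
  expect_equal(ph$grid_shape, c(128, 128))
  expect_gt(sum(ph$compartment_masks == 1L), 0)
})

test_that("phantom round-trips through plain-text serialization", {
  dir <- withr::local_tempdir()
  ph <- default_phantom()
  write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "phantom.json")))
  back <- read_phantom(dir)
  expect_equal(back$activity_layers$basal, ph$activity_layers$basal,
               tolerance = 1e-12)
  expect_equal(back$compartment_masks, ph$compartment_masks)
  expect_equal(back$pixel_size, ph$pixel_size)
  expect_equal(unname(ideal_hmr(back)), unname(ideal_hmr(ph)),
               tolerance = 1e-9)
})
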