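# Planar projector: attenuation projection, PSF, detection weights,
# simulation determinism and detector robustness.

test_that("attenuation projection handles the degenerate cases", {
  ph <- default_phantom()
  empty <- ph
  empty$activity_layers <- lapply(ph$activity_layers, function(m) m * 0)
  expect_true(all(ideal_project(empty, "anterior") == 0))

  # single unit-activity pixel projects to its own pixel only,
  # attenuated by the within-layer integral of its layer
  one <- empty
  one$activity_layers$layer2[100, 120] <- 1
  img <- ideal_project(one, "anterior")
  expect_equal(sum(img > 0), 1L)
  mu <- mu_linear("pmma", 159)
  z1 <- 24; z2 <- 50   # layer2 depth interval, anterior side
  expect_equal(img[100, 120],
               (exp(-mu * z1) - exp(-mu * z2)) / (mu * (z2 - z1)),
               tolerance = 1e-12)
  # the posterior view sees the same pixel mirrored and less attenuated
  post <- ideal_project(one, "posterior")
  expect_equal(sum(post > 0), 1L)
  expect_equal(which(post > 0, arr.ind = TRUE)[1, ],
               c(row = 100, col = ncol(post) - 120 + 1))
  expect_gt(post[100, ncol(post) - 120 + 1], img[100, 120])
})

test_that("system PSF is normalized, symmetric, and Gaussian when p = 0", {
  megp <- discovery_presets()$MEGP
  det <- standard_detector()
  k <- system_psf(megp, det, 159)
  expect_equal(sum(k), 1, tolerance = 1e-6)
  expect_equal(k, t(k), tolerance = 1e-12)            # 90 deg rotation
  expect_equal(k, k[nrow(k):1, ], tolerance = 1e-12)  # reflection
  k0 <- system_psf(megp, det, 159, penetration = 0)
  expect_equal(sum(k0), 1, tolerance = 1e-6)
  # MEGP at 159 keV: tail weight below 1e-3, kernel ~ pure Gaussian
  expect_lt(septal_penetration(megp, 159), 1e-3)
  # LEHR at 529 keV carries a visible tail: more mass far from centre
  lehr <- discovery_presets()$LEHR
  kt <- system_psf(lehr, det, 529)
  expect_gt(nrow(kt), nrow(k0))
})

test_that("detection weights behave with window, crystal and energy", {
  det <- standard_detector()
  acq <- acquisition_spec()
  narrow <- acquisition_spec(window_halfwidth = 1e-6)
  for (e in c(159, 529))
    expect_lt(detection_weight(det, e, narrow), 1e-4)
  expect_gt(detection_weight(det, 159, acq), 0.5)
  thick <- detector_spec(crystal_thickness = 15.9)
  expect_gt(detection_weight(thick, 159, acq),
            detection_weight(det, 159, acq))
  # high-energy lines reach the window only via downscatter
  expect_lt(detection_weight(det, 529, acq), 0.5)
  expect_gt(detection_weight(det, 529, acq), 0)
})

test_that("planar simulation is seeded, deterministic, and linear in budget", {
  ph <- calibrated_phantom()
  det <- standard_detector()
  acq <- fast_acq(seed = 5)
  lehr <- discovery_presets()$LEHR
  i1 <- simulate_planar(ph, lehr, det, acq, "anterior", seed = 5)
  i2 <- simulate_planar(ph, lehr, det, acq, "anterior", seed = 5)
  i3 <- simulate_planar(ph, lehr, det, acq, "anterior", seed = 6)
  expect_identical(i1$counts, i2$counts)
  expect_false(identical(i1$counts, i3$counts))
  expect_true(all(i1$counts >= 0))
  expect_identical(dim(i1$counts), c(acq$matrix, acq$matrix))

  e1 <- expected_planar(ph, lehr, det, acq, "anterior")
  e2 <- expected_planar(ph, lehr, det,
                        fast_acq(total_photons = 2e6), "anterior")
  expect_equal(sum(e2$counts) / sum(e1$counts), 2, tolerance = 1e-9)
})

test_that("penetration-free MEGP images sit closer to the designated HMR", {
  ph <- calibrated_phantom()
  det <- standard_detector()
  acq <- fast_acq()
  rois <- place_rois(ph)
  h <- vapply(c("LEHR", "MEGP"), function(nm) {
    img <- simulate_planar(ph, discovery_presets()[[nm]], det, acq,
                           "anterior", noise = FALSE)
    compute_hmr(img, rois)
  }, numeric(1))
  expect_lt(abs(h[["MEGP"]] - 2.6), abs(h[["LEHR"]] - 2.6))
})

test_that("coefficients are robust to detector-resolution settings", {
  ph <- calibrated_phantom()
  acq <- fast_acq()
  lehr <- discovery_presets()$LEHR
  base <- noisefree_cc(lehr)
  for (det in list(detector_spec(intrinsic_resolution = 3.3,
                                 energy_resolution_140 = 0.095),
                   detector_spec(intrinsic_resolution = 4.5,
                                 energy_resolution_140 = 0.099))) {
    cc <- simulate_conversion(calibrated_phantom(), lehr, det, acq,
                              n_replicates = 1, noise = FALSE)$compensated_cc
    expect_lt(abs(cc - base), 0.03)
  }
})

test_that("a thicker crystal raises the low-energy-collimator coefficient", {
  lehr <- discovery_presets()$LEHR
  cc38 <- noisefree_cc(lehr, detector_spec(crystal_thickness = 9.5))
  cc58 <- noisefree_cc(lehr, detector_spec(crystal_thickness = 15.9))
  expect_gt(cc58, cc38)
})

test_that("a starved photon budget warns about the heart ROI", {
  ph <- calibrated_phantom()
  expect_warning(
    simulate_planar(ph, discovery_presets()$LEHR, standard_detector(),
                    fast_acq(total_photons = 500), "anterior", seed = 3),
    "heart ROI")
})
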