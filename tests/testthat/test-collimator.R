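# Collimator response model: attenuation tables, effective length,
# geometric resolution, septal path and penetration, emission spectrum.

test_that("attenuation coefficients decrease with energy for every material", {
  tab <- attenuation_table()
  for (m in unique(tab$material)) {
    sub <- tab[tab$material == m, ]
    sub <- sub[order(sub$energy_kev), ]
    expect_true(all(diff(sub$mu_over_rho_cm2_g) < 0), info = m)
  }
  expect_error(mu_linear("lead", 50), "outside")
  expect_error(mu_linear("pmma", 700), "outside")
})

test_that("effective length follows L - 2/mu and its limits", {
  megp <- discovery_presets()$MEGP
  mu <- mu_linear("lead", 159)
  expect_equal(effective_length(megp, 159), megp$length - 2 / mu)
  expect_gt(effective_length(megp, 159), 56)
  expect_lt(effective_length(megp, 159), 58)
  # opaque-septa limit: lower energy, larger mu, L_eff closer to L
  expect_gt(effective_length(megp, 100), effective_length(megp, 159))
  # additivity in L
  longer <- collimator(3.0, 1.05, 68)
  expect_equal(effective_length(longer, 159) - effective_length(megp, 159), 10)
  # transparent collimator is a domain error
  expect_error(effective_length(collimator(1.5, 0.2, 5), 600), "transparent")
})

test_that("geometric FWHM is the standard projection formula", {
  megp <- discovery_presets()$MEGP
  leff <- effective_length(megp, 159)
  expect_equal(geometric_fwhm(megp, 159, 100), 3.0 * (leff + 100) / leff,
               tolerance = 1e-12)
  expect_equal(geometric_fwhm(megp, 159, 100), 8.2, tolerance = 0.02)
  # source at the face: FWHM = d (within the effective-length correction)
  expect_gte(geometric_fwhm(megp, 159, 0), megp$hole_diameter)
  expect_lt(geometric_fwhm(megp, 159, 0), 1.05 * megp$hole_diameter)
  # linear in d
  wide <- collimator(6.0, 1.05, 58)
  expect_equal(geometric_fwhm(wide, 159, 75),
               2 * geometric_fwhm(megp, 159, 75))
  expect_error(geometric_fwhm(megp, 159, -1), ">= 0")
})

test_that("minimal septal path matches hand arithmetic", {
  expect_equal(septal_path_min(discovery_presets()$LEHR),
               35 * 0.2 / (2 * 1.5 + 0.2))
  expect_equal(septal_path_min(discovery_presets()$LEHR), 2.1875)
  expect_equal(septal_path_min(discovery_presets()$MEGP), 58 * 1.05 / 7.05)
  # vanishing septa
  expect_lt(septal_path_min(collimator(1.5, 1e-7, 35)), 1e-5)
})

test_that("septal penetration has the right limits and magnitudes", {
  lehr <- discovery_presets()$LEHR
  # oracle: table lookup + exponential with the 1.5 mean-path factor
  mu529 <- mu_linear("lead", 529)
  expect_equal(septal_penetration(lehr, 529),
               exp(-mu529 * 1.5 * 2.1875), tolerance = 1e-12)
  expect_gt(septal_penetration(lehr, 529), 0.3)
  expect_lt(septal_penetration(lehr, 159), 0.01)
  # transparent limit: mu -> 0 as the septa vanish
  expect_gt(septal_penetration(collimator(1.5, 1e-5, 35), 159), 0.999)
  expect_error(septal_penetration(lehr, 700), "outside")
})

test_that("penetration at 529 keV is monotone over the design grid", {
  g <- simulation_grid()
  p <- vapply(seq_len(nrow(g)), function(i)
    septal_penetration(collimator(g$hole_diameter[i], g$septal_thickness[i],
                                  g$length[i]), 529), numeric(1))
  g$p <- p
  # non-increasing in t at fixed (d, L); non-increasing in L at fixed
  # (d, t); non-decreasing in d at fixed (t, L) -- exhaustively
  for (sp in split(g, list(g$hole_diameter, g$length)))
    expect_true(all(diff(sp$p[order(sp$septal_thickness)]) <= 0))
  for (sp in split(g, list(g$hole_diameter, g$septal_thickness)))
    expect_true(all(diff(sp$p[order(sp$length)]) <= 0))
  for (sp in split(g, list(g$septal_thickness, g$length)))
    expect_true(all(diff(sp$p[order(sp$hole_diameter)]) >= 0))
})

test_that("commercial presets: LE collimators leak more than ME at 529 keV", {
  cp <- collimator_presets()
  for (cam in unique(cp$camera)) {
    sub <- cp[cp$camera == cam, ]
    p <- vapply(seq_len(nrow(sub)), function(i)
      septal_penetration(as_collimator(sub[i, ]), 529), numeric(1))
    expect_gt(min(p[sub$class == "LE"]), max(p[sub$class == "ME"]))
  }
  # all 18 presets pass the 1 % filter at 159 keV
  p159 <- vapply(seq_len(nrow(cp)), function(i)
    septal_penetration(as_collimator(cp[i, ]), 159), numeric(1))
  expect_true(all(p159 <= 0.01))
  expect_equal(nrow(cp), 18L)
})

test_that("emission spectrum matches the decay scheme", {
  sp <- i123_spectrum()
  expect_true(all(diff(sp$energy_kev) > 0))
  expect_true(all(sp$abundance > 0 & sp$abundance <= 1))
  in_window <- sp$energy_kev >= 159 * 0.9 & sp$energy_kev <= 159 * 1.1
  expect_equal(sum(in_window), 1L)
  expect_gt(sp$abundance[in_window], 0.8)
  he <- sum(sp$abundance[sp$energy_kev > 400])
  expect_equal(he, 0.025, tolerance = 0.4)   # 0.025 +/- 0.01
})

test_that("collimator constructor validates its inputs", {
  expect_error(collimator(0, 0.2, 35), "positive")
  expect_error(collimator(1.5, 0.2, 35, density = 10), "density")
})
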