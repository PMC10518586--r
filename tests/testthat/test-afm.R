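test_that("a planted breakthrough is recovered exactly at zero noise", {
  fc <- generate_force_curve(2e7, 2, breakthrough = c(200, 4.0), noise = 0)
  bt <- detect_breakthrough(fc)
  expect_true(bt$found)
  expect_equal(bt$yield_force, 200, tolerance = 1e-9)
  expect_equal(bt$thickness, 4.0, tolerance = 1e-9)
})

test_that("a smooth Hertzian curve yields no breakthrough", {
  fc <- generate_force_curve(2e7, 2, breakthrough = NULL, noise = 0)
  bt <- detect_breakthrough(fc)
  expect_false(bt$found)
  # a flat zero-force curve reports the lack of contact
  flat <- fc; flat$force[] <- 0
  expect_match(detect_breakthrough(flat)$diagnostic, "contact")
})

test_that("breakthrough detection tolerates noise across seeds", {
  hits <- 0
  for (s in 1:50) {
    fc <- generate_force_curve(2e7, 2, c(200, 4.0), noise = 5, seed = s)
    bt <- detect_breakthrough(fc)
    if (bt$found && abs(bt$thickness - 4.0) <= 0.2) hits <- hits + 1
  }
  expect_gte(hits, 48)  # >= 95% of runs within +-0.2 nm
})

test_that("breakthrough detection is invariant to a force offset", {
  fc <- generate_force_curve(2e7, 2, c(200, 4.0), noise = 0)
  shifted <- fc; shifted$force <- shifted$force + 37
  a <- detect_breakthrough(fc); b <- detect_breakthrough(shifted)
  expect_equal(b$thickness, a$thickness, tolerance = 1e-6)
  expect_equal(b$yield_force, a$yield_force, tolerance = 1e-6)
})

test_that("Hertz modulus is recovered exactly and scales linearly", {
  fc <- generate_force_curve(2e7, tip_radius = 2, noise = 0)
  fit <- fit_modulus(fc)
  expect_equal(fit$modulus, 2e7, tolerance = 1e-3 * 2e7 * 1e-3)

  doubled <- fc; doubled$force <- 2 * doubled$force
  expect_equal(fit_modulus(doubled)$modulus, 4e7, tolerance = 1)

  # the fit ignores post-breakthrough points: a rupture curve of the same
  # film gives the same modulus
  fcb <- generate_force_curve(2e7, 2, c(200, 4.0), noise = 0)
  expect_equal(fit_modulus(fcb)$modulus, 2e7, tolerance = 2e7 * 1e-6)
})

test_that("roughness is invariant to adding a constant or a plane", {
  g <- generate_height_map(c(32, 32), "gaussian_noise", sigma = 0.3, seed = 6)
  base <- roughness(g, n_regions = 1)
  tilt <- g
  tilt$heights <- tilt$heights + 3 +
    outer(1:32 * 0.05, 1:32 * (-0.02), "+")
  with_plane <- roughness(tilt, n_regions = 1)
  expect_equal(with_plane$Ra, base$Ra, tolerance = 1e-9)
  expect_equal(with_plane$rms, base$rms, tolerance = 1e-9)
})

test_that("region statistics match a direct-sum oracle", {
  g <- generate_height_map(c(32, 32), "gaussian_noise", sigma = 0.4, seed = 9)
  r <- roughness(g, n_regions = 1, detrend = "mean")
  z <- g$heights - mean(g$heights)
  expect_equal(r$Ra, sum(abs(z)) / length(z), tolerance = 1e-12)
  expect_equal(r$rms, sqrt(sum(z^2) / length(z)), tolerance = 1e-12)
})

test_that("random regions are seeded and fit inside the map", {
  g <- generate_height_map(c(64, 64), "gaussian_noise", sigma = 0.3, seed = 2)
  a <- roughness(g, n_regions = 4, region_size = 16, seed = 5)
  b <- roughness(g, n_regions = 4, region_size = 16, seed = 5)
  expect_identical(a$per_region, b$per_region)
  expect_error(roughness(g, region_size = 128), "larger than the map")
})

test_that("summaries report mean, standard error and contrast signs", {
  s <- summarize_measurements(list(control = c(1, 2, 3)))
  expect_equal(s$table$mean, 2)
  expect_equal(s$table$se, 0.5774, tolerance = 1e-4)
  expect_null(s$contrasts)

  one <- summarize_measurements(list(a = 5))
  expect_true(is.na(one$table$se))

  # planted ordering of system means reproduces contrast signs
  m <- summarize_measurements(list(control = c(2, 2.1, 1.9),
                                   up = c(3, 3.2), down = c(1, 0.8)))
  expect_identical(m$contrasts$sign, c(1, -1))
})
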