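test_that("a plain bilayer build echoes its construction parameters", {
  spec <- bilayer_spec(64, c(10, 10), head_plane_offset = 1.85,
                       positional_jitter_sigma = 0.03, seed = 11)
  traj <- build_trajectory(spec, 1)
  fr <- traj$frames[[1]]
  expect_equal(length(unique(fr$molecule_id[startsWith(fr$species, "LIPID")])),
               128)
  heads <- fr$positions[fr$species == "LIPID_HEAD", 3]
  expect_equal(sum(heads > 0), 64)
  expect_equal(sum(heads < 0), 64)
  # head beads at +-offset up to jitter (5 sigma band)
  expect_true(all(abs(abs(heads) - 1.85) < 5 * 0.03))
  # bead chains step toward the midplane with the configured spacing
  one <- fr$positions[fr$molecule_id == 1, 3]
  expect_equal(length(one), 11)
  expect_lt(max(abs(diff(sort(one)) - 0.12)), 5 * 0.03 * 2)
})

test_that("planted water wires are collinear with the requested spacing", {
  ws <- water_spec(c(2.3, 3.2), 0,
                   wire = wire_spec(8, spacing = 0.3, endpoints_z = c(-1, 1)))
  spec <- bilayer_spec(16, c(6, 6), water = ws,
                       positional_jitter_sigma = 0, seed = 3)
  traj <- build_trajectory(spec, 1)
  fr <- traj$frames[[1]]
  ids <- traj$manifest$wire$molecule_ids
  o <- fr$positions[fr$species == "WATER_O" & fr$molecule_id %in% ids, ]
  o <- o[order(o[, 3]), ]
  expect_equal(nrow(o), 8)
  expect_equal(range(o[, 3]), c(-1, 1))
  d <- sqrt(rowSums(diff(o)^2))
  expect_equal(d, rep(0.3, 7), tolerance = 1e-10)
  # lateral excursion stays within one spacing of the chain axis
  expect_lt(max(abs(o[, 1] - mean(o[, 1]))), 0.3)
})

test_that("the same spec and seed build bitwise-identical trajectories", {
  spec <- bilayer_spec(32, c(6, 6),
                       patch = thin_patch_spec(c(3, 3), 1.2, 1.35),
                       aggregate = aggregate_spec(6, c(3, 3), 0.5),
                       water = water_spec(c(2.3, 3.2), 40,
                                          wire = wire_spec(6, 0.3, c(-1, 1))),
                       flavonoid_count = 5, seed = 99)
  a <- build_trajectory(spec, 3)
  b <- build_trajectory(spec, 3)
  expect_identical(a$frames, b$frames)
  expect_identical(a$manifest, b$manifest)
})

test_that("impossible feature combinations fail validation by field name", {
  expect_error(bilayer_spec(16, c(6, 6), head_plane_offset = 0.5),
               "head_plane_offset")
  expect_error(
    bilayer_spec(16, c(6, 6),
                 water = water_spec(c(2.3, 9.9), 10), box_height = 7),
    "slab_bounds")
  expect_error(wire_spec(8, 0.3, c(0.5, 1.5)), "straddle")
  expect_error(thin_patch_spec(c(3, 3), -1, 1.2), "radius")
})

test_that("zero-noise SAXS generation equals the forward model exactly", {
  e <- edp_params(c(333, 293, 163, 250), c(0.45, 1.35, 2.2), c(0.25, 0.3, 0.25))
  m <- mct_params(10, 6.3, 0.1, 0.3)
  q <- seq(0.1, 4, by = 0.01)
  cv <- generate_saxs_curve(e, m, q, noise = 0, scale = 3, seed = 1)
  expect_lt(max(abs(cv$I - 3 * model_intensity(e, m, q)) /
                (3 * model_intensity(e, m, q))), 1e-12)
})

test_that("1% SAXS noise is reproducible and has the stated magnitude", {
  e <- edp_params(c(333, 293, 163, 250), c(0.45, 1.35, 2.2), c(0.25, 0.3, 0.25))
  m <- mct_params(10, 6.3, 0.1, 0.3)
  q <- seq(0.1, 4, by = 0.002)
  a <- generate_saxs_curve(e, m, q, noise = 0.01, seed = 5)
  b <- generate_saxs_curve(e, m, q, noise = 0.01, seed = 5)
  expect_identical(a$I, b$I)
  eps <- a$I / model_intensity(e, m, q) - 1
  # sample sd of the planted relative deviations ~ 1%
  expect_equal(sd(eps), 0.01, tolerance = 0.1)
})

test_that("a single-layer stack removes all Bragg structure from generated curves", {
  e <- edp_params(c(333, 293, 163, 250), c(0.45, 1.35, 2.2), c(0.25, 0.3, 0.25))
  m1 <- mct_params(1, 6.3, 0.1, 0.3)
  q <- seq(0.1, 4, by = 0.01)
  cv <- generate_saxs_curve(e, m1, q, noise = 0, seed = 1)
  expect_equal(cv$I, form_factor(e, q)^2 / q^2, tolerance = 1e-12)
})

test_that("hyperfine tables round-trip losslessly and reject bad rows", {
  tab <- data.frame(sample = "control", two_A_par_G = 50.116,
                    two_A_perp_G = 18.576)
  f <- withr::local_tempfile(fileext = ".csv")
  write_epr_table(tab, f)
  back <- read_epr_table(f)
  expect_identical(back$two_A_par_G, 50.116)
  expect_identical(back$two_A_perp_G, 18.576)

  empty <- tab[0, ]
  write_epr_table(empty, f)
  expect_equal(nrow(read_epr_table(f)), 0)

  expect_error(write_epr_table(
    data.frame(sample = "x", two_A_par_G = 10, two_A_perp_G = 12), f),
    "2A_par > 2A_perp")
  expect_error(write_epr_table(
    data.frame(sample = "x", two_A_par_G = NaN, two_A_perp_G = 2), f),
    "finite")
})

test_that("planted height-map statistics match their closed forms", {
  flat <- generate_height_map(c(16, 16), "flat")
  r <- roughness(flat, n_regions = 1)
  expect_equal(r$Ra, 0)
  expect_equal(r$rms, 0)

  # cosine phase over whole periods on a dense grid; mean detrend keeps the
  # closed forms exact up to O(1/m^2) sampling bias
  A <- 1.3
  hm <- generate_height_map(c(2, 4096), "sinusoid", amplitude = A,
                            period = 4096 * 0.1, phase = pi / 2, pixel = 0.1)
  r <- roughness(hm, n_regions = 1, detrend = "mean")
  expect_equal(r$Ra, 2 * A / pi, tolerance = 1e-6)
  expect_equal(r$rms, A / sqrt(2), tolerance = 1e-6)

  # law of large numbers: RMS of a Gaussian surface approaches sigma
  g <- generate_height_map(c(256, 256), "gaussian_noise", sigma = 0.35, seed = 8)
  r <- roughness(g, n_regions = 1, detrend = "mean")
  expect_equal(r$rms, 0.35, tolerance = 0.02)
})

test_that("force-curve generation is seeded and validates its inputs", {
  a <- generate_force_curve(2e7, 2, c(200, 4), noise = 5, seed = 12)
  b <- generate_force_curve(2e7, 2, c(200, 4), noise = 5, seed = 12)
  expect_identical(a$force, b$force)
  expect_error(generate_force_curve(-1, 2), "modulus")
  expect_error(generate_force_curve(2e7, 2, c(-200, 4)), "force")
})
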