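test_that("leaflet assignment splits a symmetric bilayer and is translation invariant", {
  fr <- simple_bilayer(64, box = c(10, 10, 7))
  lf <- assign_leaflets(fr)
  expect_equal(unname(lf$counts), c(64, 64))
  expect_equal(lf$midplane, 0, tolerance = 1e-9)

  shifted <- fr
  shifted$positions[, 3] <- shifted$positions[, 3] + 5
  lf2 <- assign_leaflets(shifted)
  expect_identical(lf2$assignment$leaflet, lf$assignment$leaflet)
  expect_equal(lf2$midplane, lf$midplane + 5)
})

test_that("leaflet assignment agrees with a k-means oracle on jittered bilayers", {
  for (seed in 1:5) {
    spec <- bilayer_spec(32, c(8, 8), positional_jitter_sigma = 0.08,
                         seed = seed)
    fr <- build_trajectory(spec, 1)$frames[[1]]
    lf <- assign_leaflets(fr)
    head <- fr$species == "LIPID_HEAD"
    hz <- tapply(fr$positions[head, 3], fr$molecule_id[head], mean)
    km <- stats::kmeans(as.numeric(hz), centers = 2, nstart = 5)
    upper_cl <- which.max(km$centers)
    oracle <- ifelse(km$cluster == upper_cl, "upper", "lower")
    got <- lf$assignment$leaflet[match(as.integer(names(hz)),
                                       lf$assignment$molecule)]
    expect_identical(got, unname(oracle))
  }
})

test_that("an ideal-gas frame yields a flat density profile at N/V", {
  set.seed(42)
  n <- 4000; box <- c(6, 6, 8)
  xyz <- cbind(runif(n) * 6, runif(n) * 6, (runif(n) - 0.5) * 8)
  fr <- point_frame(xyz, box)
  prof <- number_density_profile(mp_trajectory(list(fr)), "FLAV", 0.5)
  expected <- n / prod(box)
  # per-bin Poisson error
  sd_bin <- sqrt(n / length(prof$z)) / (6 * 6 * 0.5)
  expect_true(all(abs(prof$density - expected) < 4 * sd_bin))
})

test_that("density profiles conserve particle counts and reject empty selections", {
  traj <- build_trajectory(bilayer_spec(16, c(5, 5), seed = 2), 3)
  prof <- number_density_profile(traj, c("LIPID_HEAD", "LIPID_TAIL"), 0.13)
  binvol <- attr(prof, "bin_volume")
  expect_equal(sum(prof$density) * binvol, 16 * 2 * 11, tolerance = 1e-9)
  expect_error(number_density_profile(traj, "WATER_O", 0.1), "WATER_O")
})

test_that("a planted Gaussian z-distribution is recovered by the profile", {
  set.seed(7)
  n <- 20000; box <- c(6, 6, 8)
  z <- rnorm(n, 1.0, 0.2)
  z <- z[abs(z) < 4][1:15000]
  fr <- point_frame(cbind(runif(15000) * 6, runif(15000) * 6, z), box)
  prof <- number_density_profile(mp_trajectory(list(fr)), "FLAV", 0.1)
  expected <- 15000 * dnorm(prof$z, 1.0, 0.2) / (6 * 6)
  # sup-norm deviation, relative to the peak
  expect_lt(max(abs(prof$density - expected)) / max(expected), 0.05)
})

test_that("electron density shows head-group maxima above the midplane value", {
  traj <- build_trajectory(bilayer_spec(64, c(10, 10), seed = 5), 2)
  prof <- electron_density_profile(traj, bin_width = 0.2, symmetrize = TRUE)
  center <- prof$density[which.min(abs(prof$z))]
  upper_peak <- max(prof$density[prof$z > 0.5 & prof$z < 3])
  lower_peak <- max(prof$density[prof$z < -0.5 & prof$z > -3])
  expect_gt(upper_peak, center)
  expect_gt(lower_peak, center)
  # electron conservation
  expect_equal(sum(prof$density) * attr(prof, "bin_volume"),
               sum(traj$frames[[1]]$electrons), tolerance = 1e-9)
})

test_that("a single particle lands in one bin at electrons per bin volume", {
  fr <- mp_frame(matrix(c(1, 1, 0.05), 1), "DDA_O", 1L, c(4, 4, 6),
                 electrons = 15)
  # add two lipids so a midplane exists
  bl <- simple_bilayer(4, box = c(4, 4, 6))
  fr2 <- mp_frame(rbind(bl$positions, c(1, 1, 0.05)),
                  c(bl$species, "DDA_O"),
                  c(bl$molecule_id, 999L), c(4, 4, 6))
  prof <- electron_density_profile(mp_trajectory(list(fr2)), "DDA_O",
                                   bin_width = 0.2)
  expect_equal(sum(prof$density > 0), 1)
  expect_equal(max(prof$density), 8 / (4 * 4 * 0.2))
})

test_that("density maps localize a planted aggregate and conserve counts", {
  spec <- bilayer_spec(36, c(6, 6),
                       aggregate = aggregate_spec(6, c(2, 4), 0.15),
                       seed = 31)
  traj <- build_trajectory(spec, 4)
  dm <- density_map(traj, c("DDA_C", "DDA_O", "DDA_H"), "perpendicular",
                    voxel = 0.5, window = NULL)
  peak <- which(dm$map == max(dm$map), arr.ind = TRUE)[1, ]
  expect_lt(abs(dm$axis1[peak[1]] - 2), 1.0)
  expect_lt(abs(dm$axis2[peak[2]] - 4), 1.0)
  n_dda <- sum(startsWith(traj$frames[[1]]$species, "DDA"))
  expect_equal(sum(dm$map) * 0.5^2, n_dda, tolerance = 1e-9)
})
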