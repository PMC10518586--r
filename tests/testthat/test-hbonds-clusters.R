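test_that("a planted carboxyl dimer yields exactly the planted bond", {
  fr <- planted_dimer(oo = 0.28, angle = 175)
  hb <- detect_hbonds(fr)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 0.28, tolerance = 1e-12)
  expect_equal(hb$angle, 175, tolerance = 1e-9)
  expect_equal(hb$donor_molecule, 1L)
  expect_equal(hb$acceptor_molecule, 2L)

  # below the angle cutoff the same geometry is rejected
  bent <- planted_dimer(oo = 0.28, angle = 120)
  expect_equal(nrow(detect_hbonds(bent)), 0)
})

test_that("molecules beyond the distance cutoff give zero bonds", {
  fr <- planted_dimer(oo = 0.45, angle = 175)
  expect_equal(nrow(detect_hbonds(fr)), 0)
})

test_that("detection agrees exactly with all-pairs enumeration on aggregates", {
  for (seed in c(3, 14)) {
    spec <- bilayer_spec(9, c(6, 6),
                         aggregate = aggregate_spec(10, c(3, 3), 0.35,
                                                    carboxyl_pairing = 0.6),
                         seed = seed)
    fr <- build_trajectory(spec, 1)$frames[[1]]
    hb <- detect_hbonds(fr)
    oracle <- oracle_hbonds(fr)
    key <- function(d, h, a) paste(d, h, a)
    expect_setequal(key(hb$donor_atom, hb$hydrogen_atom, hb$acceptor_atom),
                    if (is.null(oracle)) character(0)
                    else key(oracle$donor_atom, oracle$hydrogen_atom,
                             oracle$acceptor_atom))
  }
})

test_that("planted bonds from the generator manifest are all detected", {
  spec <- bilayer_spec(16, c(8, 8),
                       aggregate = aggregate_spec(8, c(4, 4), 0.5,
                                                  carboxyl_pairing = 1),
                       seed = 23)
  traj <- build_trajectory(spec, 1)
  hb <- detect_hbonds(traj$frames[[1]])
  planted <- traj$manifest$aggregate$planted_bonds
  got <- paste(hb$donor_molecule, hb$acceptor_molecule)
  expect_true(all(paste(planted$donor_molecule,
                        planted$acceptor_molecule) %in% got))
})

test_that("missing hydrogens in the species set are flagged", {
  fr <- point_frame(rbind(c(1, 1, 0), c(2, 2, 0)), c(5, 5, 5))
  expect_error(detect_hbonds(fr, hydrogen_species = "DDA_H"), "hydrogens")
})

test_that("chained molecules form one cluster; isolated ones stay singletons", {
  # 10 DDA-like single-bead molecules chained 0.8 nm apart
  xyz <- cbind(seq(0.5, by = 0.8, length.out = 10), 1, 0)
  fr <- mp_frame(xyz, rep("DDA_C", 10), 1:10, c(10, 4, 4))
  cl <- molecule_clusters(fr, edge_rule = "com_distance", com_cutoff = 1.0)
  expect_equal(cl$sizes, 10L)
  expect_equal(sort(cl$clusters[[1]]), 1:10)

  far <- mp_frame(cbind(c(1, 4, 7), 1, 0), rep("DDA_C", 3), 1:3, c(9, 4, 4))
  cl2 <- molecule_clusters(far, edge_rule = "com_distance", com_cutoff = 1.0)
  expect_equal(cl2$sizes, c(1L, 1L, 1L))
})

test_that("cluster decomposition matches a union-find oracle on random graphs", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 30
    xyz <- cbind(runif(n) * 7, runif(n) * 7, (runif(n) - 0.5) * 4)
    fr <- mp_frame(xyz, rep("DDA_C", n), 1:n, c(7, 7, 8))
    cutoff <- runif(1, 0.8, 1.6)
    cl <- molecule_clusters(fr, edge_rule = "com_distance", com_cutoff = cutoff)
    edges <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum(min_img(xyz[i, ] - xyz[j, ], c(7, 7, 8))^2))
      if (d <= cutoff) edges <- rbind(edges, c(i, j))
    }
    oracle <- oracle_components(1:n, edges)
    canon <- function(cls) sort(vapply(cls, function(x)
      paste(sort(x), collapse = ","), character(1)))
    expect_identical(canon(cl$clusters), canon(oracle))
  }
})

test_that("clusters partition the selection and report the z-span", {
  spec <- bilayer_spec(16, c(8, 8),
                       aggregate = aggregate_spec(9, c(4, 4), 0.4,
                                                  z_span = 3.0),
                       seed = 5)
  traj <- build_trajectory(spec, 1)
  cl <- molecule_clusters(traj$frames[[1]])
  expect_equal(sum(cl$sizes), 9)
  expect_setequal(unlist(cl$clusters), traj$manifest$aggregate$molecule_ids)
  # every chain spans z_span, so the largest cluster must too
  expect_gte(cl$largest_z_span, 3.0 - 1e-9)
})

test_that("hydrogen-bond statistics reduce to direct arithmetic", {
  counts <- c(18L, 22L, 20L, 24L, 19L)
  m <- mean(counts)
  s_pop <- sqrt(mean((counts - m)^2))
  expect_equal(m, 20.6)
  expect_equal(s_pop, 2.154066, tolerance = 1e-6)

  # constant planted count across frames -> mean +- 0
  fr <- planted_dimer()
  traj <- mp_trajectory(list(fr, fr, fr, fr))
  st <- hbond_statistics(traj, window = NULL)
  expect_equal(st$mean, 1)
  expect_equal(st$sd, 0)

  # last-k window honored exactly: stats over the last 2 of 4 frames
  empty <- planted_dimer(oo = 0.45)
  mixed <- mp_trajectory(list(empty, empty, fr, fr))
  st2 <- hbond_statistics(mixed, window = c(0.5, 1))
  expect_identical(st2$per_frame, c(1L, 1L))

  one <- hbond_statistics(mp_trajectory(list(fr)), window = NULL)
  expect_true(is.na(one$sd))
  expect_match(one$note, "single frame")
})
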