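# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive (direct loops, no shared code with the package
# internals beyond the public constructors).

min_img <- function(d, L) d - L * round(d / L)

# O(N^2) all-pairs hydrogen-bond enumeration: for every hydrogen, find its
# covalently attached donor oxygen, then test every acceptor explicitly.
oracle_hbonds <- function(frame, dist_cutoff = 0.35, angle_cutoff = 150,
                          donor_species = "DDA_O", acceptor_species = "DDA_O",
                          hydrogen_species = c("DDA_H", "WATER_H"),
                          bond_cutoff = 0.12) {
  p <- frame$positions; box <- frame$box
  bonds <- NULL
  for (h in which(frame$species %in% hydrogen_species)) {
    best <- NA; bestd <- Inf
    for (d in which(frame$species %in% donor_species)) {
      if (frame$molecule_id[d] != frame$molecule_id[h]) next
      dd <- sqrt(sum(min_img(p[d, ] - p[h, ], box)^2))
      if (dd < bestd) { bestd <- dd; best <- d }
    }
    if (is.na(best) || bestd > bond_cutoff) next
    for (a in which(frame$species %in% acceptor_species)) {
      if (a == best) next
      if (frame$molecule_id[a] == frame$molecule_id[best]) next
      da <- sqrt(sum(min_img(p[a, ] - p[best, ], box)^2))
      if (da > dist_cutoff) next
      v1 <- min_img(p[best, ] - p[h, ], box)
      v2 <- min_img(p[a, ] - p[h, ], box)
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= angle_cutoff)
        bonds <- rbind(bonds, data.frame(donor_atom = best, hydrogen_atom = h,
                                         acceptor_atom = a, distance = da,
                                         angle = ang))
    }
  }
  bonds
}

# classic union-find connected components over molecule ids
oracle_components <- function(ids, edges) {
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (!is.null(edges) && nrow(edges))
    for (k in seq_len(nrow(edges))) {
      a <- find(match(edges[k, 1], ids)); b <- find(match(edges[k, 2], ids))
      if (a != b) parent[a] <- b
    }
  roots <- vapply(seq_along(ids), function(i) find(i), numeric(1))
  unname(split(ids, roots))
}

# direct per-cell thickness average over one frame
oracle_thickness_cell <- function(frame, cell) {
  lf <- assign_leaflets(frame)
  com <- molecule_com(frame)
  com <- com[com$family == "LIPID", ]
  com$leaflet <- lf$assignment$leaflet[match(com$molecule, lf$assignment$molecule)]
  nx <- ceiling(frame$box[1] / cell); ny <- ceiling(frame$box[2] / cell)
  out <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    inx <- floor((com$x %% frame$box[1]) / cell) + 1 == i &
           floor((com$y %% frame$box[2]) / cell) + 1 == j
    up <- com$z[inx & com$leaflet == "upper"]
    lo <- com$z[inx & com$leaflet == "lower"]
    if (length(up) && length(lo)) out[i, j] <- mean(up) - mean(lo)
  }
  out
}

# direct minimum-image pair histogram for the RDF
oracle_pair_counts <- function(xyz, box, r_max, bin_width, lateral = FALSE) {
  n <- nrow(xyz)
  counts <- numeric(ceiling(r_max / bin_width))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dims <- if (lateral) 1:2 else 1:3
    d <- sqrt(sum(min_img(xyz[i, dims] - xyz[j, dims], box[dims])^2))
    if (d < r_max) {
      b <- floor(d / bin_width) + 1
      counts[b] <- counts[b] + 1
    }
  }
  counts
}

# adaptive quadrature of the cosine transform of the excess density; the
# integrand is even and compactly supported in practice, so integrate the
# half line over a finite range where the contrast is non-negligible
oracle_form_factor <- function(edp, q) {
  L <- max(edp$R) + 12 * max(edp$sigma)
  vapply(q, function(qq)
    2 * stats::integrate(function(r) (edp_evaluate(edp, r) - edp$rho[1]) * cos(qq * r),
                         0, L, rel.tol = 1e-9, subdivisions = 1000)$value,
    numeric(1))
}

# minimal frame: n single-bead molecules of one species at given positions
point_frame <- function(xyz, box, species = "FLAV") {
  xyz <- as.matrix(xyz)
  mp_frame(xyz, rep(species, nrow(xyz)), seq_len(nrow(xyz)), box)
}

# two-lipid-plane bilayer frame with arbitrary extra particles
simple_bilayer <- function(n_per_leaflet = 16, box = c(6, 6, 7), offset = 1.85,
                           beads = 11, spacing = 0.12) {
  spec <- bilayer_spec(n_per_leaflet, box[1:2], offset, beads, spacing,
                       positional_jitter_sigma = 0, box_height = box[3],
                       seed = 1)
  build_trajectory(spec, 1)$frames[[1]]
}

# planted carboxyl dimer: two DDA-like molecules with one donor O-H facing
# one acceptor O at the requested geometry, far from everything else
planted_dimer <- function(oo = 0.28, angle = 175, box = c(6, 6, 6)) {
  r_oh <- 0.096
  th <- angle * pi / 180
  D <- c(2, 3, 0)
  H <- D + c(r_oh, 0, 0)
  h <- r_oh * cos(th) + sqrt(oo^2 - r_oh^2 * sin(th)^2)
  A <- H + h * c(-cos(th), sin(th), 0)
  # donor molecule: one C, donor O with H; acceptor molecule: one C, one O
  pos <- rbind(D + c(-0.15, 0, 0), D, H,
               A + c(0.15, 0, 0), A)
  mp_frame(pos,
           c("DDA_C", "DDA_O", "DDA_H", "DDA_C", "DDA_O"),
           c(1L, 1L, 1L, 2L, 2L), box)
}
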