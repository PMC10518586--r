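#' Build a synthetic bilayer trajectory with planted ground truth
#'
#' Constructs a coarse two-leaflet bilayer from a [bilayer_spec()]: lipids are
#' bead chains anchored at the leaflet head planes, optional planted features
#' (thinned patch, hydrogen-bonded DDA aggregate, bulk water with an optional
#' spanning water wire, flavonoid beads near the head region) are realized
#' exactly as specified, and a ground-truth manifest describing every planted
#' feature is attached to the result.
#'
#' Randomness: all draws come from one stream seeded with `spec$seed`, in a
#' fixed documented order (aggregate lateral placement, bulk water placement,
#' flavonoid placement, then per-frame lipid z jitter, upper leaflet before
#' lower, lipid-major bead-minor). The same spec and seed therefore give
#' bitwise-identical trajectories. Planted molecules (DDA, water, flavonoid)
#' are static across frames; only lipid jitter is redrawn per frame.
#'
#' @param spec a [bilayer_spec()].
#' @param n_frames number of frames (>= 1).
#' @return An [mp_trajectory] with an extra `manifest` element (also retrievable
#'   with `traj$manifest`) recording planted feature ground truth.
#' @export
build_trajectory <- function(spec, n_frames = 1) {
  stopifnot(inherits(spec, "mp_bilayer_spec"))
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(spec$seed)
  box <- c(spec$lateral_box, spec$box_height)

  lip <- .lipid_template(spec)
  static <- .static_particles(spec, box)   # consumes RNG draws (order documented)

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    lz <- lip$z
    if (spec$positional_jitter_sigma > 0)
      lz <- lz + stats::rnorm(length(lz), 0, spec$positional_jitter_sigma)
    pos <- rbind(cbind(lip$x, lip$y, lz), static$positions)
    frames[[f]] <- mp_frame(pos,
                            c(lip$species, static$species),
                            c(lip$molecule_id, static$molecule_id),
                            box)
  }
  traj <- mp_trajectory(frames, frame_interval = 1)
  traj$manifest <- c(list(
    seed = spec$seed,
    box = box,
    n_frames = n_frames,
    lipids = list(per_leaflet = spec$lipids_per_leaflet,
                  molecule_ids = sort(unique(lip$molecule_id)),
                  head_plane_offset = spec$head_plane_offset,
                  com_offset_below_head =
                    (spec$beads_per_lipid - 1) * spec$bead_spacing / 2,
                  patch_lipids = lip$patch_ids),
    patch = if (is.null(spec$patch)) NULL else unclass(spec$patch)
  ), static$manifest)
  traj
}

# deterministic lateral grid for one leaflet; first n cells of the smallest
# square grid that holds them
.leaflet_grid <- function(n, lateral_box) {
  g <- ceiling(sqrt(n))
  i <- (seq_len(n) - 1) %% g
  j <- (seq_len(n) - 1) %/% g
  cbind((i + 0.5) * lateral_box[1] / g, (j + 0.5) * lateral_box[2] / g)
}

.lipid_template <- function(spec) {
  n <- spec$lipids_per_leaflet
  grid <- .leaflet_grid(n, spec$lateral_box)
  nb <- spec$beads_per_lipid
  bead_off <- (seq_len(nb) - 1) * spec$bead_spacing  # toward midplane

  in_patch <- function(xy) {
    if (is.null(spec$patch)) return(rep(FALSE, nrow(xy)))
    d <- sqrt((xy[, 1] - spec$patch$center_xy[1])^2 +
              (xy[, 2] - spec$patch$center_xy[2])^2)
    d < spec$patch$radius
  }
  pin <- in_patch(grid)
  offset_of <- ifelse(pin, spec$patch$head_plane_offset_inside %||% NA,
                      spec$head_plane_offset)
  offset_of[is.na(offset_of)] <- spec$head_plane_offset

  x <- y <- z <- numeric(0); mol <- integer(0); sp <- character(0)
  patch_ids <- integer(0)
  mid <- 0L
  for (leaf in c(+1, -1)) {
    for (k in seq_len(n)) {
      mid <- mid + 1L
      if (pin[k]) patch_ids <- c(patch_ids, mid)
      x <- c(x, rep(grid[k, 1], nb))
      y <- c(y, rep(grid[k, 2], nb))
      z <- c(z, leaf * (offset_of[k] - bead_off))
      mol <- c(mol, rep(mid, nb))
      sp <- c(sp, c("LIPID_HEAD", rep("LIPID_TAIL", nb - 1)))
    }
  }
  list(x = x, y = y, z = z, molecule_id = mol, species = sp,
       patch_ids = patch_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DDA chain template: 12 backbone carbons along z, a carboxyl at each end.
# The hydroxyl (donor) oxygen sits on the +x side with its H pointing +x;
# the carbonyl (acceptor) oxygen on the -x side.
.dda_template <- function(z_span) {
  nc <- 12
  zc <- seq(-z_span / 2, z_span / 2, length.out = nc)
  r_oh <- 0.096
  pos <- rbind(cbind(0, 0, zc))                      # C1..C12
  sp <- rep("DDA_C", nc)
  for (ztip in c(zc[nc], zc[1])) {
    pos <- rbind(pos,
                 c(0.12, 0, ztip),                   # O donor (hydroxyl)
                 c(0.12 + r_oh, 0, ztip),            # H on donor O
                 c(-0.12, 0, ztip))                  # O acceptor (carbonyl)
    sp <- c(sp, "DDA_O", "DDA_H", "DDA_O")
  }
  list(pos = pos, species = sp,
       donor_O = nc + c(1L, 4L), donor_H = nc + c(2L, 5L),
       acceptor_O = nc + c(3L, 6L), r_oh = r_oh)
}

# lateral offset from a donor molecule base that places the partner's
# acceptor O at the planted O...O distance and D-H...A angle
.pair_offset <- function(tmpl, oo, angle_deg) {
  th <- angle_deg * pi / 180
  r <- tmpl$r_oh
  h <- r * cos(th) + sqrt(oo^2 - r^2 * sin(th)^2)   # law of cosines at H
  Dx <- 0.12; Hx <- 0.12 + r
  A <- c(Hx + h * (-cos(th)), h * sin(th))          # acceptor target (rel. donor base)
  c(A[1] - (-0.12), A[2])                           # partner base offset
}

.static_particles <- function(spec, box) {
  pos <- matrix(numeric(0), ncol = 3)
  sp <- character(0); mol <- integer(0)
  next_id <- 2L * spec$lipids_per_leaflet
  man <- list()

  # --- aggregate (draw order 1) ---
  agg <- spec$aggregate
  if (!is.null(agg)) {
    ctr <- agg$center_xy %||% (spec$lateral_box / 2)
    tmpl <- .dda_template(agg$z_span)
    n <- agg$n_dda
    n_pairs <- round(agg$carboxyl_pairing * (n %/% 2))
    base <- matrix(NA_real_, n, 2)
    paired_with <- rep(NA_integer_, n)
    k <- 1L
    np <- 0L
    while (k <= n) {
      base[k, ] <- ctr + stats::rnorm(2, 0, agg$lateral_sigma)
      if (np < n_pairs && k + 1L <= n) {
        base[k + 1L, ] <- base[k, ] +
          .pair_offset(tmpl, agg$oo_distance, agg$dha_angle)
        paired_with[k] <- k + 1L
        np <- np + 1L
        k <- k + 2L
      } else k <- k + 1L
    }
    dda_ids <- integer(n)
    planted <- NULL
    for (m in seq_len(n)) {
      next_id <- next_id + 1L
      dda_ids[m] <- next_id
      p <- tmpl$pos
      p[, 1] <- p[, 1] + base[m, 1]
      p[, 2] <- p[, 2] + base[m, 2]
      pos <- rbind(pos, p)
      sp <- c(sp, tmpl$species)
      mol <- c(mol, rep(next_id, nrow(p)))
    }
    for (m in which(!is.na(paired_with)))
      planted <- rbind(planted,
                       data.frame(donor_molecule = dda_ids[m],
                                  acceptor_molecule = dda_ids[paired_with[m]],
                                  end = c("top", "bottom"),
                                  oo_distance = agg$oo_distance,
                                  dha_angle = agg$dha_angle))
    man$aggregate <- list(molecule_ids = dda_ids, center_xy = ctr,
                          z_span = agg$z_span, planted_bonds = planted)
  }

  # --- bulk water (draw order 2) ---
  wat <- spec$water
  h1 <- c(0.0957, 0, 0); h2 <- c(-0.024, 0.0926, 0)  # rigid water geometry
  if (!is.null(wat) && wat$count > 0) {
    n <- wat$count
    side <- rep(c(1, -1), length.out = n)
    for (w in seq_len(n)) {
      next_id <- next_id + 1L
      xy <- stats::runif(2) * spec$lateral_box
      zz <- side[w] * stats::runif(1, wat$slab_bounds[1], wat$slab_bounds[2])
      o <- c(xy, zz)
      pos <- rbind(pos, o, o + h1, o + h2)
      sp <- c(sp, "WATER_O", "WATER_H", "WATER_H")
      mol <- c(mol, rep(next_id, 3))
    }
    man$bulk_water <- list(count = n, slab_bounds = wat$slab_bounds)
  }

  # --- water wire (deterministic, planted exactly) ---
  if (!is.null(wat) && !is.null(wat$wire)) {
    wr <- wat$wire
    ctr <- wr$center_xy %||% (spec$lateral_box / 2)
    nz <- wr$n_waters
    z <- seq(wr$endpoints_z[1], wr$endpoints_z[2], length.out = nz)
    dz <- diff(z)[1]
    # realize the requested 3D spacing by alternating lateral offsets when it
    # exceeds the vertical step; otherwise the chain is strictly vertical
    dx <- if (wr$spacing > dz) sqrt(wr$spacing^2 - dz^2) else 0
    xoff <- cumsum(c(0, rep_len(c(dx, -dx), nz - 1)))
    wire_ids <- integer(nz)
    for (w in seq_len(nz)) {
      next_id <- next_id + 1L
      wire_ids[w] <- next_id
      o <- c(ctr[1] + xoff[w], ctr[2], z[w])
      pos <- rbind(pos, o, o + h1, o + h2)
      sp <- c(sp, "WATER_O", "WATER_H", "WATER_H")
      mol <- c(mol, rep(next_id, 3))
    }
    man$wire <- list(molecule_ids = wire_ids, endpoints_z = wr$endpoints_z,
                     realized_spacing = max(wr$spacing, dz))
  }

  # --- flavonoids (draw order 3) ---
  if (spec$flavonoid_count > 0) {
    n <- spec$flavonoid_count
    side <- rep(c(1, -1), length.out = n)
    flav_ids <- integer(n)
    for (m in seq_len(n)) {
      next_id <- next_id + 1L
      flav_ids[m] <- next_id
      xy <- stats::runif(2) * spec$lateral_box
      pos <- rbind(pos, c(xy, side[m] * (spec$head_plane_offset - 0.3)))
      sp <- c(sp, "FLAV")
      mol <- c(mol, next_id)
    }
    man$flavonoids <- list(molecule_ids = flav_ids)
  }

  rownames(pos) <- NULL
  list(positions = pos, species = sp, molecule_id = mol, manifest = man)
}

#' Write a trajectory's ground-truth manifest as JSON
#'
#' @param traj trajectory from [build_trajectory()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(traj, path) {
  if (is.null(traj$manifest)) stop("trajectory has no manifest")
  jsonlite::write_json(traj$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
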