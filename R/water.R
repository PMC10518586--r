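#' Water penetration and water-wire detection
#'
#' For each frame: waters whose oxygen lies within the hydrophobic slab
#' (|z - midplane| < `z_cut`) are counted as penetrating; water oxygens are
#' linked into a graph under an O-O adjacency cutoff (minimum image), and a
#' connected component whose z-extent covers the whole slab
#' [-z_cut, +z_cut] is reported as a water wire - the onset of pore
#' formation. In a bilayer without planted defects water stays beyond the
#' polar region, so no penetrating waters and no wires are expected.
#'
#' @param traj an [mp_trajectory] containing waters.
#' @param z_cut half-width of the hydrophobic slab (nm); default 1.0.
#' @param oo_cutoff O-O adjacency cutoff (nm); default 0.35.
#' @param window fractional frame window; `NULL` = all frames.
#' @return list of class `mp_water_report`: `slab_halfwidth`,
#'   `penetrating_waters` (count per frame), `wire_present` (logical per
#'   frame), `wires` (per frame, list of molecule-id chains with z extents),
#'   `frames` (indices analyzed).
#' @export
water_analysis <- function(traj, z_cut = 1.0, oo_cutoff = 0.35, window = NULL) {
  idx <- .window_frames(traj, window)
  fr1 <- traj$frames[[idx[1]]]
  if (!any(fr1$species == "WATER_O")) stop("no waters in trajectory")
  heads <- fr1$species == "LIPID_HEAD"
  if (any(heads)) {
    z0 <- mean(fr1$positions[heads, 3])
    if (z_cut >= mean(abs(fr1$positions[heads, 3] - z0)))
      warning("z_cut reaches the head-bead planes; hydrophobic slab is not meaningful")
  }
  pen <- integer(length(idx))
  wire_present <- logical(length(idx))
  wires <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    fr <- traj$frames[[idx[k]]]
    z0 <- if (any(heads)) mean(fr$positions[fr$species == "LIPID_HEAD", 3]) else 0
    o <- which(fr$species == "WATER_O")
    z <- fr$positions[o, 3] - z0
    pen[k] <- sum(abs(z) < z_cut)
    if (length(o) >= 2) {
      comb <- utils::combn(length(o), 2)
      d <- .pair_distances(fr$positions[o, , drop = FALSE], fr$box)
      adj <- which(d <= oo_cutoff)
      g <- igraph::graph_from_data_frame(
        data.frame(from = comb[1, adj], to = comb[2, adj]),
        directed = FALSE, vertices = data.frame(name = seq_along(o)))
      comp <- igraph::components(g)
      found <- list()
      for (c_id in seq_len(comp$no)) {
        mem <- which(comp$membership == c_id)
        if (length(mem) < 2) next
        zmin <- min(z[mem]); zmax <- max(z[mem])
        if (zmin <= -z_cut + 1e-9 && zmax >= z_cut - 1e-9)
          found[[length(found) + 1L]] <- list(
            molecule_ids = sort(unique(fr$molecule_id[o[mem]])),
            z_extent = c(zmin, zmax))
      }
      wires[[k]] <- found
      wire_present[k] <- length(found) > 0
    }
  }
  structure(list(slab_halfwidth = z_cut, oo_cutoff = oo_cutoff,
                 penetrating_waters = pen, wire_present = wire_present,
                 wires = wires, frames = idx),
            class = "mp_water_report")
}
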