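#' Detect hydrogen bonds by geometric criteria
#'
#' A donor-H...acceptor triple is counted as a hydrogen bond when the
#' donor-acceptor distance is at most `dist_cutoff` and the D-H...A angle is
#' at least `angle_cutoff`. Donor atoms are those of the donor species that
#' carry a covalently attached hydrogen (same molecule, within
#' `bond_cutoff`); every atom of the acceptor species may accept. All
#' displacements use the minimum-image convention. Defaults follow the
#' common geometric criterion (0.35 nm, 150 degrees).
#'
#' @param frame an [mp_frame].
#' @param dist_cutoff maximum donor-acceptor distance (nm).
#' @param angle_cutoff minimum D-H...A angle (degrees).
#' @param donor_species species tags that can donate (must have attached H).
#' @param acceptor_species species tags that can accept.
#' @param hydrogen_species species tags treated as hydrogens.
#' @param bond_cutoff O-H covalent attachment distance (nm).
#' @param intermolecular_only drop bonds within one molecule (default TRUE).
#' @return data.frame of class `mp_hbonds` with columns donor_molecule,
#'   acceptor_molecule, donor_atom, hydrogen_atom, acceptor_atom (particle
#'   indices), distance (nm), angle (degrees).
#' @export
detect_hbonds <- function(frame, dist_cutoff = 0.35, angle_cutoff = 150,
                          donor_species = "DDA_O",
                          acceptor_species = "DDA_O",
                          hydrogen_species = c("DDA_H", "WATER_H"),
                          bond_cutoff = 0.12,
                          intermolecular_only = TRUE) {
  p <- frame$positions; box <- frame$box
  don_idx <- which(frame$species %in% donor_species)
  acc_idx <- which(frame$species %in% acceptor_species)
  h_idx <- which(frame$species %in% hydrogen_species)
  if (!length(h_idx))
    stop("no hydrogens of species ", paste(hydrogen_species, collapse = ", "),
         " in frame: donors cannot be identified")

  # attach each hydrogen to its nearest donor-species atom in the same molecule
  pairs <- NULL
  for (h in h_idx) {
    cand <- don_idx[frame$molecule_id[don_idx] == frame$molecule_id[h]]
    if (!length(cand)) next
    d <- sqrt(rowSums(minimum_image(p[cand, , drop = FALSE] -
                                    matrix(p[h, ], length(cand), 3, byrow = TRUE),
                                    box)^2))
    j <- which.min(d)
    if (d[j] <= bond_cutoff) pairs <- rbind(pairs, c(cand[j], h))
  }
  out <- data.frame(donor_molecule = integer(0), acceptor_molecule = integer(0),
                    donor_atom = integer(0), hydrogen_atom = integer(0),
                    acceptor_atom = integer(0), distance = numeric(0),
                    angle = numeric(0))
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      dID <- pairs[k, 1]; hID <- pairs[k, 2]
      acc <- acc_idx[acc_idx != dID]
      if (intermolecular_only)
        acc <- acc[frame$molecule_id[acc] != frame$molecule_id[dID]]
      if (!length(acc)) next
      dv <- minimum_image(p[acc, , drop = FALSE] -
                          matrix(p[dID, ], length(acc), 3, byrow = TRUE), box)
      da <- sqrt(rowSums(dv^2))
      close <- which(da <= dist_cutoff)
      for (a in close) {
        hd <- minimum_image(p[dID, ] - p[hID, ], box)
        ha <- minimum_image(p[acc[a], ] - p[hID, ], box)
        cosang <- sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang >= angle_cutoff)
          out <- rbind(out, data.frame(
            donor_molecule = frame$molecule_id[dID],
            acceptor_molecule = frame$molecule_id[acc[a]],
            donor_atom = dID, hydrogen_atom = hID, acceptor_atom = acc[a],
            distance = da[a], angle = ang))
      }
    }
  }
  class(out) <- c("mp_hbonds", "data.frame")
  out
}

#' Hydrogen-bond count statistics over a trajectory
#'
#' Counts intermolecular hydrogen bonds per frame (by default DDA-DDA
#' carboxyl bonds) over a frame window and reports the arithmetic mean and
#' population standard deviation, the form used for time-averaged bond
#' counts over the equilibrated part of a trajectory.
#'
#' @param traj an [mp_trajectory].
#' @param window fractional frame window; default `c(0.25, 1)` (the last
#'   three quarters, i.e. the equilibrated part).
#' @param ... criteria passed to [detect_hbonds()].
#' @return list with `per_frame` (integer counts), `mean`, `sd` (population;
#'   `NA` with a note when only one frame is in the window).
#' @export
hbond_statistics <- function(traj, window = c(0.25, 1), ...) {
  idx <- .window_frames(traj, window)
  counts <- vapply(idx, function(i)
    nrow(detect_hbonds(traj$frames[[i]], ...)), integer(1))
  m <- mean(counts)
  s <- if (length(counts) >= 2)
    sqrt(mean((counts - m)^2)) else NA_real_
  list(per_frame = counts, mean = m, sd = s,
       n_frames = length(counts),
       note = if (length(counts) < 2) "sd undefined for a single frame" else NULL)
}
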