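#' Center-of-mass radial distribution function
#'
#' Pairwise distances between molecule centers of mass under the
#' minimum-image convention, normalized by the ideal-gas expectation:
#' spherical shell volumes in `"3d"` mode, lateral annulus areas (x-y
#' distances only) in `"lateral"` mode. Strong aggregation shows up as
#' g(r) >> 1 at small r.
#'
#' @param traj an [mp_trajectory].
#' @param molecule_ids molecule ids to include (>= 2), e.g. the DDA ids from
#'   a manifest; alternatively pass `family` to select by species family.
#' @param family optional species family ("LIPID", "DDA", "WATER", "FLAV")
#'   used when `molecule_ids` is NULL.
#' @param mode `"3d"` or `"lateral"` (2D, x-y).
#' @param r_max maximum distance (nm); must not exceed half the smallest
#'   relevant box edge.
#' @param bin_width histogram bin width (nm).
#' @param window fractional frame window; `NULL` = all frames.
#' @return data.frame of class `mp_rdf`: r (bin centers), g; attribute
#'   `pair_counts` holds the raw per-bin pair counts summed over frames.
#' @export
com_rdf <- function(traj, molecule_ids = NULL, family = NULL,
                    mode = c("3d", "lateral"), r_max = NULL, bin_width = 0.05,
                    window = NULL) {
  mode <- match.arg(mode)
  box <- traj$frames[[1]]$box
  rel <- if (mode == "3d") box else box[1:2]
  if (is.null(r_max)) r_max <- min(rel) / 2
  if (r_max > min(rel) / 2 + 1e-9)
    stop("r_max exceeds half the smallest box edge (", min(rel) / 2, " nm)")
  idx <- .window_frames(traj, window)
  nb <- ceiling(r_max / bin_width)
  counts <- numeric(nb)
  npairs_tot <- 0
  n_sel <- NULL
  for (i in idx) {
    fr <- traj$frames[[i]]
    com <- molecule_com(fr)
    if (!is.null(molecule_ids)) com <- com[com$molecule %in% molecule_ids, ]
    else if (!is.null(family)) com <- com[com$family == family, ]
    if (nrow(com) < 2) stop("need at least 2 molecules selected")
    n_sel <- nrow(com)
    d <- .pair_distances(as.matrix(com[, c("x", "y", "z")]), box,
                         dims = if (mode == "3d") 1:3 else 1:2)
    d <- d[d < r_max]
    if (length(d)) {
      b <- floor(d / bin_width) + 1
      counts <- counts + tabulate(b, nbins = nb)
    }
    npairs_tot <- npairs_tot + n_sel * (n_sel - 1) / 2
  }
  edges <- seq(0, nb * bin_width, by = bin_width)
  shell <- if (mode == "3d") 4 / 3 * pi * diff(edges^3) else pi * diff(edges^2)
  vol <- if (mode == "3d") prod(box) else prod(box[1:2])
  expected <- npairs_tot * shell / vol     # ideal-gas pairs per bin
  g <- ifelse(expected > 0, counts / expected, 0)
  out <- data.frame(r = (edges[-1] + edges[-(nb + 1)]) / 2, g = g)
  attr(out, "pair_counts") <- counts
  attr(out, "mode") <- mode
  class(out) <- c("mp_rdf", "data.frame")
  out
}
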