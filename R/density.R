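#' Number density profile along the bilayer normal
#'
#' Per-frame histograms of particle z, recentred on the per-frame midplane
#' (mean lipid-head z), divided by the bin volume (lateral area x bin width)
#' and averaged over the selected frames. Bins cover the full box height so
#' that the profile integrates back to the mean particle count.
#'
#' @param traj an [mp_trajectory].
#' @param species character vector of species tags to count.
#' @param bin_width bin width (nm, > 0).
#' @param window fractional frame window, e.g. `c(0.25, 1)` for the last 75%;
#'   `NULL` uses all frames.
#' @return data.frame of class `mp_density_profile`: z (bin centers, nm
#'   relative to the midplane), density (nm^-3); attributes `bin_edges`,
#'   `n_frames_averaged`, `bin_volume`.
#' @export
number_density_profile <- function(traj, species, bin_width = 0.1,
                                   window = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  idx <- .window_frames(traj, window)
  sel0 <- traj$frames[[1]]$species %in% species
  if (!any(sel0)) stop("no particles of species: ", paste(species, collapse = ", "))
  .z_profile(traj, idx, sel0, bin_width, weights = NULL)
}

#' Electron density profile from trajectory frames
#'
#' Same histogram machinery as [number_density_profile()], weighted by the
#' per-particle electron count; units e/nm^3. With `symmetrize = TRUE` the
#' profile is averaged with its mirror image about the midplane, as is
#' conventional when comparing with scattering-derived profiles.
#'
#' @inheritParams number_density_profile
#' @param species species to include; default all particles.
#' @param symmetrize average the profile with its z -> -z mirror.
#' @return data.frame as in [number_density_profile()], density in e/nm^3.
#' @export
electron_density_profile <- function(traj, species = SPECIES, bin_width = 0.1,
                                     window = NULL, symmetrize = FALSE) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  idx <- .window_frames(traj, window)
  sel0 <- traj$frames[[1]]$species %in% species
  prof <- .z_profile(traj, idx, sel0, bin_width,
                     weights = function(fr) fr$electrons)
  if (symmetrize) prof$density <- (prof$density + rev(prof$density)) / 2
  prof
}

.z_profile <- function(traj, idx, sel, bin_width, weights = NULL) {
  Lz <- traj$frames[[1]]$box[3]
  area <- prod(traj$frames[[1]]$box[1:2])
  nb <- ceiling(Lz / bin_width)
  edges <- seq(-nb * bin_width / 2, nb * bin_width / 2, by = bin_width)
  acc <- numeric(nb)
  for (i in idx) {
    fr <- traj$frames[[i]]
    z0 <- mean(fr$positions[fr$species == "LIPID_HEAD", 3])
    if (is.nan(z0)) z0 <- 0  # no lipids: keep absolute z
    z <- fr$positions[sel, 3] - z0
    z <- ((z + nb * bin_width / 2) %% (nb * bin_width)) - nb * bin_width / 2
    bin <- pmin(pmax(floor((z - edges[1]) / bin_width) + 1, 1), nb)
    w <- if (is.null(weights)) rep(1, length(z)) else weights(fr)[sel]
    acc <- acc + as.numeric(tapply(w, factor(bin, levels = seq_len(nb)), sum,
                                   default = 0))
  }
  dens <- acc / length(idx) / (area * bin_width)
  out <- data.frame(z = (edges[-1] + edges[-length(edges)]) / 2,
                    density = dens)
  attr(out, "bin_edges") <- edges
  attr(out, "n_frames_averaged") <- length(idx)
  attr(out, "bin_volume") <- area * bin_width
  class(out) <- c("mp_density_profile", "data.frame")
  out
}

#' Time-averaged lateral/transverse density map
#'
#' Accumulates a 3D voxel histogram of the selected species over the frame
#' window and projects it onto a plane: `projection = "perpendicular"` views
#' the bilayer along its normal (an x-y map, integrated over z),
#' `projection = "parallel"` views it from the side (an x-z map, integrated
#' over y). Values are projected densities in nm^-2; they integrate over the
#' map (value x cell area) to the mean particle count.
#'
#' @param traj an [mp_trajectory].
#' @param species species tags to include.
#' @param projection `"perpendicular"` (x-y map) or `"parallel"` (x-z map).
#' @param voxel voxel edge length (nm).
#' @param window fractional frame window; default `c(0.75, 1)` (the last
#'   quarter of the trajectory, the convention used for localization maps).
#' @return list of class `mp_density_map`: `map` (matrix, nm^-2), `axis1`,
#'   `axis2` (cell centers, nm), `projection`, `n_frames_averaged`.
#' @export
density_map <- function(traj, species, projection = c("perpendicular", "parallel"),
                        voxel = 0.25, window = c(0.75, 1)) {
  projection <- match.arg(projection)
  box <- traj$frames[[1]]$box
  if (voxel <= 0 || voxel > min(box)) stop("voxel must be positive and fit in the box")
  idx <- .window_frames(traj, window)
  sel <- traj$frames[[1]]$species %in% species
  if (!any(sel)) stop("no particles of species: ", paste(species, collapse = ", "))
  dims <- if (projection == "perpendicular") c(1, 2) else c(1, 3)
  n1 <- ceiling(box[dims[1]] / voxel); n2 <- ceiling(box[dims[2]] / voxel)
  acc <- matrix(0, n1, n2)
  for (i in idx) {
    fr <- traj$frames[[i]]
    p <- fr$positions[sel, , drop = FALSE]
    a <- p[, dims[1]] %% box[dims[1]]
    b <- if (dims[2] == 3) (p[, 3] + box[3] / 2) %% box[3] else p[, 2] %% box[2]
    i1 <- pmin(floor(a / voxel) + 1, n1)
    i2 <- pmin(floor(b / voxel) + 1, n2)
    for (k in seq_along(i1)) acc[i1[k], i2[k]] <- acc[i1[k], i2[k]] + 1
  }
  map <- acc / length(idx) / voxel^2
  ax2 <- (seq_len(n2) - 0.5) * voxel
  if (dims[2] == 3) ax2 <- ax2 - box[3] / 2
  structure(list(map = map,
                 axis1 = (seq_len(n1) - 0.5) * voxel,
                 axis2 = ax2,
                 projection = projection, voxel = voxel,
                 n_frames_averaged = length(idx)),
            class = "mp_density_map")
}
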