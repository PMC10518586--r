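#' Lateral map of inter-leaflet center-of-mass distance
#'
#' For each lateral grid cell, the mean z of upper-leaflet lipid centers of
#' mass minus the mean z of lower-leaflet ones, accumulated over the frame
#' window. Lipids are assigned to cells by their center-of-mass x-y position.
#' Cells lacking lipids in either leaflet over the whole window are flagged
#' (`NA` distance, `defined = FALSE`), never silently zero. A locally thinned
#' bilayer shows up as a patch of reduced distance.
#'
#' @param traj an [mp_trajectory].
#' @param cell lateral cell edge length (nm).
#' @param window fractional frame window; default `c(0.75, 1)` (last quarter,
#'   the convention used for localization maps); `NULL` = all frames.
#' @return list of class `mp_thickness_map`: `distance` (matrix, nm; NA where
#'   undefined), `defined` (logical matrix), `occupancy` (mean lipid count
#'   per cell per frame), `x`, `y` (cell centers, nm), `cell`.
#' @export
interleaflet_distance_map <- function(traj, cell = 0.5, window = c(0.75, 1)) {
  if (cell <= 0) stop("cell must be > 0")
  box <- traj$frames[[1]]$box
  nx <- ceiling(box[1] / cell); ny <- ceiling(box[2] / cell)
  idx <- .window_frames(traj, window)
  sum_up <- cnt_up <- sum_lo <- cnt_lo <- matrix(0, nx, ny)
  for (i in idx) {
    fr <- traj$frames[[i]]
    lf <- assign_leaflets(fr)
    com <- molecule_com(fr)
    com <- com[com$family == "LIPID", ]
    com$leaflet <- lf$assignment$leaflet[match(com$molecule,
                                               lf$assignment$molecule)]
    ix <- pmin(floor((com$x %% box[1]) / cell) + 1, nx)
    iy <- pmin(floor((com$y %% box[2]) / cell) + 1, ny)
    for (k in seq_len(nrow(com))) {
      if (com$leaflet[k] == "upper") {
        sum_up[ix[k], iy[k]] <- sum_up[ix[k], iy[k]] + com$z[k]
        cnt_up[ix[k], iy[k]] <- cnt_up[ix[k], iy[k]] + 1
      } else {
        sum_lo[ix[k], iy[k]] <- sum_lo[ix[k], iy[k]] + com$z[k]
        cnt_lo[ix[k], iy[k]] <- cnt_lo[ix[k], iy[k]] + 1
      }
    }
  }
  defined <- cnt_up > 0 & cnt_lo > 0
  dist <- matrix(NA_real_, nx, ny)
  dist[defined] <- sum_up[defined] / cnt_up[defined] -
                   sum_lo[defined] / cnt_lo[defined]
  structure(list(distance = dist, defined = defined,
                 occupancy = (cnt_up + cnt_lo) / length(idx),
                 x = (seq_len(nx) - 0.5) * cell,
                 y = (seq_len(ny) - 0.5) * cell,
                 cell = cell, n_frames_averaged = length(idx)),
            class = "mp_thickness_map")
}

#' Summarize a thickness map inside/outside a circular patch
#'
#' Convenience accessor for planted-patch experiments: mean map distance over
#' defined cells whose centers lie inside (and outside) a circle.
#'
#' @param tmap result of [interleaflet_distance_map()].
#' @param center_xy circle center (nm).
#' @param radius circle radius (nm).
#' @return list with `inside`, `outside` (mean nm), `n_inside`, `n_outside`.
#' @export
thickness_patch_contrast <- function(tmap, center_xy, radius) {
  cx <- outer(tmap$x, rep(1, length(tmap$y)))
  cy <- outer(rep(1, length(tmap$x)), tmap$y)
  inside <- sqrt((cx - center_xy[1])^2 + (cy - center_xy[2])^2) < radius
  ok <- tmap$defined
  list(inside = mean(tmap$distance[inside & ok]),
       outside = mean(tmap$distance[!inside & ok]),
       n_inside = sum(inside & ok), n_outside = sum(!inside & ok))
}
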