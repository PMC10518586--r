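#' Thinned-patch specification
#'
#' Describes a circular lateral region in which the head-bead planes sit
#' closer to the midplane than in the rest of the bilayer, emulating local
#' thinning under an aggregate.
#'
#' @param center_xy lateral center (nm, length 2).
#' @param radius patch radius (nm, > 0).
#' @param head_plane_offset_inside |z| of the head-bead plane inside the
#'   patch (nm); must be smaller than the global offset.
#' @return `mp_thin_patch_spec` list.
#' @export
thin_patch_spec <- function(center_xy, radius, head_plane_offset_inside) {
  if (radius <= 0) stop("patch radius must be > 0")
  if (head_plane_offset_inside <= 0) stop("head_plane_offset_inside must be > 0")
  structure(list(center_xy = as.numeric(center_xy), radius = radius,
                 head_plane_offset_inside = head_plane_offset_inside),
            class = "mp_thin_patch_spec")
}

#' DDA aggregate specification
#'
#' A laterally localized cluster of dicarboxylic-acid molecules spanning the
#' hydrophobic core, with a configurable fraction of carboxyl pairs planted
#' in hydrogen-bond geometry.
#'
#' @param n_dda number of DDA molecules.
#' @param center_xy lateral center of the aggregate (nm).
#' @param lateral_sigma lateral Gaussian spread of molecule axes (nm).
#' @param carboxyl_pairing fraction in [0, 1] of consecutive DDA pairs placed
#'   with donor-acceptor carboxyls in hydrogen-bond geometry.
#' @param oo_distance planted donor-acceptor O...O distance (nm).
#' @param dha_angle planted D-H...A angle (degrees).
#' @param z_span vertical extent of each DDA chain (nm, > 0).
#' @return `mp_aggregate_spec` list.
#' @export
aggregate_spec <- function(n_dda, center_xy = NULL, lateral_sigma = 0.5,
                           carboxyl_pairing = 1, oo_distance = 0.28,
                           dha_angle = 175, z_span = 3.0) {
  if (n_dda < 1) stop("n_dda must be >= 1")
  if (carboxyl_pairing < 0 || carboxyl_pairing > 1)
    stop("carboxyl_pairing must lie in [0, 1]")
  if (z_span <= 0) stop("z_span must be > 0")
  structure(list(n_dda = as.integer(n_dda), center_xy = center_xy,
                 lateral_sigma = lateral_sigma,
                 carboxyl_pairing = carboxyl_pairing,
                 oo_distance = oo_distance, dha_angle = dha_angle,
                 z_span = z_span),
            class = "mp_aggregate_spec")
}

#' Water-wire specification
#'
#' A chain of water molecules planted collinearly through the hydrophobic
#' slab, connected under the O-O adjacency cutoff used by wire detection.
#'
#' @param n_waters chain length.
#' @param spacing consecutive O-O distance (nm); must stay below the
#'   detection adjacency cutoff for the wire to be recoverable.
#' @param endpoints_z z of the two chain ends (nm); must straddle the
#'   midplane.
#' @param center_xy lateral position of the (vertical) chain; defaults to the
#'   box center.
#' @return `mp_wire_spec` list.
#' @export
wire_spec <- function(n_waters = 8, spacing = 0.28, endpoints_z = c(-1, 1),
                      center_xy = NULL) {
  if (n_waters < 2) stop("a wire needs at least 2 waters")
  if (spacing <= 0) stop("spacing must be > 0")
  endpoints_z <- sort(as.numeric(endpoints_z))
  if (!(endpoints_z[1] < 0 && endpoints_z[2] > 0))
    stop("endpoints_z must straddle the midplane (one negative, one positive)")
  structure(list(n_waters = as.integer(n_waters), spacing = spacing,
                 endpoints_z = endpoints_z, center_xy = center_xy),
            class = "mp_wire_spec")
}

#' Bulk-water specification
#'
#' @param slab_bounds |z| range (nm, length 2) occupied by bulk water on each
#'   side of the bilayer.
#' @param count total number of bulk water molecules (split between sides).
#' @param wire optional [wire_spec()].
#' @return `mp_water_spec` list.
#' @export
water_spec <- function(slab_bounds, count, wire = NULL) {
  slab_bounds <- sort(as.numeric(slab_bounds))
  if (length(slab_bounds) != 2 || slab_bounds[1] < 0)
    stop("slab_bounds must be two non-negative |z| values")
  if (count < 0) stop("count must be >= 0")
  if (!is.null(wire) && !inherits(wire, "mp_wire_spec"))
    stop("wire must be built with wire_spec()")
  structure(list(slab_bounds = slab_bounds, count = as.integer(count),
                 wire = wire),
            class = "mp_water_spec")
}

#' Synthetic bilayer specification
#'
#' Defines a two-leaflet coarse bilayer: each lipid is a bead chain whose
#' head bead sits on the leaflet head plane at `|z| = head_plane_offset`
#' (or the patch offset inside a thinned patch), with `beads_per_lipid`
#' beads stepping `bead_spacing` toward the midplane. With equal bead masses
#' the lipid center of mass sits `(beads_per_lipid - 1) * bead_spacing / 2`
#' below the head bead, so center-of-mass thickness analyses do not simply
#' echo the head plane. Gaussian jitter of standard deviation
#' `positional_jitter_sigma` is applied to the z coordinate of every lipid
#' bead; planted features (patch membership, aggregate geometry, wire) are
#' realized exactly.
#'
#' @param lipids_per_leaflet lipids per leaflet (>= 1).
#' @param lateral_box lateral box edge lengths (nm, length 2).
#' @param head_plane_offset |z| of the head-bead planes (nm).
#' @param beads_per_lipid beads in each lipid chain.
#' @param bead_spacing spacing between consecutive beads (nm).
#' @param positional_jitter_sigma Gaussian sigma for bead z jitter (nm, >= 0).
#' @param patch optional [thin_patch_spec()].
#' @param aggregate optional [aggregate_spec()].
#' @param water optional [water_spec()].
#' @param flavonoid_count number of single-bead flavonoid particles placed
#'   near the head planes.
#' @param box_height box length along z (nm); default leaves 1.5 nm of
#'   head-room above each head plane.
#' @param seed integer seed controlling all randomness of the build.
#' @return `mp_bilayer_spec` list.
#' @export
bilayer_spec <- function(lipids_per_leaflet = 64,
                         lateral_box = c(6.2, 6.2),
                         head_plane_offset = 1.85,
                         beads_per_lipid = 11,
                         bead_spacing = 0.12,
                         positional_jitter_sigma = 0.05,
                         patch = NULL, aggregate = NULL, water = NULL,
                         flavonoid_count = 0,
                         box_height = NULL,
                         seed = 1L) {
  if (lipids_per_leaflet < 1) stop("lipids_per_leaflet must be >= 1")
  lateral_box <- as.numeric(lateral_box)
  if (length(lateral_box) != 2 || any(lateral_box <= 0))
    stop("lateral_box must be two positive lengths")
  if (positional_jitter_sigma < 0) stop("positional_jitter_sigma must be >= 0")
  if (head_plane_offset <= (beads_per_lipid - 1) * bead_spacing / 2)
    stop("head_plane_offset must exceed half the chain length ",
         "((beads_per_lipid - 1) * bead_spacing / 2)")
  if (!is.null(patch)) {
    if (!inherits(patch, "mp_thin_patch_spec")) stop("patch must come from thin_patch_spec()")
    if (patch$head_plane_offset_inside >= head_plane_offset)
      stop("patch head_plane_offset_inside must be below the global head_plane_offset")
    if (is.null(patch$center_xy)) patch$center_xy <- lateral_box / 2
  }
  if (!is.null(aggregate) && !inherits(aggregate, "mp_aggregate_spec"))
    stop("aggregate must come from aggregate_spec()")
  if (!is.null(water) && !inherits(water, "mp_water_spec"))
    stop("water must come from water_spec()")
  if (is.null(box_height)) box_height <- 2 * (head_plane_offset + 1.5)
  if (!is.null(water)) {
    if (water$slab_bounds[2] > box_height / 2)
      stop("water slab_bounds exceed box_height/2")
    if (!is.null(water$wire)) {
      w <- water$wire
      if (min(w$endpoints_z) < -box_height / 2 || max(w$endpoints_z) > box_height / 2)
        stop("wire endpoints_z outside the box")
    }
  }
  structure(list(lipids_per_leaflet = as.integer(lipids_per_leaflet),
                 lateral_box = lateral_box,
                 head_plane_offset = head_plane_offset,
                 beads_per_lipid = as.integer(beads_per_lipid),
                 bead_spacing = bead_spacing,
                 positional_jitter_sigma = positional_jitter_sigma,
                 patch = patch, aggregate = aggregate, water = water,
                 flavonoid_count = as.integer(flavonoid_count),
                 box_height = box_height,
                 seed = as.integer(seed)),
            class = "mp_bilayer_spec")
}
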