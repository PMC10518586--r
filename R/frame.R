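#' Particle species recognised by the package
#'
#' Coarse-grained species tags used throughout: lipid head and tail beads,
#' dicarboxylic-acid (DDA) carbon/oxygen/hydroxyl-hydrogen beads, water oxygen
#' and hydrogen, and a single flavonoid bead.
#'
#' @format Character vector of the eight valid species tags.
#' @export
SPECIES <- c("LIPID_HEAD", "LIPID_TAIL", "DDA_C", "DDA_O", "DDA_H",
             "WATER_O", "WATER_H", "FLAV")

# Electron counts per coarse bead. The head bead stands for the
# phosphate/choline region (electron rich), tails for CH2/CH3 groups; values
# only need the right contrast for electron-density profiles, not atomistic
# bookkeeping.
.default_electrons <- c(
  LIPID_HEAD = 50, LIPID_TAIL = 8,
  DDA_C = 6, DDA_O = 8, DDA_H = 1,
  WATER_O = 8, WATER_H = 1,
  FLAV = 120
)

#' Construct a single trajectory frame
#'
#' A frame holds particle coordinates (nm) in an orthorhombic box together
#' with a species tag, a molecule id and an electron count per particle.
#'
#' @param positions numeric matrix, n x 3, coordinates in nm.
#' @param species character vector of tags from [SPECIES].
#' @param molecule_id integer vector; all particles of one molecule share an id.
#' @param box numeric length-3 orthorhombic box edge lengths (nm).
#' @param electrons optional numeric vector of electron counts per particle;
#'   defaults to a per-species table.
#' @return An object of class `mp_frame`.
#' @export
mp_frame <- function(positions, species, molecule_id, box, electrons = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  species <- as.character(species)
  molecule_id <- as.integer(molecule_id)
  if (length(species) != n || length(molecule_id) != n)
    stop("species and molecule_id must match nrow(positions)")
  bad <- setdiff(unique(species), SPECIES)
  if (length(bad))
    stop("unknown species tag(s): ", paste(bad, collapse = ", "))
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive lengths (nm)")
  if (is.null(electrons)) electrons <- unname(.default_electrons[species])
  electrons <- as.numeric(electrons)
  if (length(electrons) != n || any(electrons < 1))
    stop("electrons must be >= 1 per particle")
  # every molecule id must map to a single species family
  fam <- .species_family(species)
  if (anyNA(fam)) stop("internal: unmapped species family")
  mixed <- tapply(fam, molecule_id, function(f) length(unique(f)) > 1)
  if (any(mixed))
    stop("molecule id(s) span multiple species families: ",
         paste(names(mixed)[mixed], collapse = ", "))
  structure(list(positions = positions, species = species,
                 molecule_id = molecule_id, electrons = electrons, box = box),
            class = "mp_frame")
}

.species_family <- function(species) {
  c(LIPID_HEAD = "LIPID", LIPID_TAIL = "LIPID",
    DDA_C = "DDA", DDA_O = "DDA", DDA_H = "DDA",
    WATER_O = "WATER", WATER_H = "WATER", FLAV = "FLAV")[species]
}

#' @export
print.mp_frame <- function(x, ...) {
  cat(sprintf("<mp_frame> %d particles, %d molecules, box %.3f x %.3f x %.3f nm\n",
              nrow(x$positions), length(unique(x$molecule_id)),
              x$box[1], x$box[2], x$box[3]))
  tab <- table(x$species)
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' @param frames list of [mp_frame] objects with identical particle count,
#'   ordering and species.
#' @param frame_interval time between frames in ns (metadata only).
#' @return An object of class `mp_trajectory`.
#' @export
mp_trajectory <- function(frames, frame_interval = 1) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "mp_frame")))
    stop("all frames must be mp_frame objects")
  n0 <- nrow(frames[[1]]$positions)
  sp0 <- frames[[1]]$species
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$positions) != n0 || !identical(frames[[i]]$species, sp0))
      stop("frame ", i, " differs in particle count or ordering")
  }
  structure(list(frames = frames, frame_interval = as.numeric(frame_interval)),
            class = "mp_trajectory")
}

#' @export
print.mp_trajectory <- function(x, ...) {
  cat(sprintf("<mp_trajectory> %d frame(s) x %d particles, interval %g ns\n",
              length(x$frames), nrow(x$frames[[1]]$positions), x$frame_interval))
  invisible(x)
}

#' @export
length.mp_trajectory <- function(x) length(x$frames)

#' Minimum-image displacement components
#'
#' @param d numeric vector or matrix of raw coordinate differences (nm).
#' @param box box edge length(s) matching the columns of `d`.
#' @return Differences folded into (-box/2, box/2].
#' @export
minimum_image <- function(d, box) {
  if (is.matrix(d)) {
    for (k in seq_len(ncol(d))) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  } else {
    d - box * round(d / box)
  }
}

# all pairwise minimum-image distances among rows of xyz (k columns used)
.pair_distances <- function(xyz, box, dims = seq_len(ncol(xyz))) {
  n <- nrow(xyz)
  if (n < 2) return(numeric(0))
  idx <- utils::combn(n, 2)
  d2 <- 0
  for (k in dims) {
    dk <- minimum_image(xyz[idx[1, ], k] - xyz[idx[2, ], k], box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Wrap frame coordinates into the primary box image
#'
#' x and y are wrapped into [0, L); z into [-Lz/2, Lz/2) so that the bilayer
#' midplane stays near the coordinate origin.
#'
#' @param frame an [mp_frame].
#' @return The frame with wrapped coordinates.
#' @export
wrap_frame <- function(frame) {
  p <- frame$positions
  for (k in 1:2) p[, k] <- p[, k] %% frame$box[k]
  Lz <- frame$box[3]
  p[, 3] <- ((p[, 3] + Lz / 2) %% Lz) - Lz / 2
  frame$positions <- p
  frame
}

#' Per-molecule centers of mass
#'
#' Equal-mass bead convention: the center of mass of a molecule is the
#' unweighted mean of its bead coordinates.
#'
#' @param frame an [mp_frame].
#' @param molecule_ids optional subset of molecule ids.
#' @return data.frame with molecule, family, x, y, z.
#' @export
molecule_com <- function(frame, molecule_ids = NULL) {
  ids <- frame$molecule_id
  keep <- if (is.null(molecule_ids)) rep(TRUE, length(ids)) else ids %in% molecule_ids
  ids <- ids[keep]
  p <- frame$positions[keep, , drop = FALSE]
  fam <- .species_family(frame$species[keep])
  ord <- order(ids)
  ids <- ids[ord]; p <- p[ord, , drop = FALSE]; fam <- fam[ord]
  ug <- unique(ids)
  cx <- tapply(p[, 1], ids, mean)
  cy <- tapply(p[, 2], ids, mean)
  cz <- tapply(p[, 3], ids, mean)
  data.frame(molecule = as.integer(names(cx)),
             family = fam[match(as.integer(names(cx)), ids)],
             x = as.numeric(cx), y = as.numeric(cy), z = as.numeric(cz))
}

# select frame indices by fractional window, e.g. c(0.25, 1) = last 75%
.window_frames <- function(traj, window) {
  nf <- length(traj$frames)
  if (is.null(window)) return(seq_len(nf))
  if (length(window) != 2 || window[1] < 0 || window[2] > 1 || window[1] >= window[2])
    stop("window must be a fraction interval within [0, 1]")
  i0 <- max(1L, floor(window[1] * nf) + 1L)
  i1 <- max(i0, ceiling(window[2] * nf))
  i0:i1
}
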