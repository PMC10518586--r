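#' Assign lipids to leaflets
#'
#' The bilayer midplane is the mean z of all lipid head beads; each lipid is
#' assigned to the upper or lower leaflet by the sign of its head-bead z
#' relative to that midplane. Translation of the whole frame along z leaves
#' the assignment unchanged.
#'
#' @param frame an [mp_frame] with at least two lipids.
#' @return list with `midplane` (z0, nm), `assignment` (data.frame: molecule,
#'   leaflet) and `counts` (named upper/lower).
#' @export
assign_leaflets <- function(frame) {
  head <- frame$species == "LIPID_HEAD"
  if (!any(head)) stop("frame contains no lipid head beads")
  mol <- frame$molecule_id[head]
  if (length(unique(mol)) < 2) stop("need at least 2 lipids")
  hz <- tapply(frame$positions[head, 3], mol, mean)  # one head bead per lipid
  z0 <- mean(frame$positions[head, 3])
  leaflet <- ifelse(as.numeric(hz) >= z0, "upper", "lower")
  if (length(unique(leaflet)) == 1)
    warning("all lipids assigned to one leaflet")
  assignment <- data.frame(molecule = as.integer(names(hz)), leaflet = leaflet,
                           row.names = NULL)
  list(midplane = z0, assignment = assignment,
       counts = c(upper = sum(leaflet == "upper"),
                  lower = sum(leaflet == "lower")))
}
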