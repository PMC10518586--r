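#' Cluster molecules into connected components
#'
#' Builds a molecule graph under the chosen edge rule - hydrogen bonds
#' (edges between donor and acceptor molecules from [detect_hbonds()]) or
#' center-of-mass distance below a cutoff (minimum image) - and decomposes
#' it into connected components. The clusters partition the selection;
#' singletons are clusters of size one. Reports the size distribution and
#' the z-extent (max minus min particle z over member molecules) of the
#' largest cluster, which for a membrane-spanning aggregate approaches the
#' bilayer width.
#'
#' @param frame an [mp_frame].
#' @param molecule_ids molecules to cluster; default all DDA molecules.
#' @param edge_rule `"hbond"` or `"com_distance"`.
#' @param com_cutoff center-of-mass distance cutoff (nm) for
#'   `edge_rule = "com_distance"`.
#' @param ... hydrogen-bond criteria forwarded to [detect_hbonds()].
#' @return list of class `mp_clusters`: `clusters` (list of molecule-id
#'   vectors, largest first), `sizes`, `largest_z_span` (nm), `edge_rule`.
#' @export
molecule_clusters <- function(frame, molecule_ids = NULL,
                              edge_rule = c("hbond", "com_distance"),
                              com_cutoff = 1.0, ...) {
  edge_rule <- match.arg(edge_rule)
  if (is.null(molecule_ids)) {
    fam <- .species_family(frame$species)
    molecule_ids <- sort(unique(frame$molecule_id[fam == "DDA"]))
  }
  if (!length(molecule_ids)) stop("empty molecule selection")

  edges <- matrix(integer(0), ncol = 2)
  if (edge_rule == "hbond") {
    hb <- detect_hbonds(frame, ...)
    hb <- hb[hb$donor_molecule %in% molecule_ids &
             hb$acceptor_molecule %in% molecule_ids, ]
    if (nrow(hb))
      edges <- unique(cbind(pmin(hb$donor_molecule, hb$acceptor_molecule),
                            pmax(hb$donor_molecule, hb$acceptor_molecule)))
  } else {
    com <- molecule_com(frame, molecule_ids)
    n <- nrow(com)
    if (n >= 2) {
      idx <- utils::combn(n, 2)
      d <- .pair_distances(as.matrix(com[, c("x", "y", "z")]), frame$box)
      hit <- which(d <= com_cutoff)
      if (length(hit))
        edges <- cbind(com$molecule[idx[1, hit]], com$molecule[idx[2, hit]])
    }
  }

  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[, 1][seq_len(nrow(edges))]),
                   to = as.character(edges[, 2][seq_len(nrow(edges))])),
    directed = FALSE,
    vertices = data.frame(name = as.character(molecule_ids)))
  comp <- igraph::components(g)
  clusters <- split(as.integer(igraph::V(g)$name), comp$membership)
  clusters <- clusters[order(-vapply(clusters, length, integer(1)))]
  names(clusters) <- NULL
  largest <- clusters[[1]]
  zmem <- frame$positions[frame$molecule_id %in% largest, 3]
  structure(list(clusters = clusters,
                 sizes = vapply(clusters, length, integer(1)),
                 largest_z_span = max(zmem) - min(zmem),
                 edge_rule = edge_rule),
            class = "mp_clusters")
}
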