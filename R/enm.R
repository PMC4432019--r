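#' Build a Tirion elastic network
#'
#' Connects every pair of beads whose Euclidean distance is at most `cutoff`
#' (closed interval) with a Hookean spring of constant `base_spring`. The
#' ligand representation may additionally inject `stiffen_pairs` edges
#' (pocket-stiffening model); those get `base_spring * stiffen_factor`
#' regardless of distance.
#'
#' @param nodes a `node_set`.
#' @param cutoff spring distance cutoff, Angstrom (> 0); 8 is the default
#'   used throughout for CAP-sized systems.
#' @param base_spring uniform spring constant k (> 0), arbitrary stiffness
#'   units (the cooperativity ratio is independent of its scale).
#' @param stiffen_pairs optional 2-column matrix of bead index pairs; default
#'   taken from the `stiffen_pairs` attribute of `nodes` if present.
#' @param stiffen_factor multiplier applied to stiffened pairs (default 2).
#' @return object of class `elastic_network`: list with `nodes`, `cutoff`,
#'   `base_spring`, and `edges` (data.frame i, j, dist, k with i < j).
#' @export
build_network <- function(nodes, cutoff = 8, base_spring = 1,
                          stiffen_pairs = NULL, stiffen_factor = 2) {
  stopifnot_scalar_num(cutoff, "cutoff", positive = TRUE)
  stopifnot_scalar_num(base_spring, "base_spring", positive = TRUE)
  if (!inherits(nodes, "node_set")) stop("nodes must be a node_set")
  stiffen_pairs <- stiffen_pairs %||% attr(nodes, "stiffen_pairs")
  d <- pairwise_dist(nodes$xyz)
  n <- nrow(nodes$xyz)
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  edges <- data.frame(i = sel[, 1], j = sel[, 2], dist = d[sel],
                      k = rep(base_spring, nrow(sel)))
  if (!is.null(stiffen_pairs)) {
    sp <- cbind(pmin(stiffen_pairs[, 1], stiffen_pairs[, 2]),
                pmax(stiffen_pairs[, 1], stiffen_pairs[, 2]))
    key <- paste(edges$i, edges$j)
    spkey <- paste(sp[, 1], sp[, 2])
    hit <- key %in% spkey
    edges$k[hit] <- base_spring * stiffen_factor
    miss <- !(spkey %in% key)
    if (any(miss)) {
      add <- sp[miss, , drop = FALSE]
      edges <- rbind(edges, data.frame(
        i = add[, 1], j = add[, 2],
        dist = d[add], k = base_spring * stiffen_factor))
    }
  }
  edges <- edges[order(edges$i, edges$j), ]
  rownames(edges) <- NULL
  if (any(edges$dist < 1e-9))
    stop("coincident beads connected by a spring (zero bond length)")
  structure(list(nodes = nodes, cutoff = cutoff, base_spring = base_spring,
                 edges = edges),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cr <- connectivity_report(x)
  cat(sprintf(
    "elastic_network: %d beads, %d springs (cutoff %g A, k %g), %d component(s)\n",
    nrow(x$nodes$xyz), nrow(x$edges), x$cutoff, x$base_spring, cr$n_components))
  invisible(x)
}

#' Connected components of an elastic network
#'
#' A properly built single-molecule network must form one component; extra
#' components ("atoms improperly connected", as happens for CAP-sized
#' networks at cutoffs of 7.5 Angstrom and below) each contribute six
#' spurious rigid-body zero modes.
#'
#' @param network an `elastic_network`.
#' @return list with `n_components` and `sizes` (decreasing).
#' @export
connectivity_report <- function(network) {
  n <- nrow(network$nodes$xyz)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(network$edges))
    g <- igraph::add_edges(g, rbind(network$edges$i, network$edges$j))
  comp <- igraph::components(g)
  list(n_components = comp$no, sizes = sort(comp$csize, decreasing = TRUE))
}

#' Rescale all springs incident to a bead
#'
#' The elementary move of the allosteric control scan: multiply the constant
#' of every spring touching the given bead(s) by `factor` (k_R/k), leaving
#' topology untouched. Factors above 1 model a strengthened side-chain
#' interaction, below 1 a weakened one. When several beads are given the
#' perturbations compose, so an edge joining two selected beads is scaled
#' once per selected endpoint.
#'
#' @param network an `elastic_network`.
#' @param bead bead reference, see [resolve_bead()].
#' @param factor positive scale factor k_R/k.
#' @return a new `elastic_network`.
#' @export
perturb_site <- function(network, bead, factor) {
  stopifnot_scalar_num(factor, "factor", positive = TRUE)
  idx <- resolve_bead(network$nodes, bead)
  for (b in idx) {
    hit <- network$edges$i == b | network$edges$j == b
    network$edges$k[hit] <- network$edges$k[hit] * factor
  }
  network
}

#' Export / import a network edge list as TSV
#'
#' Columns: i, j, dist (Angstrom), k. For debugging and cross-tool
#' comparison.
#'
#' @param network an `elastic_network`.
#' @param path output file.
#' @return `path` invisibly; `read_network_tsv` returns the edge data.frame.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
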