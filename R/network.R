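# Disease-network construction: intersect the disease-gene set with the
# measured genes, induce the PPI subgraph on the intersection, drop isolated
# nodes, and compute node topology (degree, normalized betweenness).

#' Intersect disease genes with measured genes
#'
#' Exact, case-sensitive string intersection; this is the node universe from
#' which the disease network is induced.
#'
#' @param disease_genes character vector of disease-associated genes.
#' @param measured_genes character vector of genes detected in the study.
#' @return character vector of the intersection (sorted).
#' @export
intersect_genes <- function(disease_genes, measured_genes) {
  if (!length(disease_genes) || !length(measured_genes)) {
    stop("both gene sets must be non-empty", call. = FALSE)
  }
  inter <- sort(intersect(unique(disease_genes), unique(measured_genes)))
  if (!length(inter)) {
    stop("disease genes and measured genes do not overlap; nothing to build",
         call. = FALSE)
  }
  inter
}

#' Build the disease network from an intersection set and PPI edges
#'
#' Induces the subgraph of the PPI edge list on the intersection set. Genes
#' in the intersection with no incident edge inside it are moved to
#' \code{dropped_isolated}, so every retained node has degree >= 1 and
#' \code{length(nodes) + length(dropped_isolated) == length(intersection)}.
#'
#' @param intersection character vector from \code{\link{intersect_genes}}.
#' @param ppi_edges data.frame(node_a, node_b, score) as returned by
#'   \code{\link{read_ppi_edges}} or \code{\link{generate_ppi}}.
#' @return object of class \code{disease_network}: list with \code{nodes},
#'   \code{edges} (data.frame restricted to the network),
#'   \code{dropped_isolated}, and \code{graph} (an igraph object).
#' @export
build_network <- function(intersection, ppi_edges) {
  stopifnot(length(intersection) > 0)
  keep <- ppi_edges$node_a %in% intersection &
    ppi_edges$node_b %in% intersection
  edges <- ppi_edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  connected <- sort(unique(c(edges$node_a, edges$node_b)))
  isolated <- sort(setdiff(intersection, connected))
  if (!length(connected)) {
    warning("no PPI edge joins two intersection genes; the network is empty")
  }
  graph <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = data.frame(name = connected, stringsAsFactors = FALSE)
  )
  structure(list(nodes = connected, edges = edges,
                 dropped_isolated = isolated, graph = graph),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("Disease network: %d nodes, %d edges (%d isolated genes dropped)\n",
              length(x$nodes), nrow(x$edges), length(x$dropped_isolated)))
  invisible(x)
}

#' Per-node degree and betweenness of a disease network
#'
#' Degree counts incident edges; betweenness is the fraction of unweighted
#' shortest paths through the node, normalized by \eqn{(n-1)(n-2)/2}. Both are
#' computed on the unweighted graph: the STRING combined score acts only as an
#' edge-inclusion filter upstream, matching the defaults of the usual network
#' analyzer tooling. On disconnected graphs, paths are counted within
#' components.
#'
#' @param network a \code{\link{build_network}} result.
#' @return data.frame(gene_id, degree, betweenness), one row per node, in
#'   sorted node order.
#' @export
network_topology <- function(network) {
  stopifnot(inherits(network, "disease_network"))
  if (!length(network$nodes)) stop("network has no nodes", call. = FALSE)
  g <- network$graph
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  n <- length(network$nodes)
  if (n <= 2L) btw[] <- 0   # normalization undefined; no through-paths exist
  out <- data.frame(gene_id = igraph::V(g)$name,
                    degree = as.integer(deg),
                    betweenness = as.numeric(btw),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a disease network to GraphML and TSV
#'
#' @param network a \code{\link{build_network}} result.
#' @param graphml_path,edges_path,topology_path output paths (any may be
#'   \code{NULL} to skip).
#' @return invisibly, the network.
#' @export
export_network <- function(network, graphml_path = NULL, edges_path = NULL,
                           topology_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) write_ppi_edges(network$edges, edges_path)
  if (!is.null(topology_path)) {
    write.table(network_topology(network), topology_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(network)
}
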