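#' @include constructors.R
NULL

#' Hypergeometric module / eQTL-gene overlap test
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between a module and the eQTL gene set when drawing the module
#' without replacement from the gene universe.
#'
#' @param moduleGenes,eqtlGenes,universe character vectors (both sets must
#'   lie inside the universe).
#' @return list: \code{overlap}, \code{fraction} (overlap / module size),
#'   \code{p_value} = P(X >= overlap).
#' @export
moduleEqtlOverlap <- function(moduleGenes, eqtlGenes, universe) {
  if (!length(universe)) stop("empty universe")
  moduleGenes <- unique(moduleGenes); eqtlGenes <- unique(eqtlGenes)
  if (!all(moduleGenes %in% universe) || !all(eqtlGenes %in% universe))
    stop("module and eQTL genes must be subsets of the universe")
  ov <- length(intersect(moduleGenes, eqtlGenes))
  m <- length(eqtlGenes); nU <- length(universe); k <- length(moduleGenes)
  p <- if (ov == 0L) 1 else
    stats::phyper(ov - 1L, m, nU - m, k, lower.tail = FALSE)
  list(overlap = ov,
       fraction = if (k) ov / k else 0,
       p_value = min(1, p))
}

#' Count cis-eQTL genes in each module
#'
#' Per module: the number of cis-eQTL genes it contains, that count as a
#' percentage of the module size, and the hypergeometric overlap p value
#' against the assigned-gene universe.  Sorted by p value.
#'
#' @param labels named integer module labels (0 = unassigned).
#' @param cisEqtlGenes character vector of cis-eQTL gene ids.
#' @param universe gene universe (default: all labelled genes).
#' @return \code{data.frame}: module, size, n_eqtl, percent, p_value.
#' @export
countModuleEqtls <- function(labels, cisEqtlGenes, universe = NULL) {
  if (is.null(universe)) universe <- names(labels)
  eq <- intersect(unique(cisEqtlGenes), universe)
  mods <- sort(unique(labels[labels > 0L]))
  rows <- lapply(mods, function(m) {
    genes <- intersect(names(labels)[labels == m], universe)
    ov <- moduleEqtlOverlap(genes, eq, universe)
    data.frame(module = m, size = length(genes), n_eqtl = ov$overlap,
               percent = 100 * ov$fraction, p_value = ov$p_value)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$module), , drop = FALSE]
}

#' Merge a module co-expression network with PPI edges
#'
#' Builds the integrated graph: module genes plus proteins, with
#' co-expression edges (kept when their weight is at least
#' \code{weightThreshold}), PPI edges, and gene-protein identity fusion:
#' a protein mapping to a module gene is fused into that gene's node.
#' Many-to-many mappings use the first mapping and log the conflict.
#'
#' @param moduleEdges \code{data.frame}: gene_a, gene_b, weight (e.g. TOM).
#' @param ppiEdges \code{data.frame}: protein_a, protein_b.
#' @param idMap optional \code{data.frame}: protein, gene.
#' @param weightThreshold minimum co-expression weight (default 0.1).
#' @return an undirected \code{igraph} with vertex attribute \code{type}
#'   (gene/protein) and edge attributes \code{type} (coexpression/ppi) and
#'   \code{weight}.
#' @importFrom igraph graph_from_data_frame V
#' @export
mergeCoexpressionPpi <- function(moduleEdges, ppiEdges, idMap = NULL,
                                 weightThreshold = 0.1) {
  me <- moduleEdges[moduleEdges$weight >= weightThreshold, , drop = FALSE]
  edges <- data.frame(from = as.character(me[[1]]),
                      to = as.character(me[[2]]),
                      weight = me$weight, type = "coexpression")
  geneNodes <- unique(c(edges$from, edges$to))
  mapProt <- function(p) p
  if (!is.null(idMap) && nrow(idMap)) {
    dup <- duplicated(idMap$protein)
    if (any(dup))
      message(sum(dup), " conflicting protein mapping(s): first kept")
    idMap <- idMap[!dup, , drop = FALSE]
    mapProt <- function(p) {
      hit <- match(p, idMap$protein)
      fuse <- !is.na(hit) & idMap$gene[hit] %in% geneNodes
      p[fuse] <- idMap$gene[hit[fuse]]
      p
    }
  }
  if (nrow(ppiEdges)) {
    pa <- mapProt(as.character(ppiEdges[[1]]))
    pb <- mapProt(as.character(ppiEdges[[2]]))
    keep <- pa != pb
    edges <- rbind(edges, data.frame(from = pa[keep], to = pb[keep],
                                     weight = 1, type = "ppi"))
  }
  # drop duplicate edges of the same type (order-insensitive)
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
               edges$type)
  edges <- edges[!duplicated(key), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::V(g)$type <- ifelse(igraph::V(g)$name %in% geneNodes,
                              "gene", "protein")
  g
}

#' Normalized betweenness centrality
#'
#' Unweighted shortest-path betweenness, normalized by (n-1)(n-2)/2 for an
#' undirected graph.
#'
#' @param graph an \code{igraph}.
#' @return named numeric vector of scores in [0, 1].
#' @importFrom igraph betweenness vcount
#' @export
betweennessCentrality <- function(graph) {
  n <- igraph::vcount(graph)
  b <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  if (n > 2) b / ((n - 1) * (n - 2) / 2) else b * 0
}

#' Community clustering by greedy modularity maximization
#'
#' Agglomerative greedy modularity maximization on the unweighted graph
#' (the package's deterministic stand-in for GUI community-clustering
#' tools).  Returns the membership and the final modularity.
#'
#' @param graph an \code{igraph} (edge weights ignored).
#' @return list: \code{membership} (named integer), \code{modularity},
#'   \code{n_communities}.
#' @importFrom igraph cluster_fast_greedy membership modularity simplify
#'   cut_at ecount
#' @export
communityClusters <- function(graph) {
  if (igraph::vcount(graph) < 1L) stop("graph must have at least one node")
  g <- igraph::simplify(graph, remove.multiple = TRUE,
                        remove.loops = TRUE)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  if (igraph::ecount(g) == 0L)
    return(list(membership = stats::setNames(seq_len(n), nm),
                modularity = 0, n_communities = n))
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  # pick the dendrogram cut maximizing modularity; ties (within fp noise)
  # resolved toward fewer communities
  kmin <- max(1L, n - nrow(cl$merges))  # components cannot be merged
  ks <- seq(kmin, n)
  qs <- vapply(ks, function(k)
    igraph::modularity(g, igraph::cut_at(cl, no = k)), numeric(1))
  best <- ks[which(qs >= max(qs) - 1e-12)][1]
  mem <- igraph::cut_at(cl, no = best)
  list(membership = stats::setNames(as.integer(mem), nm),
       modularity = igraph::modularity(g, mem),
       n_communities = length(unique(mem)))
}

#' Integrate a module network with PPIs and analyze its topology
#'
#' Merges the module's TOM edges with PPI edges, then computes normalized
#' betweenness and greedy-modularity communities.
#'
#' @param tom TOM matrix of the selected module's genes.
#' @param moduleGenes genes of the selected module.
#' @param ppiEdges PPI edge \code{data.frame}.
#' @param idMap optional protein-to-gene mapping.
#' @param weightThreshold minimum TOM weight for a co-expression edge.
#' @param restrictPpi keep only PPI edges with at least one endpoint in the
#'   module (directly or through \code{idMap}); the merge then adds the
#'   module genes' interaction partners rather than the whole PPI universe.
#' @return list: \code{graph}, \code{betweenness}, \code{communities},
#'   \code{n_nodes}, \code{n_edges}.
#' @importFrom igraph ecount
#' @export
integrateModulePpi <- function(tom, moduleGenes, ppiEdges, idMap = NULL,
                               weightThreshold = 0.1, restrictPpi = TRUE) {
  genes <- intersect(moduleGenes, rownames(tom))
  if (restrictPpi && nrow(ppiEdges)) {
    inMod <- function(p) p %in% genes |
      (!is.null(idMap) & p %in% idMap$protein[idMap$gene %in% genes])
    keep <- inMod(as.character(ppiEdges[[1]])) |
      inMod(as.character(ppiEdges[[2]]))
    ppiEdges <- ppiEdges[keep, , drop = FALSE]
  }
  sub <- tom[genes, genes, drop = FALSE]
  idx <- which(upper.tri(sub), arr.ind = TRUE)
  me <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                   weight = sub[idx])
  g <- mergeCoexpressionPpi(me, ppiEdges, idMap, weightThreshold)
  list(graph = g,
       betweenness = betweennessCentrality(g),
       communities = communityClusters(g),
       n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g))
}
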