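#' Pearson similarity matrix between genes
#'
#' Correlations are computed across all samples pooled over conditions (the
#' network describes co-expression over the whole experiment). Zero-variance
#' genes are excluded with a warning.
#'
#' @param values Log2 expression matrix (genes x samples) restricted to the
#'   genes of interest, at least 3 samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(values) {
  if (ncol(values) < 3) abort("need at least 3 samples for correlations")
  v <- apply(values, 1, sd)
  if (any(v == 0)) {
    warn(paste0(sum(v == 0), " zero-variance gene(s) excluded from the network"))
    values <- values[v > 0, , drop = FALSE]
  }
  cor(t(values))
}

#' Hard-threshold a similarity matrix into a binary adjacency
#'
#' `a_ij = 1` iff `|r_ij| > r0` and `i != j` (strict inequality; the
#' boundary is measure-zero but fixed for determinism). Both strong
#' positive and strong negative correlations create edges.
#'
#' @param S Correlation matrix from [correlation_matrix()].
#' @param r0 Threshold in (0, 1); default 0.98.
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
threshold_adjacency <- function(S, r0 = 0.98) {
  if (r0 <= 0 || r0 >= 1) abort("threshold r0 must lie in (0, 1)")
  A <- (abs(S) > r0) * 1L
  diag(A) <- 0L
  A
}

#' Build a relevance network from an expression matrix
#'
#' The three-step construction: Pearson similarity, hard thresholding at
#' `|r| > r0`, graph representation. When several probes map to the same
#' gene, each gene is represented by its highest-variance probe. The
#' returned object also stores the correlation attached to each edge.
#'
#' @param values Log2 expression matrix (probes x samples).
#' @param annotation Optional tibble `probe_id`, `gene_symbol`; when
#'   supplied, probes are collapsed to genes by highest variance and nodes
#'   are named by gene (unannotated probes keep their probe id).
#' @param r0 Hard threshold on |Pearson r|.
#' @return An object of class `relevance_network`: list with `graph`
#'   (igraph), `edges` (tibble `gene_a`, `gene_b`, `r`), `nodes`
#'   (character), `r0`.
#' @export
relevance_network <- function(values, annotation = NULL, r0 = 0.98) {
  if (!is.null(annotation)) {
    values <- representative_probes(values, annotation)
  }
  S <- correlation_matrix(values)
  A <- threshold_adjacency(S, r0)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- tibble(
    gene_a = el[, 1], gene_b = el[, 2],
    r = S[cbind(el[, 1], el[, 2])]
  )
  if (nrow(edges) > 0) {
    igraph::E(g)$r <- edges$r
  }
  out <- list(graph = g, edges = edges, nodes = rownames(S), r0 = r0)
  class(out) <- "relevance_network"
  out
}

# one representative probe per gene: highest variance, ties by probe id
representative_probes <- function(values, annotation) {
  ann <- annotation
  ann$gene_symbol[is.na(ann$gene_symbol) | ann$gene_symbol == "unannotated"] <-
    NA_character_
  map <- setNames(ann$gene_symbol, ann$probe_id)
  gene <- map[rownames(values)]
  gene[is.na(gene)] <- rownames(values)[is.na(gene)]
  v <- apply(values, 1, var)
  ord <- order(gene, -v, rownames(values))
  keep <- ord[!duplicated(gene[ord])]
  out <- values[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out[order(rownames(out)), , drop = FALSE]
}

#' @export
print.relevance_network <- function(x, ...) {
  cat("Relevance network: |r| >", x$r0, "\n")
  cat(" ", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Largest connected component of a network
#'
#' The maximal component by node count; among equally large components the
#' one containing the lexicographically smallest node name is returned, so
#' the choice is deterministic.
#'
#' @param network A `relevance_network` or igraph graph.
#' @return An igraph graph induced on the winning component (empty graph
#'   for an empty input).
#' @export
largest_connected_component <- function(network) {
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0) return(g)
  comp <- igraph::components(g)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1) {
    firsts <- vapply(big, function(b) {
      min(igraph::V(g)$name[comp$membership == b])
    }, character(1))
    big <- big[order(firsts)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == big))
}

as_igraph <- function(network) {
  if (inherits(network, "relevance_network")) network$graph else network
}

#' Fast-greedy modularity communities
#'
#' Agglomerative Clauset-Newman-Moore optimisation of the Newman-Girvan
#' modularity \eqn{Q = \sum_c (e_c - a_c^2)} on the unweighted graph:
#' starting from singletons, the pair of communities with the largest
#' modularity gain is merged and the dendrogram is cut at the maximum of Q.
#' A graph without edges yields singleton communities with Q = 0.
#'
#' @param graph An igraph graph (or `relevance_network`).
#' @return List: `membership` (named integer vector), `modularity` (Q of
#'   the returned partition), `n_communities`.
#' @export
fastgreedy_communities <- function(graph) {
  g <- as_igraph(graph)
  if (igraph::ecount(g) == 0) {
    memb <- seq_len(igraph::vcount(g))
    names(memb) <- igraph::V(g)$name
    return(list(membership = memb, modularity = 0,
                n_communities = igraph::vcount(g)))
  }
  cl <- igraph::cluster_fast_greedy(
    g, merges = TRUE, modularity = TRUE, membership = TRUE, weights = NULL
  )
  # cut the agglomeration dendrogram at the first maximum of Q ourselves:
  # igraph's own membership can stop a merge short of the Q maximum
  qpath <- cl$modularity
  cut <- which(qpath >= max(qpath) - 1e-12)[1]
  memb <- igraph::cut_at(cl, steps = cut - 1L)
  names(memb) <- igraph::V(g)$name
  q <- igraph::modularity(g, memb)
  list(
    membership = setNames(as.integer(memb), names(memb)),
    modularity = q,
    n_communities = length(unique(memb))
  )
}

#' Degree and betweenness centrality per node
#'
#' Degree is the number of incident edges; betweenness is the Brandes
#' count of shortest paths through a node, unnormalized (each unordered
#' pair of other nodes contributes the fraction of its shortest paths
#' passing through the node), with unweighted (hop-count) paths.
#'
#' @param graph An igraph graph (or `relevance_network`).
#' @return Tibble: `gene`, `degree`, `betweenness`.
#' @export
centralities <- function(graph) {
  g <- as_igraph(graph)
  tibble(
    gene = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    betweenness = as.numeric(
      igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
    )
  )
}

#' Hub and bridge gene report
#'
#' Centralities plus community labels, ranked. High-degree genes are hubs;
#' high-betweenness genes bridge communities.
#'
#' @param graph An igraph graph (typically the largest connected component)
#'   or `relevance_network`.
#' @param communities Optional result of [fastgreedy_communities()];
#'   computed on `graph` when omitted.
#' @return Tibble sorted by decreasing degree (ties by gene id): `gene`,
#'   `degree`, `betweenness`, `community`, `rank_degree`,
#'   `rank_betweenness`.
#' @export
hub_report <- function(graph, communities = NULL) {
  g <- as_igraph(graph)
  cent <- centralities(g)
  if (is.null(communities)) communities <- fastgreedy_communities(g)
  cent$community <- as.integer(communities$membership[cent$gene])
  cent <- arrange(cent, desc(.data$degree), .data$gene)
  cent$rank_degree <- seq_len(nrow(cent))
  bt_order <- order(-cent$betweenness, cent$gene)
  cent$rank_betweenness <- NA_integer_
  cent$rank_betweenness[bt_order] <- seq_len(nrow(cent))
  cent
}
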