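#' Tidy a mixed fit into a coefficient table
#'
#' @param x A `mixed_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (log2 units; NA for aliased terms).
#' @export
tidy.mixed_fit <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' One-row summary of a mixed fit
#'
#' @param x A `mixed_fit`.
#' @param ... Unused.
#' @return Tibble with `sigma2_sow`, `sigma2_resid`, `lambda`, `loglik_ml`,
#'   `n_params`, `rank`, `n`, `bic`, `not_testable`.
#' @export
glance.mixed_fit <- function(x, ...) {
  tibble(
    sigma2_sow = x$sigma2_sow, sigma2_resid = x$sigma2_resid,
    lambda = x$lambda, loglik_ml = x$loglik_ml,
    n_params = x$n_params, rank = x$rank, n = x$n,
    bic = if (is.finite(x$loglik_ml)) bic(x) else NA_real_,
    not_testable = x$not_testable
  )
}

#' Tidy a relevance network into its edge list
#'
#' @param x A `relevance_network`.
#' @param ... Unused.
#' @return Tibble `gene_a`, `gene_b`, `r`.
#' @export
tidy.relevance_network <- function(x, ...) x$edges

#' One-row summary of a relevance network
#'
#' @param x A `relevance_network`.
#' @param ... Unused.
#' @return Tibble `n_nodes`, `n_edges`, `r0`, `n_components`,
#'   `lcc_nodes`, `lcc_edges`.
#' @export
glance.relevance_network <- function(x, ...) {
  lcc <- largest_connected_component(x)
  tibble(
    n_nodes = length(x$nodes), n_edges = nrow(x$edges), r0 = x$r0,
    n_components = igraph::components(x$graph)$no,
    lcc_nodes = igraph::vcount(lcc), lcc_edges = igraph::ecount(lcc)
  )
}

#' Plot PCA sample scores
#'
#' Scatter of two principal components, optionally coloured/shaped by
#' design factors.
#'
#' @param object An `expr_pca` from [pca_scores()].
#' @param design Optional design tibble joined by `sample_id` for
#'   aesthetics.
#' @param components Which two components to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expr_pca <- function(object, design = NULL, components = c(1, 2),
                              ...) {
  pcs <- paste0("PC", components)
  df <- object$scores
  if (!all(pcs %in% names(df))) abort("requested components not computed")
  fr <- object$variance$variance_fraction[components]
  if (!is.null(design)) df <- left_join(df, design, by = "sample_id")
  aes_args <- list(x = rlang::sym(pcs[1]), y = rlang::sym(pcs[2]))
  if (!is.null(design) && "age" %in% names(df)) {
    aes_args$colour <- rlang::sym("age")
  }
  if (!is.null(design) && "fetal_genotype" %in% names(df)) {
    aes_args$shape <- rlang::sym("fetal_genotype")
  }
  ggplot2::ggplot(df, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1], 100 * fr[1]),
      y = sprintf("%s (%.1f%%)", pcs[2], 100 * fr[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a relevance network
#'
#' Force-directed layout with nodes coloured by fast-greedy community and
#' sized by degree.
#'
#' @param object A `relevance_network` or igraph graph (e.g. the largest
#'   connected component).
#' @param communities Optional [fastgreedy_communities()] result.
#' @param seed Layout seed (layouts are stochastic).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relevance_network <- function(object, communities = NULL, seed = 1,
                                       ...) {
  g <- as_igraph(object)
  if (igraph::vcount(g) == 0) abort("empty network")
  if (is.null(communities)) communities <- fastgreedy_communities(g)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(
    gene = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
    degree = as.integer(igraph::degree(g)),
    community = factor(communities$membership[igraph::V(g)$name])
  )
  el <- igraph::as_edgelist(g)
  segs <- tibble(
    x = xy[match(el[, 1], nodes$gene), 1],
    y = xy[match(el[, 1], nodes$gene), 2],
    xend = xy[match(el[, 2], nodes$gene), 1],
    yend = xy[match(el[, 2], nodes$gene), 2]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$community,
                   size = .data$degree)
    ) +
    ggplot2::scale_size_continuous(range = c(1, 5)) +
    ggplot2::theme_void()
}
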