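#' Collapse probe-level test results to genes
#'
#' Microarray probes map many-to-one onto genes; for enrichment the unit is
#' the gene. Each annotated gene keeps the fold-change values of its
#' largest-|overall log2 fold change| probe (ties broken by probe id);
#' unannotated probes are dropped and their count reported via a message.
#' The operation is idempotent.
#'
#' @param results Probe-level tibble (from [dge_test()], or any table with
#'   `probe_id` and `log2fc_*` columns).
#' @param annotation Tibble `probe_id`, `gene_symbol`
#'   (`"unannotated"`/NA = no gene).
#' @return Per-gene tibble: `gene_symbol`, `probe_id` (the representative
#'   probe) and the fold-change columns of `results`.
#' @export
collapse_probes_to_genes <- function(results, annotation) {
  ann <- annotation
  ann$gene_symbol[is.na(ann$gene_symbol)] <- "unannotated"
  joined <- left_join(results, ann, by = "probe_id")
  joined$gene_symbol[is.na(joined$gene_symbol)] <- "unannotated"
  n_dropped <- sum(joined$gene_symbol == "unannotated")
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " unannotated probe(s) dropped in gene collapse"))
  }
  joined <- filter(joined, .data$gene_symbol != "unannotated")
  fc_cols <- grep("^log2fc_", names(results), value = TRUE)
  if (length(fc_cols) == 0) abort("results has no log2fc_* columns")
  joined |>
    mutate(.abs_fc = abs(.data[[fc_cols[1]]])) |>
    arrange(desc(.data$.abs_fc), .data$probe_id) |>
    group_by(.data$gene_symbol) |>
    slice(1) |>
    ungroup() |>
    select("gene_symbol", "probe_id", all_of(fc_cols)) |>
    arrange(.data$gene_symbol)
}

#' Split genes into up-regulated lists by fold-change filter
#'
#' Applies the fold-change gate used before enrichment: genes with
#' `log2FC >= +threshold` are up-regulated at day 110, genes with
#' `log2FC <= -threshold` up-regulated at day 90. The default threshold is
#' `log2(1.4)` (absolute fold change 1.4); the boundary is inclusive. The
#' scope selects which fold change is filtered: averaged over genotypes
#' (`"overall"`) or within one breed (`"LW"`, `"MS"`).
#'
#' @param per_gene Per-gene tibble from [collapse_probes_to_genes()].
#' @param fc_threshold Log2 fold-change threshold (> 0).
#' @param scope `"overall"`, `"LW"` or `"MS"`.
#' @return List of two character vectors: `up_at_d110`, `up_at_d90`
#'   (disjoint).
#' @export
select_regulated <- function(per_gene, fc_threshold = log2(1.4),
                             scope = c("overall", "LW", "MS")) {
  scope <- match.arg(scope)
  if (fc_threshold <= 0) abort("fc_threshold must be positive")
  col <- paste0("log2fc_age_", scope)
  if (!col %in% names(per_gene)) {
    abort(paste0("column ", col, " absent from per-gene table"))
  }
  fc <- per_gene[[col]]
  list(
    up_at_d110 = per_gene$gene_symbol[!is.na(fc) & fc >= fc_threshold],
    up_at_d90 = per_gene$gene_symbol[!is.na(fc) & fc <= -fc_threshold]
  )
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of observing at least `k` annotated genes in a query of size
#' `n` when `K` of the `N` universe genes carry the annotation:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Overlap between query and set.
#' @param n Query size.
#' @param K Set size (within the universe).
#' @param N Universe size.
#' @return The p-value in (0, 1].
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    abort("inconsistent hypergeometric counts: need 0 <= k <= min(n, K) <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' One upper-tail hypergeometric test per gene set against a fixed
#' universe (by default all genes appearing in the collection restricted to
#' `universe`), Benjamini-Hochberg adjustment across sets, sorted by raw
#' p-value. Query genes outside the universe are dropped with a warning.
#'
#' @param query Character vector of gene symbols.
#' @param collection Named list of gene-symbol vectors (see [read_gmt()]).
#' @param universe Character vector of background genes (the annotated
#'   genes measured on the array).
#' @param q_threshold Significance threshold on the adjusted p-value.
#' @return Tibble: `set_name`, `overlap`, `query_size`, `set_size`,
#'   `universe_size`, `p_raw`, `q_bh`, `significant`, `overlap_genes`
#'   (list-column), sorted by `p_raw` then `set_name`.
#' @export
enrich <- function(query, collection, universe, q_threshold = 0.01) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " query gene(s) outside the universe dropped"))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) {
    warn("empty query: returning no enrichment results")
    return(tibble(
      set_name = character(0), overlap = integer(0), query_size = integer(0),
      set_size = integer(0), universe_size = integer(0),
      p_raw = numeric(0), q_bh = numeric(0), significant = logical(0),
      overlap_genes = list()
    ))
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::imap(collection, function(members, nm) {
    set <- intersect(unique(members), universe)
    hits <- intersect(query, set)
    tibble(
      set_name = nm, overlap = length(hits), query_size = n,
      set_size = length(set), universe_size = N,
      p_raw = hypergeom_test(length(hits), n, length(set), N),
      overlap_genes = list(sort(hits))
    )
  })
  out <- bind_rows(rows)
  out$q_bh <- adjust_pvalues(out$p_raw, "bh")
  out$significant <- out$q_bh < q_threshold
  out |>
    arrange(.data$p_raw, .data$set_name) |>
    select("set_name", "overlap", "query_size", "set_size",
           "universe_size", "p_raw", "q_bh", "significant", "overlap_genes")
}
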