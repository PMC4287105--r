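#' Run the full maturity analysis pipeline
#'
#' Orchestrates the stages end-to-end on in-memory inputs: quantile
#' normalization (optional pass-through), PCA quality control, per-probe
#' mixed-model F-tests against the null model, DEP calling, BIC sub-model
#' classification, model-based fold changes, fold-change-filtered regulated
#' gene lists with hypergeometric enrichment, the hard-thresholded
#' relevance network built on interaction-model (sub-model 1) genes, and
#' the parental-genome interaction tests. Thresholds default to the study
#' settings: Bonferroni 1% for DEPs, FDR 1% for enrichment and parental
#' calls, absolute fold change 1.4, correlation threshold 0.98.
#'
#' @param values Log2 expression matrix (probes x samples).
#' @param design Design tibble (see [complete_design()]).
#' @param annotation Tibble `probe_id`, `gene_symbol`.
#' @param collection Named list of gene sets (see [read_gmt()]); `NULL`
#'   skips enrichment.
#' @param alpha DEP significance threshold (adjusted p).
#' @param correction DEP multiple-testing correction, `"bonferroni"` or
#'   `"bh"`.
#' @param fdr FDR threshold for enrichment and parental calls.
#' @param fc_threshold Fold-change gate (linear scale; filtering happens at
#'   `log2(fc_threshold)`).
#' @param r0 Hard threshold on |Pearson r| for the relevance network.
#' @param normalize Apply [quantile_normalize()] first. Defaults to
#'   `FALSE`: the pipeline takes already-normalized log2 input (as the
#'   synthetic generator produces). Enable when importing raw-scale or
#'   un-normalized arrays; note quantile normalization assumes most genes
#'   are unchanged between samples, which holds on genome-wide arrays but
#'   not on small simulated panels where most genes carry planted effects.
#' @param outdir Optional directory: every stage table is written as TSV
#'   plus a `summary.json`.
#' @return A list of stage results: `values` (normalized), `pca`, `dge`,
#'   `deps`, `submodels`, `per_gene`, `regulated`, `enrichment_up_d110`,
#'   `enrichment_up_d90`, `network`, `lcc`, `communities`, `hubs`,
#'   `parental`, `summary` (named list of stage counts).
#' @export
run_pipeline <- function(values, design, annotation,
                         collection = NULL,
                         alpha = 0.01, correction = "bonferroni",
                         fdr = 0.01, fc_threshold = 1.4, r0 = 0.98,
                         normalize = FALSE, outdir = NULL) {
  stopifnot(is.matrix(values))
  design <- ensure_parental(design)
  if (normalize) values <- quantile_normalize(values)

  pca <- pca_scores(values, n_components = min(3, ncol(values) - 1))
  dge <- dge_test(values, design)
  deps <- call_deps(dge, alpha = alpha, method = correction)
  submodels <- if (length(deps) > 0) {
    classify_submodels(values, design, deps)
  } else {
    classify_submodels(values, design, character(0))
  }

  sub1 <- submodels$probe_id[submodels$label == 1L]
  dge_sub1 <- dge[dge$probe_id %in% sub1, , drop = FALSE]
  per_gene <- collapse_probes_to_genes(dge_sub1, annotation)
  regulated <- select_regulated(per_gene, log2(fc_threshold), "overall")

  universe <- unique(annotation$gene_symbol[
    !is.na(annotation$gene_symbol) & annotation$gene_symbol != "unannotated"
  ])
  enr_110 <- enr_90 <- NULL
  if (!is.null(collection)) {
    enr_110 <- enrich(regulated$up_at_d110, collection, universe, fdr)
    enr_90 <- enrich(regulated$up_at_d90, collection, universe, fdr)
  }

  network <- lcc <- communities <- hubs <- NULL
  if (length(sub1) >= 2) {
    network <- relevance_network(
      values[sub1, , drop = FALSE], annotation, r0 = r0
    )
    lcc <- largest_connected_component(network)
    communities <- fastgreedy_communities(lcc)
    hubs <- hub_report(lcc, communities)
  }

  parental <- test_parental_interactions(values, design, q_threshold = fdr)

  summary <- list(
    n_probes = nrow(values),
    n_samples = ncol(values),
    pca_variance_fractions = pca$variance$variance_fraction,
    n_deps = length(deps),
    submodel_counts = as.list(setNames(
      submodel_proportions(submodels)$n, paste0("submodel", 1:4)
    )),
    submodel_proportions = as.list(setNames(
      submodel_proportions(submodels)$proportion, paste0("submodel", 1:4)
    )),
    n_sub1_genes = nrow(per_gene),
    n_up_at_d110 = length(regulated$up_at_d110),
    n_up_at_d90 = length(regulated$up_at_d90),
    n_enriched_up_d110 = if (is.null(enr_110)) NA else sum(enr_110$significant),
    n_enriched_up_d90 = if (is.null(enr_90)) NA else sum(enr_90$significant),
    network_nodes = if (is.null(network)) 0L else length(network$nodes),
    network_edges = if (is.null(network)) 0L else nrow(network$edges),
    lcc_nodes = if (is.null(lcc)) 0L else igraph::vcount(lcc),
    lcc_edges = if (is.null(lcc)) 0L else igraph::ecount(lcc),
    modularity = if (is.null(communities)) NA else communities$modularity,
    n_communities = if (is.null(communities)) NA else communities$n_communities,
    n_parental_maternal = sum(parental$call == "maternal", na.rm = TRUE),
    n_parental_paternal = sum(parental$call == "paternal", na.rm = TRUE),
    n_parental_both = sum(parental$call == "both", na.rm = TRUE)
  )

  out <- list(
    values = values, pca = pca, dge = dge, deps = deps,
    submodels = submodels, per_gene = per_gene, regulated = regulated,
    enrichment_up_d110 = enr_110, enrichment_up_d90 = enr_90,
    network = network, lcc = lcc, communities = communities, hubs = hubs,
    parental = parental, summary = summary
  )
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(out$dge, "dge_results.tsv")
  tsv(tibble(probe_id = out$deps), "deps.tsv")
  tsv(out$submodels, "submodel_assignments.tsv")
  tsv(out$per_gene, "sub1_genes.tsv")
  tsv(out$parental, "parental_tests.tsv")
  if (!is.null(out$network)) tsv(out$network$edges, "network_edges.tsv")
  if (!is.null(out$hubs)) tsv(out$hubs, "network_hubs.tsv")
  if (!is.null(out$enrichment_up_d110)) {
    tsv(select(out$enrichment_up_d110, -"overlap_genes"), "enrichment_up_d110.tsv")
    tsv(select(out$enrichment_up_d90, -"overlap_genes"), "enrichment_up_d90.tsv")
  }
  jsonlite::write_json(
    out$summary, file.path(outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(outdir)
}

#' Simulate a data set and run the pipeline with truth-based scoring
#'
#' Generates a full synthetic data set from a [sim_config()], runs
#' [run_pipeline()], and scores every recoverable stage against the planted
#' truth: DEP sensitivity/specificity, the sub-model confusion matrix,
#' parental-call sensitivity and cross-calls, the adjusted Rand index of
#' the network communities against the planted blocks, and the qPCR
#' validation correlations.
#'
#' @param cfg A [sim_config()].
#' @param ... Passed to [run_pipeline()] (thresholds, `outdir`, ...).
#' @param qpcr Also simulate and score the qPCR arm.
#' @return A list: `data` (the simulated inputs), `pipeline` (the
#'   [run_pipeline()] result) and `recovery`, a list with
#'   `dep_sensitivity`, `dep_specificity`, `submodel_confusion` (rows =
#'   planted classes 1-4, columns = assigned label or "none"),
#'   `submodel_accuracy` (named per class), `parental` (sensitivity and
#'   cross-call rates), `network_ari`, and `qpcr` (per-gene validation
#'   correlations) when requested.
#' @export
simulate_and_run <- function(cfg, ..., qpcr = TRUE) {
  design <- simulate_design(cfg)
  sim <- simulate_expression(cfg, design)
  sets <- simulate_genesets(cfg, sim$truth)
  pipe <- run_pipeline(sim$values, design, sim$annotation,
                       collection = sets, ...)
  truth <- sim$truth

  is_null <- truth$class == "null"
  called <- truth$probe_id %in% pipe$deps
  recovery <- list(
    dep_sensitivity = mean(called[!is_null]),
    dep_specificity = mean(!called[is_null])
  )

  planted <- paste0("submodel", 1:4)
  lab <- setNames(pipe$submodels$label, pipe$submodels$probe_id)
  conf <- matrix(0L, nrow = 4, ncol = 5,
                 dimnames = list(planted, c(paste0("label", 1:4), "none")))
  for (m in 1:4) {
    ids <- truth$probe_id[truth$class == planted[m]]
    l <- lab[ids]
    conf[m, 1:4] <- vapply(1:4, function(k) sum(l == k, na.rm = TRUE), integer(1))
    conf[m, 5] <- sum(is.na(l))
  }
  recovery$submodel_confusion <- conf
  recovery$submodel_accuracy <- setNames(
    diag(conf[, 1:4]) / pmax(1L, rowSums(conf)), planted
  )

  par_call <- setNames(pipe$parental$call, pipe$parental$probe_id)
  mat_ids <- truth$probe_id[truth$class == "maternal_interaction"]
  pat_ids <- truth$probe_id[truth$class == "paternal_interaction"]
  recovery$parental <- list(
    maternal_sensitivity = mean(par_call[mat_ids] %in% c("maternal", "both")),
    paternal_sensitivity = mean(par_call[pat_ids] %in% c("paternal", "both")),
    paternal_cross_called_maternal =
      mean(par_call[pat_ids] %in% c("maternal", "both")),
    maternal_cross_called_paternal =
      mean(par_call[mat_ids] %in% c("paternal", "both"))
  )

  # block recovery is scored on the whole thresholded graph (the planted
  # blocks need not share a connected component), with fast-greedy
  # communities computed per component
  recovery$network_ari <- NA_real_
  if (!is.null(pipe$network) && igraph::vcount(pipe$network$graph) > 0) {
    memb <- fastgreedy_communities(pipe$network$graph)$membership
    block_genes <- truth[!is.na(truth$block_id), c("gene_id", "block_id")]
    present <- block_genes$gene_id[block_genes$gene_id %in% names(memb)]
    if (length(present) > 2) {
      truth_part <- block_genes$block_id[match(present, block_genes$gene_id)]
      recovery$network_ari <- igraph::compare(
        as.integer(factor(truth_part)),
        as.integer(factor(memb[present])),
        method = "adjusted.rand"
      )
    }
  }

  qres <- NULL
  if (qpcr) {
    qsim <- simulate_qpcr(cfg, sim)
    eff <- qsim$dilution |>
      group_by(.data$gene) |>
      dplyr::group_modify(~ estimate_efficiency(.x)) |>
      ungroup()
    quant <- pfaffl_quantify(qsim$ct, eff, qsim$reference_gene)
    targets <- setdiff(qsim$truth$gene, qsim$reference_gene)
    probe_of <- setNames(sim$truth$probe_id, sim$truth$gene_id)
    qres <- purrr::map(targets, function(g) {
      qs <- filter(quant, .data$gene == g)
      ma <- sim$values[probe_of[[g]], qs$sample_id]
      bind_cols(tibble(gene = g),
                validate_against_microarray(qs$log2_ratio, ma))
    }) |> bind_rows()
  }
  recovery$qpcr <- qres

  list(data = c(sim, list(design = design, genesets = sets)),
       pipeline = pipe, recovery = recovery)
}
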