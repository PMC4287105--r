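#' Read and write log2 expression matrices
#'
#' Tab-delimited layout: first column probe ids, header row sample ids,
#' numeric body. `read_expression()` preserves file order and refuses
#' duplicated probe or sample ids; non-numeric cells raise a parse error
#' naming the offending probe row and sample column.
#'
#' @param path File path.
#' @return `read_expression()`: a numeric matrix (probes x samples) with
#'   probe ids as rownames and sample ids as colnames.
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) abort("expression file needs a probe column and at least one sample")
  probe_id <- raw[[1]]
  if (anyDuplicated(probe_id)) {
    abort(paste0("duplicated probe id: ",
                 probe_id[duplicated(probe_id)][1]))
  }
  sample_id <- colnames(raw)[-1]
  if (anyDuplicated(sample_id)) {
    abort(paste0("duplicated sample id: ",
                 sample_id[duplicated(sample_id)][1]))
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(
    as.numeric(body), nrow = nrow(body),
    dimnames = list(probe_id, sample_id)
  ))
  if (anyNA(values) && !anyNA(body)) {
    bad <- which(is.na(values) & !is.na(body), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-numeric value '%s' at probe '%s', sample '%s'",
      body[bad[1], bad[2]], probe_id[bad[1]], sample_id[bad[2]]
    ))
  }
  values
}

#' @rdname read_expression
#' @param values Numeric probes x samples matrix with dimnames.
#' @export
write_expression <- function(values, path) {
  df <- data.frame(probe_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Two-column tab-delimited file `probe_id<TAB>gene_symbol`; the symbol
#' `"unannotated"` (or an empty field) marks probes without a gene.
#'
#' @param path File path.
#' @return Tibble with columns `probe_id`, `gene_symbol`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  names(df)[1:2] <- c("probe_id", "gene_symbol")
  df$gene_symbol[df$gene_symbol == "" | is.na(df$gene_symbol)] <- "unannotated"
  as_tibble(df[, 1:2])
}

#' Read a sample design table
#'
#' Comma-separated file with header
#' `sample_id,sow_id,age,fetal_genotype`; parental genotypes are derived
#' via [complete_design()].
#'
#' @param path File path.
#' @return A completed design tibble.
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  complete_design(df)
}

#' @rdname read_design
#' @param design Design tibble.
#' @export
write_design <- function(design, path) {
  utils::write.csv(
    design[, c("sample_id", "sow_id", "age", "fetal_genotype")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read and write gene-set collections in GMT format
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) abort("duplicated set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same distribution of values:
#' each column's sorted values are replaced by the rank-wise means of the
#' sorted columns, preserving within-column rank order. Ties receive the
#' mean of the target values over the tied ranks, so the operation is
#' deterministic and permutation-invariant. Normalization operates on the
#' supplied scale; the pipeline convention is log2 input.
#'
#' @param values Numeric probes x samples matrix without missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  if (anyNA(values)) abort("quantile_normalize requires a complete matrix")
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Principal component scores for sample-level quality control
#'
#' PCA of samples over probes (samples as observations, probes as
#' variables, centred and unscaled -- expression is already on a common
#' log2 scale), used to check that the leading axes of variation follow the
#' design factors.
#'
#' @param values Numeric probes x samples matrix.
#' @param n_components Number of components to return; truncated with a
#'   warning when it exceeds the rank of the centred data.
#' @return An object of class `expr_pca`: list with `scores` (tibble
#'   `sample_id`, `PC1`, ...) and `variance` (tibble `component`,
#'   `variance_fraction`, non-increasing, summing to <= 1).
#' @export
pca_scores <- function(values, n_components = 3) {
  if (ncol(values) < 2) abort("PCA needs at least 2 samples")
  p <- prcomp(t(values), center = TRUE, scale. = FALSE)
  rank <- sum(p$sdev > max(p$sdev) * 1e-12)
  if (n_components > rank) {
    warn(sprintf("n_components truncated from %d to rank %d",
                 n_components, rank))
    n_components <- rank
  }
  frac <- p$sdev^2 / sum(p$sdev^2)
  scores <- as_tibble(p$x[, seq_len(n_components), drop = FALSE])
  scores <- bind_cols(tibble(sample_id = colnames(values)), scores)
  out <- list(
    scores = scores,
    variance = tibble(
      component = seq_len(n_components),
      variance_fraction = frac[seq_len(n_components)]
    )
  )
  class(out) <- "expr_pca"
  out
}

#' @export
print.expr_pca <- function(x, ...) {
  cat("PCA of samples;", nrow(x$scores), "samples,",
      nrow(x$variance), "components\n")
  print(x$variance)
  invisible(x)
}
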