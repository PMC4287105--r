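#' Fit the four candidate fixed-effect sub-models to one probe
#'
#' The differentially expressed probes are partitioned by which fixed-effect
#' structure best explains them; all four candidates keep the random sow
#' intercept:
#' * sub-model 1: age + genotype + age:genotype;
#' * sub-model 2: age + genotype (additive);
#' * sub-model 3: age only;
#' * sub-model 4: genotype only.
#'
#' @param y Numeric log2 expression vector.
#' @param design Design tibble.
#' @return Named list of four `mixed_fit` objects
#'   (`submodel1` ... `submodel4`).
#' @seealso [classify_submodels()] for the batched version over a DEP list.
#' @export
fit_submodels <- function(y, design) {
  design <- ensure_parental(design)
  shorthands <- c(submodel1 = "full", submodel2 = "additive",
                  submodel3 = "age", submodel4 = "genotype")
  lapply(shorthands, function(s) fit_mixed(y, design, s))
}

submodel_terms <- c(submodel1 = "full", submodel2 = "additive",
                    submodel3 = "age", submodel4 = "genotype")

#' Assign each DEP to its BIC-best sub-model
#'
#' Fits the four candidate sub-models to every listed probe by profile ML
#' and labels each probe with the sub-model minimising
#' `BIC = -2 loglik + (rank + 2) log(n)` (see [bic()]). Exact BIC ties are
#' broken toward the most parsimonious sub-model (fewest parameters:
#' age-only before genotype-only before additive before interaction).
#'
#' @param values Log2 expression matrix (probes x samples).
#' @param design Design tibble.
#' @param probes Probe ids to classify (typically the DEP list from
#'   [call_deps()]); defaults to all rows.
#' @return A tibble: `probe_id`, `bic_1` ... `bic_4`, `label` (integer
#'   1-4), `delta_bic` (gap to the runner-up, >= 0).
#' @export
classify_submodels <- function(values, design, probes = rownames(values)) {
  design <- ensure_parental(design)
  design <- check_design_matches(values, design)
  str <- sow_structure(design$sow_id)
  missing_probes <- setdiff(probes, rownames(values))
  if (length(missing_probes) > 0) {
    abort(paste0("probes absent from the matrix: ",
                 paste(head(missing_probes, 3), collapse = ", ")))
  }
  Y <- t(values[probes, , drop = FALSE])
  n <- nrow(Y)
  bics <- matrix(NA_real_, nrow = length(probes), ncol = 4)
  ranks <- integer(4)
  for (m in 1:4) {
    X <- fixed_design_matrix(submodel_terms[m], design)
    mf <- fit_mixed_matrix(Y, X, str)
    ranks[m] <- mf$rank
    bics[, m] <- -2 * mf$loglik + (mf$rank + 2) * log(n)
  }
  label <- apply(bics, 1, pick_bic_label, ranks = ranks)
  delta <- apply(bics, 1, function(b) {
    s <- sort(b)
    s[2] - s[1]
  })
  tibble(
    probe_id = probes,
    bic_1 = bics[, 1], bic_2 = bics[, 2],
    bic_3 = bics[, 3], bic_4 = bics[, 4],
    label = as.integer(label),
    delta_bic = delta
  )
}

# argmin BIC with exact ties broken toward the fewest parameters
pick_bic_label <- function(b, ranks) {
  pars_order <- order(ranks)
  pars_order[which(b[pars_order] == min(b))[1]]
}

#' Sub-model label proportions
#'
#' @param assignments Tibble from [classify_submodels()].
#' @return Tibble `label`, `n`, `proportion` (over all assigned probes;
#'   proportions sum to 1).
#' @export
submodel_proportions <- function(assignments) {
  counts <- table(factor(assignments$label, levels = 1:4))
  tibble(
    label = 1:4,
    n = as.integer(counts),
    proportion = as.numeric(counts) / max(1L, nrow(assignments))
  )
}
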