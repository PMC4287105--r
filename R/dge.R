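#' Per-probe differential expression over the age x genotype design
#'
#' Fits the full mixed model (age + fetal genotype + interaction + random
#' sow intercept) to every probe of a log2 expression matrix, tests it
#' against the null model `y = mu + S + e` with the GLS F-type test, adjusts
#' p-values (Bonferroni and Benjamini-Hochberg), and computes model-based
#' log2 fold changes between gestational ages: one per fetal genotype
#' (estimated cell mean at d110 minus at d90) and their unweighted average
#' over genotypes ("overall", sign convention d110/d90).
#'
#' Probes with zero variance are reported with `status = "not_testable"`
#' and NA statistics; they are excluded from the multiple-testing family.
#'
#' @param values Numeric matrix of log2 expression, probes x samples, with
#'   probe ids as rownames and sample ids as colnames.
#' @param design Design tibble ([complete_design()] is applied if the
#'   parental columns are absent); samples are matched to columns by
#'   `sample_id`.
#' @return A tibble with one row per probe: `probe_id`, `F_stat`, `df_num`,
#'   `df_den`, `p_raw`, `p_bonferroni`, `q_bh`, `log2fc_age_overall`,
#'   `log2fc_age_<genotype>` for each observed genotype, the variance
#'   components, `loglik_full` and `status`.
#' @seealso [call_deps()], [classify_submodels()], [select_regulated()]
#' @examples
#' cfg <- sim_config(seed = 3, n_genes = c(null = 30, submodel3 = 10))
#' des <- simulate_design(cfg)
#' sim <- simulate_expression(cfg, des)
#' res <- dge_test(sim$values, des)
#' head(call_deps(res))
#' @export
dge_test <- function(values, design) {
  design <- ensure_parental(design)
  design <- check_design_matches(values, design)
  str <- sow_structure(design$sow_id)
  X_full <- fixed_design_matrix("full", design)
  X_null <- fixed_design_matrix("null", design)

  probe_id <- rownames(values) %||% paste0("probe_", seq_len(nrow(values)))
  Y <- t(values)
  testable <- unname(apply(Y, 2, sd) > 0)
  n <- nrow(Y)

  res <- tibble(
    probe_id = probe_id,
    F_stat = NA_real_, df_num = NA_integer_, df_den = NA_integer_,
    p_raw = NA_real_, p_bonferroni = NA_real_, q_bh = NA_real_,
    sigma2_sow = NA_real_, sigma2_resid = NA_real_,
    loglik_full = NA_real_,
    status = ifelse(testable, "ok", "not_testable")
  )
  fc <- fold_change_frame(probe_id, design)

  if (any(testable)) {
    Yt <- Y[, testable, drop = FALSE]
    # REML covariance for testing: removes the ML bias in the sow variance
    mf <- fit_mixed_matrix(Yt, X_full, str, criterion = "reml")
    rank_null <- qr(X_null)$rank
    df_num <- mf$rank - rank_null
    df_den <- n - mf$rank
    rss_null <- rss_at_lambda(Yt, X_null, str, mf$lambda)
    F_stat <- pmax(0, rss_null - mf$rss) / df_num / (mf$rss / df_den)
    res$F_stat[testable] <- F_stat
    res$df_num[testable] <- as.integer(df_num)
    res$df_den[testable] <- as.integer(df_den)
    res$p_raw[testable] <- pf(F_stat, df_num, df_den, lower.tail = FALSE)
    res$sigma2_sow[testable] <- mf$sigma2_sow
    res$sigma2_resid[testable] <- mf$sigma2_resid
    res$loglik_full[testable] <- mf$loglik
    res$p_bonferroni[testable] <- adjust_pvalues(res$p_raw[testable], "bonferroni")
    res$q_bh[testable] <- adjust_pvalues(res$p_raw[testable], "bh")
    fc[testable, -1] <- as.data.frame(
      fold_changes_from_beta(mf$beta, X_full, design)
    )
  }
  n_skipped <- sum(!testable)
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " zero-variance probe(s) flagged not_testable"))
  }
  bind_cols(res[, 1:7], fc[, -1, drop = FALSE], res[, 8:11])
}

ensure_parental <- function(design) {
  if (!all(c("maternal_genotype", "paternal_genotype") %in% names(design))) {
    design <- complete_design(design)
  }
  design
}

fold_change_frame <- function(probe_id, design) {
  genos <- levels(design$fetal_genotype)
  out <- tibble(probe_id = probe_id, log2fc_age_overall = NA_real_)
  for (g in genos) out[[paste0("log2fc_age_", g)]] <- NA_real_
  out
}

# model-estimated cell means on the observed age x genotype grid;
# beta is p x G (NA rows for aliased columns are treated as zero)
fold_changes_from_beta <- function(beta, X_full, design) {
  cells <- dplyr::distinct(design, .data$age, .data$fetal_genotype)
  grid <- tidyr::expand_grid(
    age = factor(c("d90", "d110"), levels = levels(design$age)),
    fetal_genotype = factor(
      levels(design$fetal_genotype), levels = levels(design$fetal_genotype)
    )
  )
  grid$observed <- interaction(grid$age, grid$fetal_genotype) %in%
    interaction(cells$age, cells$fetal_genotype)
  Xg <- model.matrix(attr(X_full, "mn_formula"), data = grid)
  beta0 <- beta
  beta0[is.na(beta0)] <- 0
  means <- Xg %*% beta0                      # 8 x G
  means[!grid$observed, ] <- NA_real_
  genos <- levels(design$fetal_genotype)
  per_geno <- sapply(genos, function(g) {
    i110 <- which(grid$fetal_genotype == g & grid$age == "d110")
    i90 <- which(grid$fetal_genotype == g & grid$age == "d90")
    means[i110, ] - means[i90, ]
  })                                          # G x 4
  if (is.null(dim(per_geno))) per_geno <- matrix(per_geno, nrow = 1,
                                                 dimnames = list(NULL, genos))
  overall <- rowMeans(per_geno, na.rm = TRUE)
  overall[!is.finite(overall)] <- NA_real_
  out <- cbind(log2fc_age_overall = overall, per_geno)
  colnames(out) <- c("log2fc_age_overall", paste0("log2fc_age_", genos))
  out
}

#' Log2 fold changes between gestational ages from a full mixed fit
#'
#' Computes, from a single-probe full-model fit, the model-estimated cell
#' mean difference d110 minus d90 for each fetal genotype and their
#' unweighted mean over the genotypes observed in the design. Positive
#' values mean higher expression at day 110.
#'
#' @param fit A `mixed_fit` from [fit_mixed()] with the full
#'   age x fetal-genotype term set.
#' @return A one-row tibble: `log2fc_age_overall` plus one
#'   `log2fc_age_<genotype>` column per genotype level (NA for genotypes
#'   absent from the design).
#' @export
log2_fold_changes <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  design <- fit$design_frame
  fc <- fold_changes_from_beta(
    matrix(fit$beta, ncol = 1), fit$X, design
  )
  as_tibble(as.data.frame(fc))
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up adjusted
#' p-values, with `m` the number of supplied (non-missing) tests.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\] (NA allowed; kept NA
#'   and excluded from `m`).
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = if (method == "bh") "BH" else "bonferroni")
  out
}

#' Call differentially expressed probes
#'
#' Probes whose adjusted p-value falls below the significance threshold
#' (default: Bonferroni-adjusted p < 0.01, the conservative cutoff used for
#' the main DEP list). Input order is preserved.
#'
#' @param results Tibble from [dge_test()] (or any table with `probe_id`
#'   and the relevant adjusted-p column).
#' @param alpha Significance threshold on the adjusted p-value.
#' @param method `"bonferroni"` (uses `p_bonferroni`) or `"bh"` (uses
#'   `q_bh`).
#' @return Character vector of DEP probe ids.
#' @export
call_deps <- function(results, alpha = 0.01, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  col <- if (method == "bonferroni") "p_bonferroni" else "q_bh"
  if (nrow(results) == 0) return(character(0))
  keep <- !is.na(results[[col]]) & results[[col]] < alpha
  results$probe_id[keep]
}
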