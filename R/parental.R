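#' Parental-genotype mixed model for one probe
#'
#' The reciprocal cross maps the four fetal genotypes onto a complete
#' 2 x 2 grid of maternal x paternal genotypes, which makes the two
#' parental contributions separable. The model carries fixed effects
#' age + maternal genotype + paternal genotype + age:maternal +
#' age:paternal + maternal:paternal, plus the random sow intercept.
#'
#' @param y Numeric log2 expression vector.
#' @param design Design tibble (parental columns derived by
#'   [complete_design()] if absent).
#' @return A `mixed_fit`.
#' @section Errors: a design that does not populate all four
#'   maternal x paternal cells (e.g. purebreds only) cannot identify the
#'   parental terms and raises an error naming the absent cell.
#' @export
fit_parental <- function(y, design) {
  design <- ensure_parental(design)
  check_parental_cells(design)
  fit_mixed(y, design, "parental")
}

check_parental_cells <- function(design) {
  grid <- tidyr::expand_grid(
    maternal_genotype = c("LW", "MS"), paternal_genotype = c("LW", "MS")
  )
  seen <- dplyr::distinct(
    design, .data$maternal_genotype, .data$paternal_genotype
  )
  absent <- dplyr::anti_join(
    grid,
    dplyr::mutate(seen, across(dplyr::everything(), as.character)),
    by = c("maternal_genotype", "paternal_genotype")
  )
  if (nrow(absent) > 0) {
    abort(sprintf(
      "parental model unidentifiable: no samples with maternal %s x paternal %s",
      absent$maternal_genotype[1], absent$paternal_genotype[1]
    ))
  }
  invisible(design)
}

#' Test age-by-maternal and age-by-paternal genotype interactions
#'
#' For every probe, fits the full parental model (see [fit_parental()]) and
#' performs two GLS F-type tests against reduced models dropping exactly
#' one term: the age:maternal interaction (sensitivity to the dam's breed)
#' or the age:paternal interaction (sensitivity to the sire's breed).
#' P-values are FDR-adjusted (Benjamini-Hochberg) across probes separately
#' for each side, and probes are called `maternal`, `paternal`, `both` or
#' `none` at the given q threshold. The two lists are not forced to be
#' disjoint: the overlap is reported explicitly as `both`.
#'
#' @param values Log2 expression matrix (probes x samples).
#' @param design Design tibble.
#' @param q_threshold FDR threshold for the calls.
#' @return Tibble: `probe_id`, `F_maternal`, `p_maternal`, `q_maternal`,
#'   `F_paternal`, `p_paternal`, `q_paternal`, `call`, `status`.
#' @export
test_parental_interactions <- function(values, design, q_threshold = 0.01) {
  design <- ensure_parental(design)
  design <- check_design_matches(values, design)
  check_parental_cells(design)
  str <- sow_structure(design$sow_id)
  X_full <- fixed_design_matrix("parental", design)
  red_m <- ~ age + maternal_genotype + paternal_genotype +
    age:paternal_genotype + maternal_genotype:paternal_genotype
  red_p <- ~ age + maternal_genotype + paternal_genotype +
    age:maternal_genotype + maternal_genotype:paternal_genotype
  X_red_m <- fixed_design_matrix(red_m, design)
  X_red_p <- fixed_design_matrix(red_p, design)

  probe_id <- rownames(values) %||% paste0("probe_", seq_len(nrow(values)))
  Y <- t(values)
  testable <- unname(apply(Y, 2, sd) > 0)
  n <- nrow(Y)

  out <- tibble(
    probe_id = probe_id,
    F_maternal = NA_real_, p_maternal = NA_real_, q_maternal = NA_real_,
    F_paternal = NA_real_, p_paternal = NA_real_, q_paternal = NA_real_,
    call = NA_character_,
    status = ifelse(testable, "ok", "not_testable")
  )
  if (any(testable)) {
    Yt <- Y[, testable, drop = FALSE]
    mf <- fit_mixed_matrix(Yt, X_full, str, criterion = "reml")
    df_den <- n - mf$rank
    for (side in c("maternal", "paternal")) {
      Xr <- if (side == "maternal") X_red_m else X_red_p
      df_num <- mf$rank - qr(Xr)$rank
      rss_r <- rss_at_lambda(Yt, Xr, str, mf$lambda)
      Fs <- pmax(0, rss_r - mf$rss) / df_num / (mf$rss / df_den)
      ps <- pf(Fs, df_num, df_den, lower.tail = FALSE)
      out[[paste0("F_", side)]][testable] <- Fs
      out[[paste0("p_", side)]][testable] <- ps
      out[[paste0("q_", side)]][testable] <- adjust_pvalues(ps, "bh")
    }
    m_sig <- out$q_maternal < q_threshold
    p_sig <- out$q_paternal < q_threshold
    out$call <- dplyr::case_when(
      m_sig & p_sig ~ "both",
      m_sig ~ "maternal",
      p_sig ~ "paternal",
      !is.na(m_sig) ~ "none",
      TRUE ~ NA_character_
    )
  }
  out
}
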