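#' Amplification efficiency from a dilution-series standard curve
#'
#' Least-squares fit of `Ct ~ log10(concentration)` over a serial dilution
#' (the standard scheme is four points at relative concentrations 1, 1/2,
#' 1/4, 1/8). The amplification efficiency is `E = 10^(-1/slope)` (fold of
#' product per cycle; a perfectly doubling reaction has slope
#' `-1/log10(2) = -3.3219` and `E = 2`).
#'
#' @param dilution Tibble/data frame with columns `concentration` (> 0,
#'   relative) and `Ct`; at least 3 distinct concentrations.
#' @return A one-row tibble: `E`, `slope`, `intercept`, `r_squared`.
#' @section Errors: a non-negative slope means no amplification and raises
#'   an error.
#' @export
estimate_efficiency <- function(dilution) {
  if (!all(c("concentration", "Ct") %in% names(dilution))) {
    abort("dilution table needs columns concentration, Ct")
  }
  if (any(dilution$concentration <= 0)) abort("concentrations must be positive")
  if (length(unique(dilution$concentration)) < 3) {
    abort("need at least 3 distinct concentrations")
  }
  fit <- lm(Ct ~ log10(concentration), data = dilution)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("non-amplifying standard curve (slope >= 0)")
  tss <- sum((dilution$Ct - mean(dilution$Ct))^2)
  rss <- sum(residuals(fit)^2)
  tibble(
    E = 10^(-1 / slope),
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = if (tss > 0) 1 - rss / tss else 1
  )
}

#' Pfaffl efficiency-corrected relative expression ratio
#'
#' Relative expression of a target gene in a sample versus a calibrator,
#' normalized by a reference gene, each with its own amplification
#' efficiency:
#' \deqn{ratio = \frac{E_{target}^{\,Ct_{target,cal} - Ct_{target,sample}}}
#'   {E_{ref}^{\,Ct_{ref,cal} - Ct_{ref,sample}}}}
#' With all efficiencies equal to 2 this reduces to the classical
#' \eqn{2^{-\Delta\Delta Ct}} method.
#'
#' @param ct_target_calibrator,ct_target_sample Target-gene Ct values.
#' @param ct_ref_calibrator,ct_ref_sample Reference-gene Ct values.
#' @param e_target,e_ref Amplification efficiencies; theoretically in
#'   (1, 2], but standard-curve estimates may slightly exceed 2 under Ct
#'   noise and are accepted. Values <= 1 (no amplification) are an error.
#' @return Relative expression ratio (1 = no change vs calibrator).
#' @export
pfaffl_ratio <- function(ct_target_calibrator, ct_target_sample,
                         ct_ref_calibrator, ct_ref_sample,
                         e_target, e_ref) {
  if (any(c(e_target, e_ref) <= 1)) {
    abort("efficiencies must exceed 1")
  }
  e_target^(ct_target_calibrator - ct_target_sample) /
    e_ref^(ct_ref_calibrator - ct_ref_sample)
}

#' Per-sample Pfaffl relative expression for a Ct table
#'
#' Averages technical replicates on the Ct scale, uses the mean Ct of each
#' gene over all samples as its calibrator (a configurable choice), and
#' computes the Pfaffl ratio of every target gene in every sample against
#' the reference gene.
#'
#' @param ct Tibble `gene`, `sample_id`, `replicate`, `Ct`.
#' @param efficiencies Tibble `gene`, `E` (e.g. from
#'   [estimate_efficiency()] per gene).
#' @param reference_gene Name of the reference gene present in `ct`.
#' @return Tibble `gene`, `sample_id`, `ratio`, `log2_ratio` for all
#'   non-reference genes.
#' @export
pfaffl_quantify <- function(ct, efficiencies, reference_gene) {
  if (!reference_gene %in% ct$gene) {
    abort(paste0("reference gene ", reference_gene, " absent from Ct table"))
  }
  mean_ct <- ct |>
    group_by(.data$gene, .data$sample_id) |>
    summarise(Ct = mean(.data$Ct), .groups = "drop")
  eff <- setNames(efficiencies$E, efficiencies$gene)
  missing_e <- setdiff(unique(mean_ct$gene), names(eff))
  if (length(missing_e) > 0) {
    abort(paste0("no efficiency for gene(s): ",
                 paste(head(missing_e, 3), collapse = ", ")))
  }
  calib <- mean_ct |>
    group_by(.data$gene) |>
    summarise(ct_cal = mean(.data$Ct), .groups = "drop")
  ref <- mean_ct |>
    filter(.data$gene == reference_gene) |>
    select("sample_id", ct_ref = "Ct")
  ref_cal <- calib$ct_cal[calib$gene == reference_gene]
  e_ref <- eff[[reference_gene]]

  mean_ct |>
    filter(.data$gene != reference_gene) |>
    left_join(calib, by = "gene") |>
    left_join(ref, by = "sample_id") |>
    mutate(
      ratio = as.numeric(pfaffl_ratio(
        .data$ct_cal, .data$Ct, ref_cal, .data$ct_ref,
        unname(eff[.data$gene]), e_ref
      )),
      log2_ratio = log2(.data$ratio)
    ) |>
    select("gene", "sample_id", "ratio", "log2_ratio")
}

#' Correlate qPCR quantification with microarray expression
#'
#' Pearson correlation between log2-transformed Pfaffl ratios and log2
#' microarray values over paired samples (like-for-like log2 scales), with
#' the two-sided p-value from the t approximation.
#'
#' @param qpcr_log2 Numeric vector of log2 qPCR relative expression.
#' @param microarray_log2 Numeric vector of log2 microarray expression for
#'   the same samples, in the same order.
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
validate_against_microarray <- function(qpcr_log2, microarray_log2) {
  if (length(qpcr_log2) != length(microarray_log2)) {
    abort("paired vectors must have equal length")
  }
  ok <- is.finite(qpcr_log2) & is.finite(microarray_log2)
  if (sum(ok) < 3) abort("need at least 3 paired samples")
  ct <- cor.test(qpcr_log2[ok], microarray_log2[ok], method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
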