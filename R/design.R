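#' Sample design tables for the reciprocal-cross experiment
#'
#' The experiment crosses Large White (LW) and Meishan (MS) pigs both ways:
#' sows of each breed are inseminated with mixed LW + MS semen, so every
#' litter contains purebred fetuses (same breed as the sow) and crossbred
#' fetuses. Crossbreds are named sire-first: `LWMS` fetuses (LW sire, MS dam)
#' come from MS sows, `MSLW` fetuses (MS sire, LW dam) from LW sows.
#' `complete_design()` derives the maternal and paternal genotype of each
#' fetus from its fetal genotype and checks the structural invariants of the
#' design.
#'
#' @details
#' Genotype bookkeeping:
#' * `LW` purebred: maternal LW, paternal LW (from LW sows);
#' * `MS` purebred: maternal MS, paternal MS (from MS sows);
#' * `LWMS` crossbred carried by MS sows: maternal MS, paternal LW;
#' * `MSLW` crossbred carried by LW sows: maternal LW, paternal MS.
#'
#' Each sow is sampled at a single gestational age (fetuses are collected by
#' caesarean), so the sow (litter) random effect is nested within
#' age x maternal genotype.
#'
#' @param design A data frame with columns `sample_id`, `sow_id`, `age`
#'   (values `"d90"`/`"d110"`) and `fetal_genotype` (values `"LW"`, `"MS"`,
#'   `"LWMS"`, `"MSLW"`).
#' @return A tibble with the input columns plus `maternal_genotype` and
#'   `paternal_genotype`, with `age` and genotype columns as factors with
#'   fixed level order (`d90` and `LW` first, the model reference levels).
#' @examples
#' d <- tibble::tibble(
#'   sample_id = c("s1", "s2"), sow_id = c(1, 1),
#'   age = "d90", fetal_genotype = c("LW", "MSLW")
#' )
#' complete_design(d)
#' @export
complete_design <- function(design) {
  design <- as_tibble(design)
  required <- c("sample_id", "sow_id", "age", "fetal_genotype")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("design is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) {
    abort("duplicated sample_id in design")
  }
  age <- as.character(design$age)
  fg <- as.character(design$fetal_genotype)
  if (!all(age %in% c("d90", "d110"))) {
    abort("age must be 'd90' or 'd110'")
  }
  if (!all(fg %in% c("LW", "MS", "LWMS", "MSLW"))) {
    abort("fetal_genotype must be one of LW, MS, LWMS, MSLW")
  }
  mg <- c(LW = "LW", MS = "MS", LWMS = "MS", MSLW = "LW")[fg]
  pg <- c(LW = "LW", MS = "MS", LWMS = "LW", MSLW = "MS")[fg]
  out <- design
  out$age <- factor(age, levels = c("d90", "d110"))
  out$fetal_genotype <- factor(fg, levels = c("LW", "MS", "LWMS", "MSLW"))
  out$maternal_genotype <- factor(unname(mg), levels = c("LW", "MS"))
  out$paternal_genotype <- factor(unname(pg), levels = c("LW", "MS"))
  out$sow_id <- as.character(out$sow_id)

  # all fetuses of a sow must share maternal genotype and age
  per_sow <- dplyr::distinct(out, .data$sow_id, .data$age, .data$maternal_genotype)
  if (anyDuplicated(per_sow$sow_id)) {
    abort("each sow must have a single age and a single maternal genotype")
  }
  out
}

check_design_matches <- function(values, design) {
  if (!setequal(colnames(values), design$sample_id)) {
    abort("sample ids of the expression matrix and the design table differ")
  }
  design[match(colnames(values), design$sample_id), , drop = FALSE]
}
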