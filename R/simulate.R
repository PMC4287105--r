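#' Simulation configuration for the reciprocal-cross generator
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design: 9 LW + 9 MS sows, 61 fetuses in total (litters of 3-4,
#' each containing purebred and crossbred fetuses), two gestational ages
#' assigned between sows (each sow is sampled once, so the litter effect is
#' nested within age x maternal genotype), a random sow intercept of
#' standard deviation 0.3 log2 units and residual noise of 0.5 log2 units,
#' and fixed effects of 1 log2 unit so that the fold-change filter at
#' log2(1.4) ~ 0.485 is meaningfully straddled.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_sows_per_maternal_genotype Sows per breed of dam (default 9).
#' @param n_fetuses Total fetuses; distributed as evenly as possible over
#'   sows (base litter floor(n/sows), remainders assigned round-robin
#'   alternating between the LW and MS sow groups). Litters must hold at
#'   least 2 fetuses so both the purebred and the crossbred genotype can be
#'   placed.
#' @param sigma_sow,sigma_resid Random sow-effect and residual standard
#'   deviations (log2 units).
#' @param n_genes Named counts per generative class; names among
#'   `null`, `submodel1`, `submodel2`, `submodel3`, `submodel4`,
#'   `maternal_interaction`, `paternal_interaction`,
#'   `network_block_1` ... `network_block_4`. Unnamed classes default to 0.
#' @param effect_size Fixed-effect magnitude (log2 units).
#' @param block_within_correlation Target absolute pairwise Pearson
#'   correlation inside each planted network block.
#' @param baseline_mean Baseline log2 expression.
#' @param unannotated_fraction Fraction of null-class probes left without a
#'   gene annotation (exercises the probe-to-gene collapse bookkeeping).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_sows_per_maternal_genotype = 9,
                       n_fetuses = 61,
                       sigma_sow = 0.3,
                       sigma_resid = 0.5,
                       n_genes = NULL,
                       effect_size = 1.0,
                       block_within_correlation = 0.99,
                       baseline_mean = 8,
                       unannotated_fraction = 0.02) {
  default_genes <- c(
    null = 400, submodel1 = 100, submodel2 = 100, submodel3 = 100,
    submodel4 = 100, maternal_interaction = 50, paternal_interaction = 50,
    network_block_1 = 25, network_block_2 = 25, network_block_3 = 25,
    network_block_4 = 25
  )
  if (is.null(n_genes)) {
    n_genes <- default_genes
  } else {
    if (is.null(names(n_genes)) || !all(names(n_genes) %in% names(default_genes))) {
      abort(paste0(
        "n_genes must be a named vector with names among: ",
        paste(names(default_genes), collapse = ", ")
      ))
    }
    full <- setNames(rep(0, length(default_genes)), names(default_genes))
    full[names(n_genes)] <- n_genes
    n_genes <- full
  }
  if (any(n_genes < 0)) abort("gene counts must be >= 0")
  if (sigma_sow < 0 || sigma_resid <= 0) abort("standard deviations must be positive")
  if (block_within_correlation <= 0 || block_within_correlation >= 1) {
    abort("block_within_correlation must lie in (0, 1)")
  }
  cfg <- list(
    seed = as.integer(seed),
    n_sows_per_maternal_genotype = as.integer(n_sows_per_maternal_genotype),
    n_fetuses = as.integer(n_fetuses),
    sigma_sow = sigma_sow, sigma_resid = sigma_resid,
    n_genes = n_genes, effect_size = effect_size,
    block_within_correlation = block_within_correlation,
    baseline_mean = baseline_mean,
    unannotated_fraction = unannotated_fraction
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the reciprocal-cross sampling design
#'
#' Builds the sample table deterministically from the configuration: sows
#' of each breed alternate between gestational ages, litters alternate
#' purebred and crossbred fetuses consistent with the dam's breed (LW sows
#' carry LW and MSLW fetuses, MS sows carry MS and LWMS fetuses), and all
#' eight age x fetal-genotype conditions are populated.
#'
#' @param cfg A [sim_config()].
#' @return A design tibble (see [complete_design()]).
#' @export
simulate_design <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_group <- cfg$n_sows_per_maternal_genotype
  n_sows <- 2L * n_group
  base <- cfg$n_fetuses %/% n_sows
  if (base < 2) {
    abort("fewer than 2 fetuses per sow: cannot place both within-litter genotypes")
  }
  extras <- cfg$n_fetuses - base * n_sows
  sizes <- rep(base, n_sows)
  if (extras > 0) {
    # round-robin alternating LW sows (1..n_group) and MS sows
    order_rr <- as.vector(rbind(seq_len(n_group), n_group + seq_len(n_group)))
    sizes[order_rr[seq_len(extras)]] <- base + 1L
  }
  maternal <- rep(c("LW", "MS"), each = n_group)
  # alternate ages within each maternal group, out of phase between groups
  age_sow <- c(
    rep_len(c("d90", "d110"), n_group),
    rep_len(c("d110", "d90"), n_group)
  )
  rows <- purrr::map(seq_len(n_sows), function(s) {
    m <- maternal[s]
    pure <- m
    cross <- if (m == "LW") "MSLW" else "LWMS"
    fg <- rep_len(c(pure, cross), sizes[s])
    tibble(
      sow_id = sprintf("sow%02d", s),
      age = age_sow[s],
      fetal_genotype = fg
    )
  })
  design <- bind_rows(rows)
  design$sample_id <- sprintf("F%03d", seq_len(nrow(design)))
  complete_design(design[, c("sample_id", "sow_id", "age", "fetal_genotype")])
}

sim_classes <- function() c(
  "null", "submodel1", "submodel2", "submodel3", "submodel4",
  "maternal_interaction", "paternal_interaction",
  paste0("network_block_", 1:4)
)

# per-sample fixed-effect mean for one gene of a given class/direction.
# e is the configured effect size; genotype offsets and age-by-genotype
# slopes are fixed patterns over (LW, MS, LWMS, MSLW).
class_cell_means <- function(class, direction, design, e, mu) {
  a <- as.numeric(design$age == "d110")
  g <- as.integer(design$fetal_genotype)           # LW, MS, LWMS, MSLW
  sgn <- if (identical(direction, "up_d90")) -1 else 1
  geno_half <- e * c(0, 0.5, 0.25, 0.25)
  geno_full <- e * c(0, 1, 0.5, 0.5)
  # genotype-specific age slopes: mean slope e (the overall fold change)
  # and age-by-genotype deviations of magnitude e (the interaction signal)
  delta_int <- e * c(0, 2, 1, 1)
  switch(class,
    null = rep(mu, nrow(design)),
    submodel1 = mu + geno_half[g] + sgn * delta_int[g] * a,
    submodel2 = mu + geno_full[g] + sgn * e * a,
    submodel3 = mu + sgn * e * a,
    submodel4 = mu + geno_full[g],
    maternal_interaction = mu +
      sgn * e * a * as.numeric(design$maternal_genotype == "MS"),
    paternal_interaction = mu +
      sgn * e * a * as.numeric(design$paternal_genotype == "MS"),
    abort(paste0("unknown class ", class))
  )
}

#' Simulate a log2 expression matrix with planted effect classes
#'
#' Generates one probe per configured gene: classes follow the
#' corresponding fixed-effect sub-model (age x genotype interaction,
#' additive, age-only, genotype-only), the parental-interaction classes add
#' an age-by-maternal or age-by-paternal genotype interaction, and network
#' blocks are driven by a shared latent factor scaled so that within-block
#' |Pearson r| hits the configured target. All non-block classes receive a
#' per-gene random sow intercept shared by littermates plus residual noise;
#' block genes trade the sow effect for exact control of their pairwise
#' correlation (the factor itself carries an age-by-genotype profile, so
#' block genes behave as interaction genes downstream). Within the
#' `submodel1` class and each block, effect signs alternate gene by gene so
#' both up-at-d110 and up-at-d90 genes exist; the first gene of each block
#' is a noise-free copy of the latent factor (a planted hub).
#'
#' @param cfg A [sim_config()].
#' @param design Design tibble from [simulate_design()].
#' @return A list: `values` (probes x samples log2 matrix), `annotation`
#'   (tibble `probe_id`, `gene_symbol`, with `"unannotated"` entries for
#'   the configured fraction of null probes), and `truth` (tibble
#'   `gene_id`, `probe_id`, `class`, `direction`, `block_id`,
#'   `is_block_parent`).
#' @export
simulate_expression <- function(cfg, design) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- nrow(design)
  sow_idx <- as.integer(factor(design$sow_id))
  n_sows <- max(sow_idx)
  counts <- cfg$n_genes[cfg$n_genes > 0]
  total <- sum(counts)
  if (total == 0) abort("no genes configured")

  values <- matrix(NA_real_, nrow = total, ncol = n)
  colnames(values) <- design$sample_id
  truth <- vector("list", length(counts))
  row0 <- 0L
  gene_no <- 0L
  for (ci in seq_along(counts)) {
    cls <- names(counts)[ci]
    ng <- counts[ci]
    ids <- sprintf("P%05d", gene_no + seq_len(ng))
    if (grepl("^network_block_", cls)) {
      block <- as.integer(sub("network_block_", "", cls))
      # latent factor: interaction-profile mean plus sample-level noise
      struct <- class_cell_means("submodel1", "up_d110", design,
                                 cfg$effect_size, 0)
      f <- struct + rnorm(n, 0, cfg$sigma_resid)
      r <- cfg$block_within_correlation
      sd_f <- sd(f)
      sd_eps <- sd_f * sqrt((1 - r) / r)
      sgn <- rep_len(c(1, -1), ng)
      mus <- cfg$baseline_mean + rnorm(ng, 0, 0.25)
      block_vals <- t(sapply(seq_len(ng), function(i) {
        eps <- if (i == 1) 0 else rnorm(n, 0, sd_eps)
        mus[i] + sgn[i] * f + eps
      }))
      values[row0 + seq_len(ng), ] <- block_vals
      truth[[ci]] <- tibble(
        probe_id = ids, class = cls,
        direction = ifelse(sgn > 0, "up_d110", "up_d90"),
        block_id = block,
        is_block_parent = seq_len(ng) == 1
      )
    } else {
      dir <- if (cls %in% c("submodel1", "submodel2", "submodel3")) {
        rep_len(c("up_d110", "up_d90"), ng)
      } else {
        rep("up_d110", ng)
      }
      cls_vals <- t(sapply(seq_len(ng), function(i) {
        mean_s <- class_cell_means(cls, dir[i], design, cfg$effect_size,
                                   cfg$baseline_mean)
        sow_eff <- rnorm(n_sows, 0, cfg$sigma_sow)[sow_idx]
        mean_s + sow_eff + rnorm(n, 0, cfg$sigma_resid)
      }))
      values[row0 + seq_len(ng), ] <- cls_vals
      truth[[ci]] <- tibble(
        probe_id = ids, class = cls,
        direction = if (cls %in% c("null", "submodel4")) NA_character_ else dir,
        block_id = NA_integer_,
        is_block_parent = FALSE
      )
    }
    row0 <- row0 + ng
    gene_no <- gene_no + ng
  }
  truth <- bind_rows(truth)
  rownames(values) <- truth$probe_id
  truth$gene_id <- sub("^P", "G", truth$probe_id)

  annotation <- tibble(
    probe_id = truth$probe_id,
    gene_symbol = truth$gene_id
  )
  null_rows <- which(truth$class == "null")
  n_unann <- floor(cfg$unannotated_fraction * length(null_rows))
  if (n_unann > 0) {
    annotation$gene_symbol[null_rows[seq_len(n_unann)]] <- "unannotated"
  }
  truth <- truth[, c("gene_id", "probe_id", "class", "direction",
                     "block_id", "is_block_parent")]
  list(values = values, annotation = annotation, truth = truth)
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' Builds a GMT-style collection over the annotated simulated genes: one
#' set enriched by construction in up-at-d110 interaction genes
#' (`planted_up_d110`) plus uniformly drawn decoy sets.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth tibble from [simulate_expression()].
#' @param n_decoys Number of decoy sets.
#' @param set_size Genes per set.
#' @param planted_overlap How many members of the planted set come from the
#'   up-at-d110 `submodel1` truth class (capped at the class size).
#' @return Named list of gene-symbol vectors (a gene-set collection as
#'   read/written by [read_gmt()] / [write_gmt()]).
#' @export
simulate_genesets <- function(cfg, truth, n_decoys = 20, set_size = 30,
                              planted_overlap = 25) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  universe <- truth$gene_id
  up <- truth$gene_id[truth$class == "submodel1" &
                        !is.na(truth$direction) & truth$direction == "up_d110"]
  k <- min(planted_overlap, length(up), set_size)
  planted <- c(
    sample(up, k),
    sample(setdiff(universe, up), max(0, set_size - k))
  )
  sets <- list(planted_up_d110 = planted)
  for (i in seq_len(n_decoys)) {
    sets[[sprintf("decoy_%02d", i)]] <- sample(universe, min(set_size, length(universe)))
  }
  sets
}

#' Simulate qPCR Ct tables with dilution-series standards
#'
#' For a subset of simulated genes (default: interaction-class genes) plus
#' a stable synthetic reference gene, generates threshold-cycle values
#' `Ct = intercept - log_E(2^y) + noise` with gene-specific amplification
#' efficiency `E ~ U(1.8, 2)`, and a four-point two-fold dilution series
#' (relative concentrations 1, 1/2, 1/4, 1/8) for standard-curve
#' efficiency estimation.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [simulate_expression()].
#' @param n_genes Number of target genes to assay.
#' @param n_replicates Technical replicates per sample.
#' @param ct_noise_sd Ct noise standard deviation (cycles) in the sample
#'   assay.
#' @param dilution_noise_sd Ct noise standard deviation in the dilution
#'   series.
#' @return A list: `ct` (tibble `gene`, `sample_id`, `replicate`, `Ct`),
#'   `dilution` (tibble `gene`, `concentration`, `Ct`), `truth` (tibble
#'   `gene`, `E`, `intercept`, `reference`), and `reference_gene` (its
#'   name, `"HPRT_sim"`).
#' @export
simulate_qpcr <- function(cfg, sim, n_genes = 10, n_replicates = 2,
                          ct_noise_sd = 0.2, dilution_noise_sd = 0.15) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  candidates <- sim$truth$probe_id[sim$truth$class == "submodel1"]
  if (length(candidates) < n_genes) {
    candidates <- sim$truth$probe_id
  }
  probes <- sample(candidates, n_genes)
  genes <- sub("^P", "G", probes)
  samples <- colnames(sim$values)

  expr <- rbind(
    sim$values[probes, , drop = FALSE],
    HPRT_sim = rep(cfg$baseline_mean, length(samples))
  )
  gene_names <- c(genes, "HPRT_sim")
  E <- runif(length(gene_names), 1.8, 2.0)
  intercept <- runif(length(gene_names), 24, 30)

  ct <- purrr::map(seq_along(gene_names), function(i) {
    logE <- log(E[i])
    tidyr::expand_grid(sample_id = samples, replicate = seq_len(n_replicates)) |>
      mutate(
        gene = gene_names[i],
        Ct = intercept[i] - expr[i, .data$sample_id] * log(2) / logE +
          rnorm(dplyr::n(), 0, ct_noise_sd)
      )
  }) |>
    bind_rows() |>
    select("gene", "sample_id", "replicate", "Ct")

  conc <- c(1, 1 / 2, 1 / 4, 1 / 8)
  dilution <- purrr::map(seq_along(gene_names), function(i) {
    tibble(
      gene = gene_names[i], concentration = conc,
      Ct = intercept[i] - log(conc) / log(E[i]) +
        rnorm(length(conc), 0, dilution_noise_sd)
    )
  }) |> bind_rows()

  list(
    ct = ct, dilution = dilution,
    truth = tibble(
      gene = gene_names, E = E, intercept = intercept,
      reference = gene_names == "HPRT_sim"
    ),
    reference_gene = "HPRT_sim"
  )
}
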