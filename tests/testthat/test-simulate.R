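test_that("default design reproduces the study geometry", {
  des <- simulate_design(sim_config(seed = 1))
  expect_equal(nrow(des), 61)
  expect_equal(length(unique(des$sow_id)), 18)
  cells <- table(des$age, des$fetal_genotype)
  expect_true(all(cells > 0))
  expect_equal(dim(cells), c(2L, 4L))
  # every litter holds the purebred and the crossbred of its dam
  litters <- split(as.character(des$fetal_genotype), des$sow_id)
  for (l in litters) {
    expect_length(unique(l), 2)
  }
  lw_sows <- unique(des$sow_id[des$maternal_genotype == "LW"])
  expect_setequal(
    unique(as.character(des$fetal_genotype[des$sow_id %in% lw_sows])),
    c("LW", "MSLW")
  )
})

test_that("tiny designs and invalid configurations behave as specified", {
  des <- simulate_design(sim_config(seed = 1, n_sows_per_maternal_genotype = 1,
                                    n_fetuses = 4))
  expect_equal(nrow(des), 4)
  lw_litter <- des$fetal_genotype[des$maternal_genotype == "LW"]
  expect_setequal(as.character(lw_litter), c("LW", "MSLW"))
  expect_error(
    simulate_design(sim_config(seed = 1, n_fetuses = 20)),
    "fewer than 2 fetuses"
  )
  expect_error(sim_config(n_genes = c(bogus = 5)), "named vector")
  expect_error(sim_config(sigma_resid = 0), "positive")
})

test_that("generators are deterministic in the seed", {
  cfg <- sim_config(seed = 99, n_genes = c(null = 20, submodel1 = 10,
                                           network_block_1 = 8))
  d1 <- simulate_design(cfg)
  d2 <- simulate_design(cfg)
  expect_identical(d1, d2)
  s1 <- simulate_expression(cfg, d1)
  s2 <- simulate_expression(cfg, d2)
  expect_identical(s1, s2)
  expect_identical(simulate_genesets(cfg, s1$truth),
                   simulate_genesets(cfg, s2$truth))
  expect_identical(simulate_qpcr(cfg, s1), simulate_qpcr(cfg, s2))
})

test_that("planted age effects match their construction", {
  cfg <- sim_config(seed = 101, n_genes = c(submodel3 = 200))
  des <- simulate_design(cfg)
  sim <- simulate_expression(cfg, des)
  d110 <- des$sample_id[des$age == "d110"]
  d90 <- des$sample_id[des$age == "d90"]
  diff <- rowMeans(sim$values[, d110]) - rowMeans(sim$values[, d90])
  sgn <- ifelse(sim$truth$direction == "up_d110", 1, -1)
  expect_lt(abs(mean(sgn * diff) - 1), 3 * sd(sgn * diff) / sqrt(200))
})

test_that("null genes carry the configured variance components", {
  cfg <- sim_config(seed = 102, n_genes = c(null = 1000))
  des <- simulate_design(cfg)
  sim <- simulate_expression(cfg, des)
  str <- maturnet:::sow_structure(des$sow_id)
  X <- maturnet:::fixed_design_matrix("null", des)
  mf <- maturnet:::fit_mixed_matrix(t(sim$values), X, str)
  expect_lt(abs(mean(mf$sigma2_sow) - 0.09), 0.15 * 0.09)
  expect_lt(abs(mean(mf$sigma2_resid) - 0.25), 0.15 * 0.25)
})

test_that("without a sow effect littermates are uncorrelated", {
  cfg <- sim_config(seed = 103, sigma_sow = 1e-12,
                    n_genes = c(null = 500))
  des <- simulate_design(cfg)
  sim <- simulate_expression(cfg, des)
  str <- maturnet:::sow_structure(des$sow_id)
  X <- maturnet:::fixed_design_matrix("null", des)
  mf <- maturnet:::fit_mixed_matrix(t(sim$values), X, str)
  icc <- mf$sigma2_sow / (mf$sigma2_sow + mf$sigma2_resid)
  # boundary estimates are non-negative, so the mean sits slightly above 0
  expect_lt(mean(icc), 0.06)
  # far below the ICC implied by the default sow effect, ~0.26
  expect_lt(quantile(icc, 0.9), 0.15)
})

test_that("network blocks hit their target correlation and stay separable", {
  cfg <- sim_config(seed = 104, n_genes = c(
    network_block_1 = 15, network_block_2 = 15
  ))
  des <- simulate_design(cfg)
  sim <- simulate_expression(cfg, des)
  b1 <- sim$truth$probe_id[sim$truth$block_id == 1]
  b2 <- sim$truth$probe_id[sim$truth$block_id == 2]
  S <- correlation_matrix(sim$values)
  within <- abs(S[b1, b1][upper.tri(diag(length(b1)))])
  across <- abs(S[b1, b2])
  expect_gt(median(within), 0.98)
  expect_lt(max(across), 0.98)
})

test_that("gene sets contain the planted enrichment and consistent members", {
  cfg <- sim_config(seed = 105)
  des <- simulate_design(cfg)
  sim <- simulate_expression(cfg, des)
  sets <- simulate_genesets(cfg, sim$truth, n_decoys = 5, set_size = 30,
                            planted_overlap = 25)
  expect_length(sets, 6)
  up <- sim$truth$gene_id[sim$truth$class == "submodel1" &
                            sim$truth$direction == "up_d110"]
  expect_equal(sum(sets$planted_up_d110 %in% up), 25)
  expect_true(all(unlist(sets) %in% sim$truth$gene_id))
})

test_that("simulated qPCR obeys its generative arithmetic", {
  cfg <- sim_config(seed = 106, n_genes = c(submodel1 = 12))
  des <- simulate_design(cfg)
  sim <- simulate_expression(cfg, des)
  q <- simulate_qpcr(cfg, sim, n_genes = 4, ct_noise_sd = 0,
                     dilution_noise_sd = 0)
  # noiseless dilution: Ct spacing per halving equals log(2)/log(E)
  for (g in unique(q$dilution$gene)) {
    d <- q$dilution[q$dilution$gene == g, ]
    e_g <- q$truth$E[q$truth$gene == g]
    expect_equal(diff(d$Ct), rep(log(2) / log(e_g), 3), tolerance = 1e-10)
    est <- estimate_efficiency(d)
    expect_equal(est$E, e_g, tolerance = 1e-10)
  }
  # the reference gene is flat across samples
  ref <- q$ct[q$ct$gene == q$reference_gene, ]
  expect_equal(var(ref$Ct), 0, tolerance = 1e-20)
})

test_that("Pfaffl recovery correlates with simulated truth under noise", {
  cfg <- sim_config(seed = 107)
  des <- simulate_design(cfg)
  sim <- simulate_expression(cfg, des)
  q <- simulate_qpcr(cfg, sim, n_genes = 10, ct_noise_sd = 0.2)
  eff <- q$dilution |>
    dplyr::group_by(gene) |>
    dplyr::group_modify(~ estimate_efficiency(.x)) |>
    dplyr::ungroup()
  quant <- pfaffl_quantify(q$ct, eff, q$reference_gene)
  probe_of <- setNames(sim$truth$probe_id, sim$truth$gene_id)
  rs <- vapply(setdiff(q$truth$gene, q$reference_gene), function(g) {
    qs <- quant[quant$gene == g, ]
    truth <- sim$values[probe_of[[g]], qs$sample_id]
    cor(qs$log2_ratio, truth)
  }, numeric(1))
  expect_gt(median(rs), 0.9)
})
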