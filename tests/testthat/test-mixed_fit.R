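test_that("with one fetus per sow the fit collapses to ordinary least squares", {
  set.seed(31)
  des <- one_fetus_per_sow_design(reps = 3)
  y <- 8 + rnorm(nrow(des), sd = 0.6)
  fit <- fit_mixed(y, des, "full")
  ols <- lm(y ~ age * fetal_genotype, data = des)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-7)
  expect_lt(fit$sigma2_sow, 1e-8)
})

test_that("profile optimum matches an independent dense-grid oracle", {
  set.seed(32)
  cfg <- sim_config(seed = 32, n_sows_per_maternal_genotype = 5,
                    n_fetuses = 30)
  des <- simulate_design(cfg)
  X <- model.matrix(~ age * fetal_genotype, des)
  for (i in 1:5) {
    y <- 8 + (des$age == "d110") * runif(1, 0, 1.5) +
      rnorm(10, 0, runif(1, 0.05, 0.6))[as.integer(factor(des$sow_id))] +
      rnorm(nrow(des), 0, 0.5)
    fit <- fit_mixed(y, des, "full")
    oracle <- grid_profile_loglik(y, X, des$sow_id)
    expect_equal(fit$loglik_ml, oracle, tolerance = 1e-6)
  }
})

test_that("fit matches lme4 maximum-likelihood estimates", {
  skip_if_not_installed("lme4")
  set.seed(33)
  cfg <- sim_config(seed = 33)
  des <- simulate_design(cfg)
  for (i in 1:3) {
    y <- 8 + (des$age == "d110") +
      rnorm(18, 0, 0.3)[as.integer(factor(des$sow_id))] +
      rnorm(nrow(des), 0, 0.5)
    fit <- fit_mixed(y, des, "full")
    lmm <- lme4::lmer(y ~ age * fetal_genotype + (1 | sow_id),
                      data = des, REML = FALSE)
    expect_equal(fit$loglik_ml, as.numeric(stats::logLik(lmm)),
                 tolerance = 1e-5)
    vc <- as.data.frame(lme4::VarCorr(lmm))$vcov
    expect_equal(c(fit$sigma2_sow, fit$sigma2_resid), vc, tolerance = 1e-3)
  }
})

test_that("parameter recovery over replicated simulated genes", {
  # submodel3 truth: mu = 8, age effect 1, sigma_sow 0.3, sigma_resid 0.5
  cfg <- sim_config(seed = 34, n_genes = c(submodel3 = 400))
  des <- simulate_design(cfg)
  sim <- simulate_expression(cfg, des)
  up <- sim$truth$direction == "up_d110"
  res <- dge_test(sim$values, des)
  fc <- ifelse(up, 1, -1) * res$log2fc_age_overall
  mc_se <- sd(fc) / sqrt(length(fc))
  expect_lt(abs(mean(fc) - 1), 3 * mc_se + 1e-9)
  # ML variance components: residual nearly unbiased, sow variance within
  # a modest relative bias at 18 sows
  expect_lt(abs(mean(res$sigma2_resid) - 0.25), 0.15 * 0.25)
  expect_lt(abs(mean(res$sigma2_sow) - 0.09), 0.25 * 0.09)
})

test_that("F-test edge cases behave as defined", {
  set.seed(35)
  des <- simulate_design(sim_config(seed = 35))
  y <- rnorm(nrow(des))
  fit <- fit_mixed(y, des, "full")
  same <- ftest_vs_reduced(fit, "full")
  expect_equal(same$F_stat, 0)
  expect_equal(same$p_raw, 1)

  const <- fit_mixed(rep(2, nrow(des)), des, "full")
  expect_true(const$not_testable)
  expect_true(ftest_vs_reduced(const, "null")$not_testable)

  tiny <- des[1:4, ]
  expect_error(fit_mixed(rnorm(4), tiny, "full"), "fewer observations")
})

test_that("p-value adjustment matches definitions and the step-up reference", {
  expect_equal(adjust_pvalues(rep(0.004, 300), "bonferroni")[1], 1)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.37, "bonferroni"), 0.37)
  expect_equal(adjust_pvalues(0.37, "bh"), 0.37)
  expect_error(adjust_pvalues(c(0.1, 1.2)), "must lie in")

  set.seed(36)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))
    expect_equal(adjust_pvalues(p, "bh"), bh_stepup_ref(p))
  }
})

test_that("DEP calling applies strict threshold semantics in input order", {
  res <- tibble::tibble(
    probe_id = c("a", "b", "c"),
    p_bonferroni = c(0.009, 0.011, 0.0005),
    q_bh = c(0.2, 0.001, 0.5)
  )
  expect_identical(call_deps(res, 0.01, "bonferroni"), c("a", "c"))
  expect_identical(call_deps(res, 0.01, "bh"), "b")
  expect_identical(call_deps(res[0, ], 0.01), character(0))
})

test_that("fold changes follow cell-mean construction and linearity", {
  des <- one_fetus_per_sow_design(reps = 2)
  y <- ifelse(des$age == "d110", 9, 8)
  fit <- fit_mixed(y, des, "full")
  fc <- log2_fold_changes(fit)
  expect_equal(fc$log2fc_age_overall, 1, tolerance = 1e-8)
  for (g in c("LW", "MS", "LWMS", "MSLW")) {
    expect_equal(fc[[paste0("log2fc_age_", g)]], 1, tolerance = 1e-8)
  }

  set.seed(37)
  des2 <- simulate_design(sim_config(seed = 37))
  y2 <- 8 + rnorm(nrow(des2))
  f1 <- log2_fold_changes(fit_mixed(y2, des2, "full"))
  f2 <- log2_fold_changes(fit_mixed(-y2, des2, "full"))
  expect_equal(as.numeric(f2[1, ]), -as.numeric(f1[1, ]), tolerance = 1e-8)
})

test_that("interaction-only effects average to half across two breeds", {
  # purebred-only design: effect +1 in MS, 0 in LW -> overall 0.5
  cells <- expand.grid(age = c("d90", "d110"), fetal_genotype = c("LW", "MS"),
                       rep = 1:4, stringsAsFactors = FALSE)
  des <- complete_design(tibble::tibble(
    sample_id = paste0("s", seq_len(nrow(cells))),
    sow_id = paste0("w", seq_len(nrow(cells))),
    age = cells$age, fetal_genotype = cells$fetal_genotype
  ))
  set.seed(38)
  reps <- replicate(100, {
    y <- 8 + (des$age == "d110") * (des$fetal_genotype == "MS") +
      rnorm(nrow(des), 0, 0.3)
    fc <- log2_fold_changes(fit_mixed(y, des, "full"))
    c(fc$log2fc_age_LW, fc$log2fc_age_MS, fc$log2fc_age_overall)
  })
  means <- rowMeans(reps)
  expect_equal(means[1], 0, tolerance = 0.05)
  expect_equal(means[2], 1, tolerance = 0.05)
  expect_equal(means[3], 0.5, tolerance = 0.05)
  # genotypes absent from the design are flagged missing
  fc <- log2_fold_changes(fit_mixed(rnorm(nrow(des)) + 8, des, "full"))
  expect_true(is.na(fc$log2fc_age_LWMS) && is.na(fc$log2fc_age_MSLW))
  expect_false(is.na(fc$log2fc_age_overall))
})

test_that("zero-variance probes are flagged not testable in batch tests", {
  cfg <- sim_config(seed = 39, n_genes = c(null = 5))
  des <- simulate_design(cfg)
  sim <- simulate_expression(cfg, des)
  vals <- rbind(sim$values, flat = rep(1, ncol(sim$values)))
  expect_message(res <- dge_test(vals, des), "not_testable")
  expect_identical(res$status[res$probe_id == "flat"], "not_testable")
  expect_true(is.na(res$p_raw[res$probe_id == "flat"]))
  expect_true(all(res$status[res$probe_id != "flat"] == "ok"))
})
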