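test_that("efficiency estimation is exact on a noiseless two-fold series", {
  dil <- tibble::tibble(
    concentration = c(1, 1 / 2, 1 / 4, 1 / 8),
    Ct = 20 + c(0, 1, 2, 3)
  )
  est <- estimate_efficiency(dil)
  expect_equal(est$E, 2, tolerance = 1e-12)
  expect_equal(est$slope, -1 / log10(2), tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
})

test_that("efficiency estimation validates its inputs", {
  expect_error(estimate_efficiency(
    tibble::tibble(concentration = c(1, 0.5), Ct = c(20, 21))
  ), "3 distinct")
  expect_error(estimate_efficiency(
    tibble::tibble(concentration = c(1, 0.5, 0.25, -1), Ct = c(20, 21, 22, 23))
  ), "positive")
  expect_error(estimate_efficiency(
    tibble::tibble(concentration = c(1, 0.5, 0.25), Ct = c(20, 19, 18))
  ), "non-amplifying")
})

test_that("noisy dilution series recover the true efficiency", {
  set.seed(81)
  e_true <- 1.9
  conc <- c(1, 1 / 2, 1 / 4, 1 / 8)
  ests <- replicate(300, {
    ct <- 25 - log(conc) / log(e_true) + rnorm(4, 0, 0.15)
    estimate_efficiency(tibble::tibble(concentration = conc, Ct = ct))$E
  })
  expect_lt(abs(mean(ests) - e_true), 0.05)
})

test_that("Pfaffl ratios follow the formula and the delta-delta-Ct oracle", {
  expect_equal(pfaffl_ratio(20, 20, 18, 18, 2, 2), 1)
  expect_equal(pfaffl_ratio(21, 20, 18, 18, 2, 2), 2)
  expect_error(pfaffl_ratio(20, 20, 18, 18, 0.9, 2), "exceed 1")

  set.seed(82)
  for (i in 1:100) {
    cts <- runif(4, 15, 30)
    expect_equal(
      pfaffl_ratio(cts[1], cts[2], cts[3], cts[4], 2, 2),
      ddct_oracle(cts[1], cts[2], cts[3], cts[4]),
      tolerance = 1e-12
    )
  }
})

test_that("Pfaffl quantification is invariant to constant Ct shifts", {
  set.seed(83)
  samples <- paste0("s", 1:6)
  ct <- dplyr::bind_rows(
    tibble::tibble(gene = "tgt", sample_id = samples, replicate = 1L,
                   Ct = runif(6, 20, 24)),
    tibble::tibble(gene = "ref", sample_id = samples, replicate = 1L,
                   Ct = runif(6, 18, 19))
  )
  eff <- tibble::tibble(gene = c("tgt", "ref"), E = c(1.93, 1.87))
  q1 <- pfaffl_quantify(ct, eff, "ref")
  shifted <- ct
  shifted$Ct[shifted$gene == "tgt"] <- shifted$Ct[shifted$gene == "tgt"] + 5
  q2 <- pfaffl_quantify(shifted, eff, "ref")
  expect_equal(q2$ratio, q1$ratio, tolerance = 1e-10)
})

test_that("technical replicates are averaged on the Ct scale", {
  ct <- tibble::tibble(
    gene = rep(c("tgt", "ref"), each = 4),
    sample_id = rep(c("s1", "s2"), times = 4),
    replicate = rep(c(1L, 2L), each = 2, times = 2),
    Ct = c(20, 22, 24, 18, 15, 15, 15, 15)
  )
  eff <- tibble::tibble(gene = c("tgt", "ref"), E = c(2, 2))
  q <- pfaffl_quantify(ct, eff, "ref")
  # target means: s1 = 22, s2 = 20; calibrator = 21; ref flat
  expect_equal(q$ratio[q$sample_id == "s1"], 2^-1)
  expect_equal(q$ratio[q$sample_id == "s2"], 2^1)
  expect_error(pfaffl_quantify(ct, eff, "missing"), "absent")
})

test_that("microarray validation recovers exact and degenerate correlations", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(validate_against_microarray(x, x)$r, 1)
  expect_equal(validate_against_microarray(x, -x)$r, -1)
  expect_error(validate_against_microarray(x[1:2], x[1:2]), "at least 3")

  set.seed(84)
  a <- rnorm(40)
  b <- a + rnorm(40, 0, 0.2)
  v <- validate_against_microarray(a, b)
  expect_gt(v$r, 0.9)
  expect_lt(v$p, 1e-6)
  expect_equal(v$n, 40)
})
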