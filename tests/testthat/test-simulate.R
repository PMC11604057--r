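test_that("config validation catches out-of-range parameters", {
  expect_error(sim_config(doublet_rate = 0.6), "doublet_rate")
  expect_error(sim_config(n_samples = 1), "n_samples")
  expect_error(sim_config(sample_proportions = c(0.5, 0.4)), "summing to 1")
  expect_error(sim_config(signal_scale = 0), "signal_scale")
  expect_error(sim_config(dropout_prob = 1.2), "dropout_prob")
  expect_error(sim_config(seed = 2^31), "seed")
})

test_that("fixed seed gives bit-identical datasets", {
  cfg <- sim_config(n_cells = 200, n_snps = 80, seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(a$snp$calls), as.matrix(b$snp$calls))
  expect_identical(a$hto, b$hto)
  expect_identical(a$truth, b$truth)
  expect_identical(a$genotypes, b$genotypes)
})

test_that("genotypes follow the Bernoulli alt-allele model", {
  expect_true(all(simulate_genotypes(sim_config(alt_allele_prob = 0,
                                                seed = 1)) == 0))
  expect_true(all(simulate_genotypes(sim_config(alt_allele_prob = 1,
                                                seed = 1)) == 1))
  g <- simulate_genotypes(sim_config(n_samples = 6, n_snps = 500,
                                     alt_allele_prob = 0.3, seed = 3))
  n <- length(g)
  expect_lt(abs(mean(g) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("doublet allocation is exact and multisample fraction is analytic", {
  cfg <- sim_config(n_cells = 10000, doublet_rate = 0.2, seed = 13)
  truth <- simulate_cell_composition(cfg)
  pairs <- !is.na(truth$sample_2)
  expect_identical(sum(pairs), as.integer(round(10000 * 0.2)))
  # multisample fraction of pairs ~ 1 - sum(p_k^2) = 5/6 for equal K = 6
  frac <- mean(truth$sample_1[pairs] != truth$sample_2[pairs])
  p_multi <- 5 / 6
  expect_lt(abs(frac - p_multi),
            3 * sqrt(p_multi * (1 - p_multi) / sum(pairs)))
  # no doublets at rate 0
  t0 <- simulate_cell_composition(sim_config(doublet_rate = 0, seed = 13))
  expect_true(all(is.na(t0$sample_2)))
  expect_true(all(t0$true_label == t0$sample_1))
})

test_that("rare samples appear at their configured proportion", {
  cfg <- sim_config(sample_proportions = c(0.98, 0.02), n_samples = 2,
                    n_cells = 10000, doublet_rate = 0, seed = 17)
  truth <- simulate_cell_composition(cfg)
  frac <- mean(truth$sample_1 == "Sample2")
  expect_lt(abs(frac - 0.02), 3 * sqrt(0.02 * 0.98 / 10000))
})

test_that("SNP calls reflect genotype, dropout, error and the merge rule", {
  cfg1 <- sim_config(n_cells = 50, n_snps = 40, dropout_prob = 1, seed = 19)
  sim1 <- simulate_dataset(cfg1)
  expect_identical(length(sim1$snp$calls@x), 0L)  # all missing

  cfg2 <- sim_config(n_cells = 60, n_snps = 40, dropout_prob = 0,
                     call_error_prob = 0, doublet_rate = 0, seed = 19)
  sim2 <- simulate_dataset(cfg2)
  calls <- as.matrix(sim2$snp$calls)
  for (i in seq_len(10)) {
    g <- sim2$genotypes[sim2$truth$sample_1[i], ]
    expect_equal(unname(calls[i, ]), unname(g + 1))  # REF/ALT codes
  }

  cfg3 <- sim_config(n_cells = 100, n_snps = 40, dropout_prob = 0,
                     call_error_prob = 0, doublet_rate = 0.5, seed = 23)
  sim3 <- simulate_dataset(cfg3)
  calls3 <- as.matrix(sim3$snp$calls)
  dbl <- which(!is.na(sim3$truth$sample_2))
  for (i in dbl[1:10]) {
    g1 <- sim3$genotypes[sim3$truth$sample_1[i], ] + 1
    g2 <- sim3$genotypes[sim3$truth$sample_2[i], ] + 1
    expect_equal(unname(calls3[i, ]), unname(merge_calls(g1, g2)))
  }
})

test_that("hashing counts carry the signal structure of the composition", {
  cfg <- sim_config(n_cells = 2000, seed = 29)
  sim <- simulate_dataset(cfg)
  sn <- colnames(sim$hto)
  multi <- which(sim$truth$true_label == "DOUBLET")
  # multisample doublets are elevated in both parental hashtags
  for (i in multi[1:20]) {
    own <- match(c(sim$truth$sample_1[i], sim$truth$sample_2[i]), sn)
    expect_true(all(sim$hto[i, own] > 10 * cfg$background_mean))
  }
  # with the signal scaled into the background, a cell's own hashtag mean
  # is indistinguishable from background counts
  cfg0 <- sim_config(n_cells = 1000, signal_scale = 1e-9, doublet_rate = 0,
                     seed = 31)
  sim0 <- simulate_dataset(cfg0)
  own_idx <- cbind(seq_len(1000), match(sim0$truth$sample_1, sn))
  own <- sim0$hto[own_idx]
  keep <- matrix(TRUE, nrow(sim0$hto), ncol(sim0$hto))
  keep[own_idx] <- FALSE
  other <- sim0$hto[keep]
  expect_gt(t.test(own, other)$p.value, 0.01)
})

test_that("easy hashing data yields near-perfect singlet calls end to end", {
  sim <- simulate_dataset(sim_config(n_cells = 1500, seed = 37))
  calls <- call_hashing(sim$hto)
  singles <- sim$truth$true_label != "DOUBLET" & is.na(sim$truth$sample_2)
  called_singlet <- !(calls$label %in% c("DOUBLET", "NEGATIVE", "UNCERTAIN"))
  agree <- calls$label[singles & called_singlet] ==
    sim$truth$true_label[singles & called_singlet]
  expect_gte(mean(agree), 0.99)
})
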