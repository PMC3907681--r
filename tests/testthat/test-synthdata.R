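test_that("parents are drawn in Hardy-Weinberg proportions", {
  ps <- sim_params(n_families = 5000, n_snps = 40, maf_range = c(0.3, 0.3),
                   seed = 11)
  pan <- simulate_genotypes(ps)
  parents <- pan$X[pan$role != "child", , drop = FALSE]
  n_draws <- length(parents)                    # 10^4 parents x 40 SNPs
  se <- sqrt(2 * 0.3 * 0.7 / n_draws)
  expect_lt(abs(mean(parents) - 0.6), 3 * se)
  # genotype-frequency check at one SNP: P(het) = 2p(1-p)
  expect_lt(abs(mean(parents == 1L) - 2 * 0.3 * 0.7),
            3 * sqrt(0.42 * 0.58 / n_draws))
})

test_that("child dosage correlates with midparent dosage at 1/sqrt(2)", {
  ps <- sim_params(n_families = 2000, n_snps = 1, maf_range = c(0.5, 0.5),
                   seed = 12)
  pan <- simulate_genotypes(ps)
  ch <- pan$X[pan$role == "child", 1]
  mid <- (pan$X[pan$role == "mother", 1] + pan$X[pan$role == "father", 1]) / 2
  expect_lt(abs(cor(ch, mid) - 1 / sqrt(2)), 0.03)
})

test_that("zero divergence leaves subpopulation allele frequencies equal", {
  ps <- sim_params(n_families = 1000, n_snps = 200, n_subpop = 2, fst = 0,
                   seed = 13)
  pan <- simulate_genotypes(ps)
  expect_equal(pan$snps$freq1, pan$snps$freq2)
  p1 <- colMeans(pan$X[pan$subpop == 1 & pan$role != "child", ]) / 2
  p2 <- colMeans(pan$X[pan$subpop == 2 & pan$role != "child", ]) / 2
  expect_lt(mean(abs(p1 - p2)), 0.04)           # only binomial noise left
})

test_that("generation is Mendelian-consistent and seed-deterministic", {
  ps <- sim_params(n_families = 150, n_snps = 120, seed = 14)
  pan1 <- simulate_genotypes(ps)
  pan2 <- simulate_genotypes(ps)
  expect_identical(pan1$X, pan2$X)
  expect_true(check_mendelian(pan1))
  expect_true(all(pan1$X %in% 0:2))
  expect_identical(anyDuplicated(pan1$ids), 0L)
  ph1 <- simulate_phenotypes(pan1, ps)
  ph2 <- simulate_phenotypes(pan2, ps)
  expect_identical(ph1$ses, ph2$ses)
  expect_identical(ph1$iq, ph2$iq)
  # no child can carry 2 copies when a parent carries 0 (direct audit)
  mo <- pan1$X[pan1$role == "mother", ]
  fa <- pan1$X[pan1$role == "father", ]
  ch <- pan1$X[pan1$role == "child", ]
  expect_false(any(ch == 2 & (mo == 0 | fa == 0)))
  expect_false(any(ch == 0 & (mo == 2 | fa == 2)))
})

test_that("phenotype scaling delivers the target genetic fractions", {
  # zero heritability: no genetic variance, phenotype pure noise of var 1
  ps0 <- sim_params(n_families = 500, n_snps = 300, h2_ses = 0,
                    n_causal_ses = 100, n_causal_iq = 100, seed = 15)
  pan0 <- simulate_genotypes(ps0)
  ph0 <- simulate_phenotypes(pan0, ps0)
  expect_equal(var(ph0$g_ses), 0)
  expect_equal(var(ph0$ses), 1, tolerance = 1e-10)

  # h2 = 0.5 at 5000 families: stored genetic values have variance ~0.5
  ps <- sim_params(n_families = 5000, n_snps = 500, h2_ses = 0.5,
                   h2_iq = 0.5, n_causal_ses = 200, n_causal_iq = 200,
                   rho_eff = 1, seed = 16)
  pan <- simulate_genotypes(ps)
  ph <- simulate_phenotypes(pan, ps)
  expect_lt(abs(var(ph$g_ses) - 0.5), 0.03)
  expect_lt(abs(var(ph$g_iq) - 0.5), 0.03)
  # identical causal sets with rho_eff = 1: genetic values perfectly
  # correlated
  expect_equal(cor(ph$g_ses, ph$g_iq), 1, tolerance = 1e-10)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_params(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_params(h2_ses = 1.2), "herit")
  expect_error(sim_params(rho_eff = -1.5), "rho_eff")
  expect_error(sim_params(n_families = 0), "positive")
  ps <- sim_params(n_families = 50, n_snps = 60, seed = 1,
                   n_causal_ses = 10, n_causal_iq = 10)
  pan <- simulate_genotypes(ps)
  ps2 <- sim_params(n_families = 50, n_snps = 61, seed = 1,
                    n_causal_ses = 10, n_causal_iq = 10)
  expect_error(simulate_phenotypes(pan, ps2), "SNP count")
})
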