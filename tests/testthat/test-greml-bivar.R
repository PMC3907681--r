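test_that("alignment handles subset, disjoint and undersized overlaps", {
  set.seed(91)
  g <- compute_grm(make_panel(random_dosages(120, 200)))
  ids <- g$ids
  y1 <- setNames(rnorm(100), ids[1:100])
  y2 <- setNames(rnorm(60), ids[41:100])        # subset of pheno1 ids
  d <- align_bivariate(y1, y2, g)
  expect_identical(d$n_overlap, 60L)
  expect_identical(length(d$y), 160L)
  # overlap individuals come first in both blocks
  expect_identical(d$ids1[1:60], d$ids2[1:60])
  # disjoint samples: alignment succeeds, residual covariance fixed at 0
  y3 <- setNames(rnorm(20), ids[101:120])
  d0 <- align_bivariate(y1, y3, g)
  expect_true(d0$ce_fixed)
  # undersized overlap is refused
  y4 <- setNames(rnorm(25), ids[96:120])
  expect_error(align_bivariate(y1, y4, g, min_overlap = 30), "min_overlap")
  expect_error(align_bivariate(setNames(rnorm(2), c("x1", "x2")), y1, g),
               "absent")
})

test_that("the stacked design reproduces the published sample geometry", {
  # trait1 on 2679 ids, trait2 on 1897 ids, 1750 doubly phenotyped:
  # stacked response of length 4576
  n_all <- 2679 + 1897 - 1750
  ids <- sprintf("T%04d", seq_len(n_all))
  g <- make_grm(diag(n_all), ids)
  y1 <- setNames(rnorm(2679), ids[1:2679])
  y2 <- setNames(rnorm(1897), ids[c(1:1750, 2680:2826)])
  d <- align_bivariate(y1, y2, g)
  expect_identical(length(d$y), 2679L + 1897L)
  expect_identical(d$n_overlap, 1750L)
})

test_that("disjoint causal sets give a genetic covariance consistent with 0",
{
  ps <- sim_params(n_families = 500, n_snps = 1000, h2_ses = 0.4,
                   h2_iq = 0.4, rho_eff = 0, n_causal_ses = 200,
                   n_causal_iq = 200, seed = 92)
  pan <- simulate_genotypes(ps)
  ph <- simulate_phenotypes(pan, ps)
  g <- compute_grm(children_panel(pan))
  d <- align_bivariate(setNames(ph$ses, ph$iid), setNames(ph$iq, ph$iid), g)
  fit <- fit_bivariate(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$components[["cg"]]), 3 * fit$se[["cg"]])
})

test_that("a duplicated trait collapses to the univariate decomposition", {
  co <- small_cohort(n_fam = 300, m = 600, h2_ses = 0.5, seed = 93)
  uf <- fit_univariate(co$ses, co$grm)
  bf <- fit_bivariate(align_bivariate(co$ses, co$ses, co$grm),
                      max_iter = 200)
  expect_lt(abs(bf$components[["vg1"]] - uf$vg), 1e-4)
  expect_lt(abs(bf$components[["ve1"]] - uf$ve), 1e-4)
  expect_gt(genetic_correlation(bf)$value, 0.99)
})

test_that("genetic correlation is invariant to phenotype rescaling", {
  co <- small_cohort(n_fam = 400, m = 800, h2_ses = 0.4, h2_iq = 0.4,
                     rho_eff = 0.7, seed = 94)
  f1 <- fit_bivariate(align_bivariate(co$ses, co$iq, co$grm))
  f2 <- fit_bivariate(align_bivariate(co$ses, co$iq * 3, co$grm))
  r1 <- genetic_correlation(f1, constrain = FALSE)
  r2 <- genetic_correlation(f2, constrain = FALSE)
  expect_equal(r1$value, r2$value, tolerance = 1e-3)
  # and the genetic covariance itself scales by the constant
  expect_equal(f2$components[["cg"]] / f1$components[["cg"]], 3,
               tolerance = 0.01)
})

test_that("the footnote SE formula equals a numerical delta-method oracle", {
  set.seed(95)
  G <- matrix(rnorm(36), 6)
  Vc <- crossprod(G) / 50
  dimnames(Vc) <- list(c("vg1", "vg2", "cg", "ve1", "ve2", "ce"),
                       c("vg1", "vg2", "cg", "ve1", "ve2", "ce"))
  fit <- bivariate_components(vg1 = 0.21, vg2 = 0.28, cg = 0.29,
                              ve1 = 0.78, ve2 = 0.72, ce = 0.03, vcov = Vc)
  re <- residual_correlation(fit)
  # numerical central-difference gradient of re(ve1, ve2, ce)
  f <- function(p) p[3] / sqrt(p[1] * p[2])
  p0 <- c(0.78, 0.72, 0.03)
  h <- 1e-6
  grad <- vapply(1:3, function(i) {
    e <- rep(0, 3); e[i] <- h
    (f(p0 + e) - f(p0 - e)) / (2 * h)
  }, numeric(1))
  sub <- c("ve1", "ve2", "ce")
  se_num <- sqrt(as.numeric(t(grad) %*% Vc[sub, sub] %*% grad))
  expect_lt(abs(re$se - se_num), 1e-8)
  expect_equal(re$value, 0.03 / sqrt(0.78 * 0.72), tolerance = 1e-12)
  # Ce = 0: the footnote formula is singular; general delta method instead
  fit0 <- bivariate_components(0.2, 0.2, 0.1, 0.7, 0.7, 0, vcov = Vc)
  re0 <- residual_correlation(fit0)
  expect_identical(re0$value, 0)
  expect_equal(re0$se, sqrt(Vc["ce", "ce"] / (0.7 * 0.7)), tolerance = 1e-12)
  expect_match(re0$note, "delta")
})

test_that("derived-correlation edge cases behave", {
  fit <- bivariate_components(0.25, 0.3, 0, 0.75, 0.7, 0.1)
  expect_identical(genetic_correlation(fit)$value, 0)
  bad <- bivariate_components(0, 0.3, 0.1, 0.75, 0.7, 0.1)
  expect_error(genetic_correlation(bad), "positive")
  # mediation: zero genetic covariance -> 0%
  expect_equal(as.numeric(mediation_proportion(fit, 0.3)), 0)
  # non-unit phenotypic variances are rescaled onto the correlation scale
  f2 <- bivariate_components(0.6, 0.6, 0.4, 0.9, 0.9, 0.1)  # Vp = 1.5
  m <- mediation_proportion(f2, 0.5)
  expect_equal(as.numeric(m), 100 * (0.4 / 1.5) / 0.5, tolerance = 1e-10)
  expect_warning(mediation_proportion(fit2 <- bivariate_components(
    0.4, 0.4, 0.39, 0.6, 0.6, 0.1), 0.3), "outside")
  expect_error(mediation_proportion(fit, 0), "non-zero")
})

test_that("phenotypic correlation uses the overlap sample only", {
  set.seed(96)
  y1 <- setNames(rnorm(5000), sprintf("P%04d", 1:5000))
  expect_equal(phenotypic_correlation(y1, y1)$value, 1)
  y2 <- setNames(rnorm(5000), sprintf("P%04d", 1:5000))
  expect_lt(abs(phenotypic_correlation(y1, y2)$value), 0.03)
  expect_error(phenotypic_correlation(y1[1:2], y1[1:2]), "3 overlapping")
  # generator consistency: h2 = 0.3 on both traits with rho_eff = 1 implies
  # a phenotypic correlation near 0.3
  ps <- sim_params(n_families = 5000, n_snps = 500, h2_ses = 0.3,
                   h2_iq = 0.3, rho_eff = 1, n_causal_ses = 200,
                   n_causal_iq = 200, seed = 97)
  pan <- simulate_genotypes(ps)
  ph <- simulate_phenotypes(pan, ps)
  rp <- phenotypic_correlation(setNames(ph$ses, ph$iid),
                               setNames(ph$iq, ph$iid))
  expect_lt(abs(rp$value - 0.3), 0.04)
})

test_that("correlation-scale contributions add up to the phenotypic
          correlation", {
  co <- small_cohort(n_fam = 700, m = 1200, h2_ses = 0.4, h2_iq = 0.4,
                     rho_eff = 0.6, n_causal = 400, seed = 98)
  fit <- fit_bivariate(align_bivariate(co$ses, co$iq, co$grm))
  rp <- phenotypic_correlation(co$ses, co$iq)
  model_rp <- (fit$components[["cg"]] + fit$components[["ce"]]) /
    sqrt(fit$vp1 * fit$vp2)
  expect_lt(abs(model_rp - rp$value), 0.05)
})
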