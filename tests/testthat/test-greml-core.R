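test_that("reml_loglik agrees between dense and eigen-rotated evaluation", {
  set.seed(71)
  n <- 6
  G <- matrix(rnorm(n * 12), n)
  A <- tcrossprod(G) / 12
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  e <- eigen(A, symmetric = TRUE)
  for (vg in c(0.2, 1)) {
    for (ve in c(0.5, 2)) {
      dense <- reml_loglik(y, X, A, vg, ve)
      rot <- reml_loglik(as.vector(crossprod(e$vectors, y)),
                         crossprod(e$vectors, X), diag(e$values), vg, ve)
      expect_equal(dense, rot, tolerance = 1e-10)
    }
  }
  # vg = 0 reduces to the iid null likelihood at the fitted residual variance
  nf <- fit_null(setNames(y, paste0("i", 1:n)))
  expect_equal(reml_loglik(y, matrix(1, n, 1), A, 0, nf$ve), nf$logL,
               tolerance = 1e-8)
  expect_error(reml_loglik(y, X, A, 0.5, 0), "ve > 0")
})

test_that("the optimizer beats random points in the likelihood landscape", {
  co <- small_cohort(n_fam = 150, m = 400, h2_ses = 0.4, seed = 72)
  fit <- fit_univariate(co$ses, co$grm)
  ids <- fit$ids
  A <- co$grm$A[ids, ids]
  yv <- as.numeric(co$ses[ids])
  X <- matrix(1, fit$n, 1)
  set.seed(73)
  lls <- replicate(100, reml_loglik(yv, X, A, runif(1, 0, 2),
                                    runif(1, 0.05, 2)))
  expect_true(all(fit$logL >= lls))
  # dense evaluation at the optimum reproduces the fit's log-likelihood
  expect_equal(reml_loglik(yv, X, A, fit$vg, fit$ve), fit$logL,
               tolerance = 1e-8)
})

test_that("a null trait yields a heritability estimate consistent with zero",
{
  co <- small_cohort(n_fam = 500, m = 1000, seed = 74)
  set.seed(75)
  y0 <- setNames(rnorm(500), co$grm$ids)
  fit <- fit_univariate(y0, co$grm)
  expect_true(fit$converged)
  expect_lt(fit$h2, 2 * fit$se[["h2"]] + 1e-6)
})

test_that("simulated heritability is recovered within sampling error", {
  co <- small_cohort(n_fam = 500, m = 1000, h2_ses = 0.5, seed = 76)
  fit <- fit_univariate(co$ses, co$grm)
  expect_true(fit$converged)
  # 3-SE band: a single-draw check at 2 SE would fail 1 in 20 healthy runs
  expect_lt(abs(fit$h2 - 0.5), 3 * fit$se[["h2"]])
  expect_equal(fit$vp, fit$vg + fit$ve, tolerance = 1e-10)
  # accepted AI iterations never decrease the log-likelihood
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
})

test_that("estimates are invariant to a permutation of individuals", {
  co <- small_cohort(n_fam = 200, m = 500, h2_ses = 0.5, seed = 77)
  kids <- children_panel(co$panel)
  set.seed(78)
  perm <- sample(length(kids$ids))
  grm_p <- compute_grm(subset_panel(kids, perm))
  f1 <- fit_univariate(co$ses, co$grm)
  f2 <- fit_univariate(co$ses, grm_p)
  expect_equal(f1$vg, f2$vg, tolerance = 1e-6)
  expect_equal(f1$ve, f2$ve, tolerance = 1e-6)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-6)
})

test_that("an identity GRM is flagged as unidentifiable, not fitted", {
  set.seed(79)
  n <- 100
  g <- make_grm(diag(n))
  y <- setNames(rnorm(n), g$ids)
  fit <- fit_univariate(y, g)
  expect_false(fit$identifiable)
  expect_false(fit$converged)
})

test_that("the null fit matches closed forms and the boundary test behaves",
{
  set.seed(80)
  y <- setNames(rnorm(400, 5, 2), paste0("i", 1:400))
  nf <- fit_null(y)
  expect_equal(nf$ve, var(y), tolerance = 1e-12)
  # LRT of equal likelihoods sits at the boundary mass
  l0 <- lrt(-100, -100)
  expect_identical(l0$lrt, 0)
  expect_equal(l0$p, 0.5)
  # mismatched samples are refused
  co <- small_cohort(n_fam = 60, m = 100, n_causal = 50, seed = 81)
  fit <- fit_univariate(co$ses, co$grm)
  nf2 <- fit_null(co$ses[1:50])
  expect_error(lrt(fit, nf2), "different samples")
  # unknown phenotype ids are refused
  bad <- setNames(rnorm(3), c("nope1", "nope2", "nope3"))
  expect_error(fit_univariate(bad, co$grm), "absent from the GRM")
})

test_that("hsq reports round-trip the fitted quantities", {
  co <- small_cohort(n_fam = 120, m = 300, seed = 82)
  fit <- fit_univariate(co$ses, co$grm)
  nf <- fit_null(co$ses)
  path <- file.path(tempdir(), "test.hsq")
  write_hsq(fit, nf, path)
  lines <- readLines(path)
  expect_identical(length(lines), 11L)
  vg_line <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.numeric(vg_line[2]), fit$vg, tolerance = 1e-6)
  expect_match(lines[8], "^LRT")
})
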