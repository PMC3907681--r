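test_that("the GRM matches the hand-computed allele-frequency weighting", {
  # 3 individuals x 2 SNPs, sample p = (0.5, 0.5):
  # A_12 = (1/2)[(0-1)(2-1) + (2-1)(0-1)] / 0.5 = -2
  X <- matrix(c(0L, 2L, 1L, 2L, 0L, 1L), 3, 2)
  g <- compute_grm(make_panel(X))
  expect_equal(g$A[1, 2], -2)
  expect_equal(g$A[1, 1], 2)
  expect_equal(g$A[3, 3], 0)
  expect_equal(g$A[1, 3], 0)
  expect_equal(g$A, t(g$A))
})

test_that("a duplicated individual has identical diagonal and pair entries", {
  set.seed(41)
  X <- random_dosages(6, 100, maf = c(0.3, 0.5))
  X[2, ] <- X[1, ]
  X <- X[, apply(X, 2, function(col) length(unique(col)) > 1)]
  g <- compute_grm(make_panel(X))
  expect_equal(g$A[1, 2], g$A[1, 1])
  expect_equal(g$A[1, 2], g$A[2, 2])
})

test_that("off-diagonals of an unrelated panel center near zero", {
  set.seed(42)
  X <- random_dosages(150, 800, maf = c(0.1, 0.5))
  n <- nrow(X)
  g <- compute_grm(make_panel(X))
  off <- g$A[upper.tri(g$A)]
  # sample-frequency centering makes each SNP's scores sum to zero exactly,
  # so the mean off-diagonal equals -mean(diagonal)/(n-1): near zero at
  # large n, and an exact brute-force identity at any n
  expect_equal(mean(off), -mean(diag(g$A)) / (n - 1), tolerance = 1e-10)
  expect_lt(abs(mean(off)), 0.01)
})

test_that("missing dosages use pairwise deletion, matching a loop oracle", {
  set.seed(43)
  X <- random_dosages(12, 40, maf = c(0.2, 0.5))
  X[sample(length(X), 30)] <- NA
  g <- compute_grm(make_panel(X))
  p <- colMeans(X, na.rm = TRUE) / 2
  oracle <- function(i, j) {
    num <- 0; mij <- 0
    for (k in seq_len(ncol(X))) {
      if (!is.na(X[i, k]) && !is.na(X[j, k])) {
        num <- num + (X[i, k] - 2 * p[k]) * (X[j, k] - 2 * p[k]) /
          (2 * p[k] * (1 - p[k]))
        mij <- mij + 1
      }
    }
    c(num / mij, mij)
  }
  for (pair in list(c(1, 2), c(3, 9), c(5, 5), c(12, 4))) {
    o <- oracle(pair[1], pair[2])
    expect_equal(g$A[pair[1], pair[2]], o[1], tolerance = 1e-12)
    expect_equal(g$n_pairs[pair[1], pair[2]], o[2])
  }
})

test_that("the GRM is invariant to SNP ordering", {
  set.seed(44)
  X <- random_dosages(30, 60)
  perm <- sample(ncol(X))
  g1 <- compute_grm(make_panel(X))
  g2 <- compute_grm(make_panel(X[, perm]))
  expect_equal(g1$A, g2$A, tolerance = 1e-12)
})

test_that("monomorphic SNPs reaching the GRM raise an instructive error", {
  X <- random_dosages(10, 5)
  X[, 3] <- 2L
  expect_error(compute_grm(make_panel(X)), "QC")
})

test_that("relatedness pruning removes the minimum necessary individuals", {
  set.seed(45)
  base <- matrix(rnorm(20 * 20, sd = 0.004), 20, 20)
  A <- (base + t(base)) / 2
  diag(A) <- 1
  # below-threshold panel: everyone retained
  g0 <- make_grm(A)
  expect_identical(length(prune_related(g0, 0.025)), 20L)
  # planted duplicate pair: exactly one of the two removed (the later)
  A1 <- A; A1[3, 7] <- A1[7, 3] <- 0.98
  kept <- prune_related(make_grm(A1), 0.025)
  expect_identical(setdiff(make_grm(A1)$ids, kept), "I007")
  # planted clique of 4: exactly 3 removed (minimal vertex cover of K4)
  A2 <- A
  cl <- c(2, 8, 11, 17)
  for (i in cl) for (j in cl) if (i != j) A2[i, j] <- 0.5
  g2 <- make_grm(A2)
  kept2 <- prune_related(g2, 0.025)
  expect_identical(length(setdiff(g2$ids, kept2)), 3L)
  # invariant: no violating pair among survivors
  sub <- g2$A[kept2, kept2]
  expect_true(max(sub[upper.tri(sub)]) < 0.025)
  expect_error(prune_related(g0, 0), "positive")
})

test_that("GCTA GRM triplets round-trip within 4-byte precision", {
  set.seed(46)
  g3 <- compute_grm(make_panel(random_dosages(3, 50)))
  prefix <- file.path(tempdir(), "g3")
  write_grm_gcta(g3, prefix)
  expect_identical(file.size(paste0(prefix, ".grm.bin")), 6 * 4)
  g50 <- compute_grm(make_panel(random_dosages(50, 200)))
  prefix50 <- file.path(tempdir(), "g50")
  write_grm_gcta(g50, prefix50)
  back <- read_grm_gcta(prefix50)
  expect_lt(max(abs(back$A - g50$A)), 1e-6)
  expect_identical(back$ids, g50$ids)
  # inconsistent triplet: 7 stored values cannot match 3 ids
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(numeric(7), con, size = 4); close(con)
  expect_error(read_grm_gcta(prefix), "n\\(n\\+1\\)/2")
})
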