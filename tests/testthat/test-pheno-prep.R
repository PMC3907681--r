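test_that("the first-PC composite captures a planted common factor", {
  set.seed(61)
  # rank-1 case: two perfectly correlated indicators
  f <- rnorm(200)
  two <- cbind(a = f, b = 2 * f + 5)
  c2 <- ses_composite(two)
  expect_equal(attr(c2, "variance_explained"), 1)
  expect_gt(cor(c2, f), 0.999)

  # five indicators loading 0.8 on one factor: PC1 explains > 50%
  n <- 2000
  g <- rnorm(n)
  ind <- sapply(1:5, function(j) 0.8 * g + sqrt(1 - 0.64) * rnorm(n))
  c5 <- ses_composite(ind)
  expect_gt(attr(c5, "variance_explained"), 0.5)
  # brute-force oracle: top eigenvalue share of the correlation matrix
  ev <- eigen(cor(ind), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(attr(c5, "variance_explained"), ev[1] / 5, tolerance = 1e-10)
  # sign convention: positive correlation with the first indicator
  expect_gt(cor(c5, ind[, 1]), 0)

  # independent noise: each axis explains about 1/5
  noise <- matrix(rnorm(n * 5), n, 5)
  expect_lt(abs(attr(ses_composite(noise), "variance_explained") - 0.2),
            0.05)
  expect_error(ses_composite(cbind(rep(1, 10), rnorm(10))), "constant")
})

test_that("outlier flagging matches the normal tail expectation", {
  set.seed(62)
  x <- rnorm(1e4)
  flagged <- sum(exclude_outliers(x, 3))
  expected <- 1e4 * 2 * pnorm(-3)               # ~27
  expect_lt(abs(flagged - expected), 3 * sqrt(expected) + 3)
  y <- c(rep(0, 20), 10)
  expect_identical(which(exclude_outliers(y, 3)), 21L)
  expect_identical(sum(exclude_outliers(x, Inf)), 0L)
  expect_error(exclude_outliers(rep(1, 10)), "zero-variance")
  expect_error(exclude_outliers(c(1, NA, NA)), "non-missing")
})

test_that("age/sex adjustment plus rank-normalization is order-preserving", {
  set.seed(63)
  n <- 1000
  age <- rnorm(n, 7, 0.3)
  sex <- rbinom(n, 1, 0.5)
  x <- rnorm(n)
  out <- adjust_and_normalize(x, age, sex)
  expect_gt(cor(out, x), 0.99)
  # hand-computed Blom oracle at n = 5
  x5 <- c(2.3, -1.1, 0.4, 5.0, 0.9)
  age5 <- c(7.1, 8.2, 7.6, 8.0, 7.3)
  sex5 <- c(0, 1, 1, 0, 0)
  out5 <- adjust_and_normalize(x5, age5, sex5)
  # residual ranks map through qnorm((r - 3/8)/(n + 1/4))
  r5 <- lm.fit(cbind(1, age5, sex5), x5)$residuals
  expect_equal(out5, qnorm((rank(r5) - 3 / 8) / 5.25), tolerance = 1e-12)
  # perfect-fit edge: flagged, output is rank noise
  expect_warning(adjust_and_normalize(2 * age, age, sex), "perfectly")
  expect_error(adjust_and_normalize(x, age, rep(1, n)), "collinear")
  expect_error(adjust_and_normalize(c(1, 2, 3), c(7, NA, 8), c(0, 1, 0)),
               "missing covariates")
})

test_that("rank-normalized output is distribution-free", {
  set.seed(64)
  for (gen in list(rexp, function(n) rt(n, 2), function(n) rbinom(n, 20,
                                                                  0.2))) {
    x <- gen(800)
    out <- adjust_and_normalize(x, rnorm(800), rbinom(800, 1, 0.5))
    D <- suppressWarnings(ks.test(out, "pnorm")$statistic)
    expect_lt(D, 0.01)
  }
})

test_that("the IQ composite requires 3 of 4 tests and averages the rest", {
  M <- rbind(c(1, 2, 3, NA),                    # 3 present -> mean 2
             c(1, 2, NA, NA),                   # 2 present -> missing
             c(1, 1, 1, 1))                     # complete -> 1
  comp <- iq_composite(M, min_present = 3, standardize = FALSE)
  expect_equal(comp, c(2, NA, 1))
  expect_error(iq_composite(M, min_present = 5), "min_present")
  expect_error(iq_composite(M[, 1:3], 3), "4 test columns")
})

test_that("trait preparation applies exclusion before regression", {
  set.seed(65)
  n <- 300
  age <- rnorm(n, 7, 0.3)
  sex <- rbinom(n, 1, 0.5)
  x <- rnorm(n)
  x[17] <- 40                                   # gross outlier
  out <- prepare_trait(x, age, sex, sd_limit = 3)
  expect_true(is.na(out[17]))
  expect_identical(attr(out, "outliers"), 17L)
  expect_identical(sum(is.na(out)), 1L)
})
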