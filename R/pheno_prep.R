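#' First-principal-component SES composite
#'
#' Standardizes the indicator columns and returns the scores of the first
#' unrotated principal component, together with the fraction of total
#' variance it explains.  The sign convention is fixed so the composite
#' correlates positively with the first indicator column.  Rows with any
#' missing indicator get a missing composite.
#'
#' @param indicators data frame or matrix of >= 2 numeric indicator columns
#'   (e.g. parental education, occupation).
#' @return numeric composite scores with attribute \code{"variance_explained"}.
#' @export
ses_composite <- function(indicators) {
  M <- as.matrix(indicators)
  if (ncol(M) < 2) stop("need at least 2 indicator columns", call. = FALSE)
  cc <- complete.cases(M)
  if (sum(cc) < 3) stop("need at least 3 complete rows", call. = FALSE)
  sds <- apply(M[cc, , drop = FALSE], 2, sd)
  if (any(sds == 0)) {
    stop("constant indicator column: ",
         paste(colnames(M)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- prcomp(M[cc, , drop = FALSE], center = TRUE, scale. = TRUE)
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  sc <- pc$x[, 1]
  if (cor(sc, M[cc, 1]) < 0) sc <- -sc
  out <- rep(NA_real_, nrow(M))
  out[cc] <- sc
  attr(out, "variance_explained") <- ve
  out
}

#' Flag outliers beyond a z-score limit
#'
#' The mean and SD are computed once on the input distribution (no
#' iteration); values with |z| above \code{sd_limit} are flagged.  Missing
#' values are never flagged.
#'
#' @param scores numeric vector (>= 3 non-missing values).
#' @param sd_limit threshold in SD units (default 3; \code{Inf} flags none).
#' @return logical mask, TRUE where the value is an outlier.
#' @export
exclude_outliers <- function(scores, sd_limit = 3) {
  ok <- !is.na(scores)
  if (sum(ok) < 3) stop("need at least 3 non-missing values", call. = FALSE)
  s <- sd(scores[ok])
  if (s == 0) stop("zero-variance input", call. = FALSE)
  z <- (scores - mean(scores[ok])) / s
  !is.na(z) & abs(z) > sd_limit
}

#' Age/sex adjustment and rank-based inverse-normal transformation
#'
#' Regresses the scores on an intercept, age and sex by ordinary least
#' squares, standardizes the residuals, and maps them to normal quantiles by
#' rank with the Blom offset \eqn{(r - 3/8)/(n + 1/4)}; ties share their
#' average rank.  A warning is raised when the regression leaves essentially
#' no residual variance (the ranks are then pure noise).
#'
#' @param scores numeric vector (may contain NA).
#' @param age,sex numeric covariates, complete wherever \code{scores} is
#'   non-missing.
#' @return numeric vector of normalized residuals (NA preserved).
#' @export
adjust_and_normalize <- function(scores, age, sex) {
  ok <- !is.na(scores)
  if (any(is.na(age[ok])) || any(is.na(sex[ok]))) {
    stop("missing covariates for non-missing scores", call. = FALSE)
  }
  X <- cbind(1, age[ok], sex[ok])
  if (qr(X)$rank < ncol(X)) stop("collinear covariates", call. = FALSE)
  fit <- lm.fit(X, scores[ok])
  r <- fit$residuals
  if (var(r) < 1e-12 * max(var(scores[ok]), .Machine$double.eps)) {
    warning("age/sex regression fits the scores almost perfectly; ",
            "normalized output is rank noise", call. = FALSE)
  } else {
    r <- r / sd(r)
  }
  n <- length(r)
  q <- qnorm((rank(r, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  out <- rep(NA_real_, length(scores))
  out[ok] <- q
  out
}

#' Unit-weighted IQ composite over four tests
#'
#' Standardizes each test column and averages the available tests per
#' individual, requiring at least \code{min_present} of the four (the
#' composite is missing otherwise).
#'
#' @param test_scores data frame or matrix with exactly 4 test columns
#'   (by convention 2 verbal, 2 non-verbal).
#' @param min_present minimum number of non-missing tests (default 3).
#' @param standardize standardize columns before averaging (default TRUE;
#'   set FALSE when the tests are already on a common scale).
#' @return numeric composite vector.
#' @export
iq_composite <- function(test_scores, min_present = 3, standardize = TRUE) {
  M <- as.matrix(test_scores)
  if (ncol(M) != 4) stop("expected exactly 4 test columns", call. = FALSE)
  if (min_present > 4 || min_present < 1) {
    stop("min_present must be in 1..4", call. = FALSE)
  }
  if (standardize) M <- scale(M)
  k <- rowSums(!is.na(M))
  out <- rowMeans(M, na.rm = TRUE)
  out[k < min_present] <- NA_real_
  out
}

#' Prepare a trait column the standard way
#'
#' Fixed order, logged: outlier exclusion on the raw score, age/sex
#' regression, quantile normalization.  Used per cognitive test before the
#' composite; exposed so the pipeline order is auditable.
#'
#' @param scores,age,sex as in [adjust_and_normalize()].
#' @param sd_limit outlier threshold passed to [exclude_outliers()].
#' @return normalized vector with outliers set NA (flagged in attribute
#'   \code{"outliers"}, never silently dropped).
#' @export
prepare_trait <- function(scores, age, sex, sd_limit = 3) {
  out_mask <- exclude_outliers(scores, sd_limit)
  sc <- scores
  sc[out_mask] <- NA
  res <- adjust_and_normalize(sc, age, sex)
  attr(res, "outliers") <- which(out_mask)
  res
}
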