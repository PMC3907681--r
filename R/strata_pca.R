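#' LD pruning by squared dosage correlation
#'
#' Slides a window across each chromosome; within a window, while any pair of
#' retained SNPs has squared correlation above \code{r2_max}, the later SNP
#' of the worst (highest r-squared) pair is dropped.  Deterministic.
#'
#' @param panel a \code{genotype_panel}.
#' @param r2_max squared-correlation ceiling, in (0, 1] (default 0.2).
#' @param window window size in SNPs (>= 2).
#' @param step window advance in SNPs.
#' @return character vector of retained SNP ids (original order).
#' @export
ld_prune <- function(panel, r2_max = 0.2, window = 50, step = 20) {
  stop_if_not_panel(panel)
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0, 1]",
                                      call. = FALSE)
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  if (step < 1) stop("step must be >= 1", call. = FALSE)
  m <- ncol(panel$X)
  keep <- rep(TRUE, m)
  for (chr in unique(panel$snps$chr)) {
    idx <- which(panel$snps$chr == chr)
    start <- 1
    repeat {
      w <- idx[seq(start, min(start + window - 1, length(idx)))]
      w <- w[keep[w]]
      if (length(w) > 1) {
        R2 <- suppressWarnings(
          cor(panel$X[, w, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        R2[!is.finite(R2)] <- 0
        diag(R2) <- 0
        while (max(R2) > r2_max) {
          worst <- which(R2 == max(R2), arr.ind = TRUE)[1, ]
          drop <- max(worst)                   # the later SNP of the pair
          keep[w[drop]] <- FALSE
          R2[drop, ] <- 0
          R2[, drop] <- 0
        }
      }
      if (start + window - 1 >= length(idx)) break
      start <- start + step
    }
  }
  panel$snps$id[keep]
}

#' Ancestry principal components of standardized dosages
#'
#' Eigen-decomposes the individual-by-individual covariance of
#' column-standardized dosages (mean \eqn{2\hat p}, sd
#' \eqn{\sqrt{2\hat p(1-\hat p)}}, sample frequencies — the same weighting as
#' the GRM).  Axis scores are scaled so each score vector's variance equals
#' its eigenvalue.
#'
#' @param panel a \code{genotype_panel}.
#' @param snp_subset optional character SNP ids (e.g. from [ld_prune()]).
#' @param k number of axes to return scores for (may be 0).
#' @return a \code{pc_result}: \code{values} (all eigenvalues, descending),
#'   \code{scores} (n x k), \code{n}, \code{m}.
#' @export
pca_axes <- function(panel, snp_subset = NULL, k = 10) {
  stop_if_not_panel(panel)
  sub <- if (is.null(snp_subset)) panel else subset_panel(panel,
                                                          snps = snp_subset)
  n <- nrow(sub$X)
  m <- ncol(sub$X)
  if (k < 0 || k >= min(n, m)) stop("need 0 <= k < min(individuals, SNPs)",
                                    call. = FALSE)
  p <- colMeans(sub$X, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1)) stop("constant SNP in PCA subset", call. = FALSE)
  Z <- standardize_dosage(sub$X, p)
  Z <- sweep(Z, 2, colMeans(Z))                 # exact column centering
  K <- tcrossprod(Z) / m
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  scores <- if (k > 0) {
    sweep(e$vectors[, seq_len(k), drop = FALSE], 2,
          sqrt(pmax(vals[seq_len(k)], 0) * (n - 1)), "*")
  } else {
    matrix(0, n, 0)
  }
  rownames(scores) <- sub$ids
  if (k > 0) colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(values = vals, scores = scores, ids = sub$ids,
                 fid = sub$fid, n = n, m = m),
            class = "pc_result")
}

# interpolated right-tail probability of the Tracy-Widom (beta = 1) law,
# from the frozen grid in tw-table.R (log-linear in the survival function)
tw1_pvalue <- function(x) {
  lp <- approx(.tw1_x, log(.tw1_sf), xout = x, rule = 2)$y
  exp(lp)
}

#' Tracy-Widom selection of significant ancestry axes
#'
#' Standardizes each leading eigenvalue by an effective-dimension
#' (Patterson-style) centering and scaling and compares it with the
#' Tracy-Widom (beta = 1) distribution.  Axes are tested sequentially from
#' the top; testing stops at the first non-significant axis.  At each step,
#' with \eqn{p} remaining eigenvalues and \eqn{S_1, S_2} their sum and sum of
#' squares, the effective number of markers is the Wishart moment estimator
#' \eqn{\hat n = R(p+1)/(p-R)} with \eqn{R = S_1^2/S_2} (derived from
#' \eqn{E\,tr W = np}, \eqn{E\,tr W^2 = np(n+p+1)} for a white Wishart
#' \eqn{W_p(n)}); the leading eigenvalue is rescaled to that Wishart scale,
#' \eqn{\lambda^* = \lambda_1 p \hat n / S_1}, and standardized by the
#' Johnstone centering \eqn{\mu = (\sqrt{\hat n - 1}+\sqrt{p})^2} and
#' \eqn{\sigma = (\sqrt{\hat n - 1}+\sqrt{p})
#' (1/\sqrt{\hat n - 1}+1/\sqrt{p})^{1/3}}.  The construction is invariant to
#' the overall eigenvalue scale.
#'
#' @param pcs a \code{pc_result} from [pca_axes()].
#' @param alpha significance level in (0, 1); \code{alpha = 0} selects none.
#' @param max_axes cap on the number of axes tested.
#' @return integer vector of selected axis indices, with the per-axis test
#'   table (statistic and p-value) as attribute \code{"table"}.
#' @export
tracy_widom_select <- function(pcs, alpha = 0.05, max_axes = 20) {
  if (!inherits(pcs, "pc_result")) stop("expected a 'pc_result'",
                                        call. = FALSE)
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)", call. = FALSE)
  lam <- pcs$values
  lam <- lam[lam > max(lam) * 1e-9]             # rank-deficiency cut
  sel <- integer(0)
  stat <- p <- numeric(0)
  i <- 1
  while (i <= min(max_axes, length(lam) - 2)) {
    rem <- lam[i:length(lam)]
    mp <- length(rem)
    S1 <- sum(rem)
    S2 <- sum(rem^2)
    R <- S1^2 / S2
    neff <- R * (mp + 1) / (mp - R)
    if (!is.finite(neff) || neff <= 1) break
    l1 <- rem[1] * mp * neff / S1
    mu <- (sqrt(neff - 1) + sqrt(mp))^2
    sg <- (sqrt(neff - 1) + sqrt(mp)) *
      (1 / sqrt(neff - 1) + 1 / sqrt(mp))^(1 / 3)
    x <- (l1 - mu) / sg
    pv <- tw1_pvalue(x)
    stat <- c(stat, x)
    p <- c(p, pv)
    if (pv >= alpha) break
    sel <- c(sel, i)
    i <- i + 1
  }
  structure(sel,
            table = data.frame(axis = seq_along(stat), statistic = stat,
                               p_value = p))
}

#' Write principal-component scores as a covariate table
#'
#' @param pcs a \code{pc_result}.
#' @param path output file (tab-delimited FID IID PC1..PCk).
#' @param axes which axes to write (default: all computed scores).
#' @return the path, invisibly.
#' @export
write_covariates <- function(pcs, path, axes = NULL) {
  sc <- pcs$scores
  if (!is.null(axes)) sc <- sc[, axes, drop = FALSE]
  df <- data.frame(FID = pcs$fid, IID = pcs$ids, sc, check.names = FALSE)
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
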