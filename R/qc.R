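#' Genotype quality control
#'
#' Applies the standard pre-GRM filters: SNPs are dropped when their
#' minor-allele frequency falls below \code{maf_min} or their missingness
#' exceeds \code{snp_missing_max}; individuals are dropped when their
#' heterozygosity rate (fraction of heterozygous calls over retained SNPs)
#' deviates more than \code{het_sd} standard deviations from the sample mean.
#' Row and column order of the survivors is preserved.
#'
#' @param panel a \code{genotype_panel}.
#' @param maf_min minor-allele-frequency floor (default 0.01).
#' @param snp_missing_max per-SNP missingness ceiling (default 0.05).
#' @param het_sd heterozygosity outlier threshold in SDs (default 3;
#'   \code{Inf} disables the filter).
#' @return list with the filtered \code{panel} and a \code{qc_report}
#'   (counts removed per filter, removed ids, thresholds).
#' @export
qc_filter <- function(panel, maf_min = 0.01, snp_missing_max = 0.05,
                      het_sd = 3) {
  stop_if_not_panel(panel)
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must be in [0, 0.5)",
                                          call. = FALSE)
  if (snp_missing_max < 0 || snp_missing_max > 1) {
    stop("snp_missing_max must be in [0, 1]", call. = FALSE)
  }
  X <- panel$X
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0                        # all-missing SNP
  miss <- colMeans(is.na(X))
  keep_snp <- maf >= maf_min & miss <= snp_missing_max
  n_maf <- sum(maf < maf_min)
  n_miss <- sum(miss > snp_missing_max & maf >= maf_min)
  if (!any(keep_snp)) {
    stop("QC removed all SNPs (MAF floor ", maf_min, ", missingness ceiling ",
         snp_missing_max, ")", call. = FALSE)
  }

  het <- rowMeans(X[, keep_snp, drop = FALSE] == 1L, na.rm = TRUE)
  mu <- mean(het)
  sdh <- sd(het)
  keep_ind <- if (!is.finite(het_sd) || sdh == 0) rep(TRUE, nrow(X))
              else abs(het - mu) <= het_sd * sdh
  report <- structure(list(
    n_snps_in = ncol(X), n_ind_in = nrow(X),
    n_snp_maf = n_maf, n_snp_missing = n_miss,
    n_ind_het = sum(!keep_ind),
    removed_snps = panel$snps$id[!keep_snp],
    removed_ids = panel$ids[!keep_ind],
    het_rate = setNames(het, panel$ids),
    thresholds = list(maf_min = maf_min, snp_missing_max = snp_missing_max,
                      het_sd = het_sd),
    n_snps_out = sum(keep_snp), n_ind_out = sum(keep_ind)
  ), class = "qc_report")
  list(panel = subset_panel(panel, which(keep_ind), which(keep_snp)),
       report = report)
}

#' Drop SNPs monomorphic within the current individual set
#'
#' After subsetting a panel (e.g. to children only, or after relatedness
#' pruning) a SNP that passed cohort-level QC can be constant in the
#' remaining sample; allele-frequency weighting is undefined for it.
#'
#' @param panel a \code{genotype_panel}.
#' @return the panel with constant (or all-missing) SNPs removed; the number
#'   removed is attribute \code{"n_dropped"}.
#' @export
drop_monomorphic <- function(panel) {
  stop_if_not_panel(panel)
  p <- colMeans(panel$X, na.rm = TRUE) / 2
  keep <- is.finite(p) & p > 0 & p < 1
  out <- if (all(keep)) panel else subset_panel(panel, snps = which(keep))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC: %d/%d SNPs retained (%d MAF < %g, %d missingness > %g);\n",
    x$n_snps_out, x$n_snps_in, x$n_snp_maf, x$thresholds$maf_min,
    x$n_snp_missing, x$thresholds$snp_missing_max))
  cat(sprintf("    %d/%d individuals retained (%d heterozygosity > %g SD)\n",
              x$n_ind_out, x$n_ind_in, x$n_ind_het, x$thresholds$het_sd))
  invisible(x)
}
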