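#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; report tables here follow the
#' half-up convention common in printed tables (93.548 -> 94, 56.25 -> 56).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dosage matrix column standardization by sample allele frequency:
# mean 2p, sd sqrt(2p(1-p)); missing entries -> 0 (pairwise handling is the
# caller's job).  Errors on monomorphic columns unless drop_monomorphic.
standardize_dosage <- function(X, p = NULL) {
  if (is.null(p)) p <- colMeans(X, na.rm = TRUE) / 2
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("monomorphic or all-missing SNP encountered; run QC first",
         call. = FALSE)
  }
  Z <- sweep(X, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  Z
}

stop_if_not_panel <- function(panel) {
  if (!inherits(panel, "genotype_panel")) {
    stop("expected a 'genotype_panel' object", call. = FALSE)
  }
  invisible(panel)
}
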