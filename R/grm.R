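#' Compute the genetic relatedness matrix (GRM)
#'
#' Each entry is the mean over SNPs of allele-frequency-weighted genotype
#' products:
#' \deqn{A_{ij} = \frac{1}{m_{ij}} \sum_k
#'   \frac{(x_{ik} - 2p_k)(x_{jk} - 2p_k)}{2p_k(1-p_k)},}
#' with \eqn{p_k} the sample allele frequency and \eqn{m_{ij}} the number of
#' SNPs non-missing in both individuals (pairwise deletion).  The diagonal
#' uses the same centered product with \eqn{i = j}.
#'
#' @param panel a \code{genotype_panel} (post-QC: no monomorphic SNPs), or a
#'   numeric dosage matrix (individuals x SNPs) with row names as ids.
#' @return a \code{grm} object: \code{A} (symmetric relatedness matrix),
#'   \code{n_pairs} (per-pair non-missing SNP counts; a scalar when there is
#'   no missingness), \code{ids}, \code{fid}, and a provenance \code{note}.
#' @export
compute_grm <- function(panel) {
  if (inherits(panel, "genotype_panel")) {
    X <- panel$X
    ids <- panel$ids
    fid <- panel$fid
  } else {
    X <- as.matrix(panel)
    ids <- rownames(X) %||% paste0("ind", seq_len(nrow(X)))
    fid <- ids
  }
  if (nrow(X) < 2) stop("need at least 2 individuals", call. = FALSE)
  if (ncol(X) < 1) stop("need at least 1 SNP", call. = FALSE)
  Z <- standardize_dosage(X)                   # errors on monomorphic SNPs
  if (anyNA(X)) {
    obs <- !is.na(X)
    storage.mode(obs) <- "numeric"
    Np <- tcrossprod(obs)
    if (any(Np == 0)) stop("individual pair with no shared non-missing SNPs",
                           call. = FALSE)
  } else {
    Np <- ncol(X)
  }
  A <- tcrossprod(Z) / Np
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, n_pairs = Np, ids = ids, fid = fid,
                 note = sprintf("%d SNPs, sample allele frequencies",
                                ncol(X))),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals (%s); mean diagonal %.4f\n",
              length(x$ids), x$note, mean(diag(x$A))))
  invisible(x)
}

#' Greedy relatedness pruning
#'
#' Removes individuals until no remaining pair has relatedness at or above
#' \code{threshold} (the GREML convention: drop one of each pair related at
#' 0.025 or more, i.e. closer than about fifth-degree relatives).  Removal is
#' greedy: repeatedly drop the individual in the most violating pairs,
#' breaking ties by later position in the id order, which makes the result
#' deterministic.
#'
#' @param grm a \code{grm} object.
#' @param threshold relatedness cutoff (default 0.025).
#' @return character vector of retained ids, with the removed ids as
#'   attribute \code{"removed"}.
#' @export
prune_related <- function(grm, threshold = 0.025) {
  if (!inherits(grm, "grm")) stop("expected a 'grm' object", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  A <- grm$A
  n <- nrow(A)
  viol <- A >= threshold                        # similarity, signed: negative
                                                # estimates are chance noise
  viol[upper.tri(viol, diag = TRUE)] <- FALSE   # keep lower triangle pairs
  alive <- rep(TRUE, n)
  deg <- function() {
    v <- viol & outer(alive, alive, "&")
    rowSums(v) + colSums(v)
  }
  repeat {
    d <- deg()
    if (max(d) == 0) break
    worst <- max(which(d == max(d)))            # tie -> later id
    alive[worst] <- FALSE
  }
  structure(grm$ids[alive], removed = grm$ids[!alive])
}

#' Write a GRM as the GCTA binary triplet
#'
#' \code{prefix.grm.bin} holds the lower triangle including the diagonal,
#' row-major, as 4-byte little-endian reals; \code{prefix.grm.N.bin} the
#' per-pair non-missing SNP counts in the same order; \code{prefix.grm.id}
#' the FID/IID lines.
#'
#' @param grm a \code{grm} object.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_grm_gcta <- function(grm, prefix) {
  if (!inherits(grm, "grm")) stop("expected a 'grm' object", call. = FALSE)
  n <- length(grm$ids)
  tri <- upper.tri(grm$A, diag = TRUE)          # column-major == row-major
  vals <- t(grm$A)[tri]                         # traversal of the lower tri
  Np <- grm$n_pairs
  nvals <- if (is.matrix(Np)) t(Np)[tri] else rep(Np, n * (n + 1) / 2)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(nvals), con, size = 4, endian = "little")
  close(con)
  write.table(data.frame(grm$fid, grm$ids), paste0(prefix, ".grm.id"),
              quote = FALSE, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM triplet
#'
#' @param prefix path prefix of the \code{.grm.bin/.grm.N.bin/.grm.id} files.
#' @return a \code{grm} object (4-byte precision).
#' @export
read_grm_gcta <- function(prefix) {
  idf <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(idf)
  ntri <- n * (n + 1) / 2
  f <- paste0(prefix, ".grm.bin")
  nstored <- file.size(f) / 4
  if (nstored != ntri) {
    stop(sprintf("%s holds %d values but %d ids imply n(n+1)/2 = %d",
                 f, nstored, n, ntri), call. = FALSE)
  }
  vals <- readBin(f, "numeric", n = ntri, size = 4, endian = "little")
  A <- matrix(0, n, n)
  tri <- upper.tri(A, diag = TRUE)
  tA <- t(A)
  tA[tri] <- vals
  A <- t(tA)
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  dimnames(A) <- list(idf[[2]], idf[[2]])
  nf <- paste0(prefix, ".grm.N.bin")
  Np <- if (file.exists(nf)) {
    nv <- readBin(nf, "numeric", n = ntri, size = 4, endian = "little")
    M <- matrix(0, n, n)
    tM <- t(M)
    tM[tri] <- nv
    M <- t(tM)
    M[upper.tri(M)] <- t(M)[upper.tri(M)]
    M
  } else {
    NA_real_
  }
  structure(list(A = A, n_pairs = Np, ids = idf[[2]], fid = idf[[1]],
                 note = sprintf("read from %s", prefix)),
            class = "grm")
}

#' Subset a GRM to a set of individuals
#'
#' @param grm a \code{grm} object.
#' @param ids character ids to keep, in the order given.
#' @return the subset \code{grm}.
#' @export
subset_grm <- function(grm, ids) {
  i <- match(ids, grm$ids)
  if (anyNA(i)) stop("ids not present in GRM", call. = FALSE)
  structure(list(A = grm$A[i, i, drop = FALSE],
                 n_pairs = if (is.matrix(grm$n_pairs))
                   grm$n_pairs[i, i, drop = FALSE] else grm$n_pairs,
                 ids = grm$ids[i], fid = grm$fid[i], note = grm$note),
            class = "grm")
}
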