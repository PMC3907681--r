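# build a genotype_panel directly from a dosage matrix (individuals x SNPs)
make_panel <- function(X, ids = NULL, fid = NULL, role = NULL, sex = NULL,
                       subpop = NULL, chr = NULL) {
  n <- nrow(X)
  m <- ncol(X)
  ids <- ids %||% sprintf("I%03d", seq_len(n))
  storage.mode(X) <- "integer"
  rownames(X) <- ids
  snp_id <- colnames(X) %||% sprintf("s%04d", seq_len(m))
  colnames(X) <- snp_id
  p <- colMeans(X, na.rm = TRUE) / 2
  structure(list(
    ids = ids, fid = fid %||% ids, role = role %||% rep(NA_character_, n),
    sex = sex %||% rep(0L, n), subpop = subpop %||% rep(1L, n), X = X,
    snps = data.frame(id = snp_id, chr = chr %||% rep(1L, m),
                      pos = seq_len(m) * 100L, a1 = "A", a2 = "C",
                      freq1 = p, stringsAsFactors = FALSE),
    transmission = NULL, params = NULL
  ), class = "genotype_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random unrelated dosage matrix under Hardy-Weinberg; columns are resampled
# until polymorphic so tiny fixtures never hit the monomorphic-SNP guard
random_dosages <- function(n, m, maf = c(0.1, 0.5)) {
  p <- runif(m, maf[1], maf[2])
  X <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  repeat {
    mono <- which(apply(X, 2, function(col) length(unique(col)) == 1))
    if (!length(mono)) break
    X[, mono] <- rbinom(n * length(mono), 2L, 0.4)
  }
  X
}

# build a grm object directly from a relatedness matrix
make_grm <- function(A, ids = NULL) {
  ids <- ids %||% sprintf("I%03d", seq_len(nrow(A)))
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, n_pairs = 1000, ids = ids, fid = ids,
                 note = "synthetic"), class = "grm")
}

# small simulated cohort: panel + phenotypes + child GRM
small_cohort <- function(n_fam = 400, m = 800, h2_ses = 0.5, h2_iq = 0.5,
                         rho_eff = 1, n_causal = 200, seed = 1,
                         ses_mode = "child-genic") {
  ps <- sim_params(n_families = n_fam, n_snps = m, h2_ses = h2_ses,
                   h2_iq = h2_iq, rho_eff = rho_eff, n_causal_ses = n_causal,
                   n_causal_iq = n_causal, ses_mode = ses_mode, seed = seed)
  pan <- simulate_genotypes(ps)
  ph <- simulate_phenotypes(pan, ps)
  grm <- compute_grm(children_panel(pan))
  list(params = ps, panel = pan, pheno = ph, grm = grm,
       ses = setNames(ph$ses, ph$iid), iq = setNames(ph$iq, ph$iid))
}
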