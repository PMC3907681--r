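#' Simulation parameters for the family-structured generator
#'
#' Bundles and validates every knob of the synthetic cohort: unrelated nuclear
#' families (two parents, one child), Mendelian transmission, optional
#' two-or-more subpopulation stratification (Balding-Nichols allele-frequency
#' divergence), a family-level SES phenotype built from parental or child
#' genotypes, and a child IQ phenotype sharing causal variants with SES.
#'
#' Defaults emulate the cohort structure the analysis is designed for:
#' thousands of unrelated families, SNP-heritability around 0.2 for family SES
#' and 0.3 for child IQ, and a genetic correlation near 1 between the two
#' traits (effect correlation \code{rho_eff = 1} over a shared causal set).
#'
#' @param n_families number of nuclear families (one child per family).
#' @param n_snps number of biallelic SNPs.
#' @param maf_range length-2 numeric, ancestral minor-allele-frequency range;
#'   must lie within (0, 0.5].
#' @param n_causal_ses,n_causal_iq numbers of causal SNPs per trait (default
#'   \code{min(500, n_snps)}).  The
#'   first \code{min(n_causal_ses, n_causal_iq)} causal SNPs are shared
#'   between the traits; remaining causal SNPs are trait-specific.
#' @param rho_eff correlation of per-SNP effect sizes over the shared causal
#'   set, in [-1, 1]; with equal causal sets the true genetic correlation of
#'   the two traits is approximately \code{rho_eff}.
#' @param h2_ses,h2_iq target heritabilities in [0, 1] (for SES this is the
#'   heritability of its generating genetic value; see \code{ses_mode}).
#' @param ses_mode \code{"child-genic"}: the SES genetic value is the child's
#'   own additive score (the GREML estimand on a child GRM then equals
#'   \code{h2_ses}); \code{"midparent-genic"}: it is the mean of the two
#'   parents' additive scores, so a child-GRM GREML estimate is attenuated.
#' @param n_subpop number of subpopulations (families are split evenly).
#' @param fst Balding-Nichols divergence of subpopulation allele frequencies
#'   from the ancestral frequency; 0 means no stratification.
#' @param seed integer random seed; all generator functions are deterministic
#'   given the params object.
#' @return an object of class \code{sim_params}.
#' @export
sim_params <- function(n_families = 2000, n_snps = 4000,
                       maf_range = c(0.05, 0.5),
                       n_causal_ses = NULL, n_causal_iq = NULL,
                       rho_eff = 1, h2_ses = 0.2, h2_iq = 0.3,
                       ses_mode = c("child-genic", "midparent-genic"),
                       n_subpop = 1, fst = 0, seed = 1) {
  ses_mode <- match.arg(ses_mode)
  if (n_families < 1 || n_snps < 1) {
    stop("n_families and n_snps must be positive", call. = FALSE)
  }
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (h2_ses < 0 || h2_ses > 1 || h2_iq < 0 || h2_iq > 1) {
    stop("heritabilities must be in [0, 1]", call. = FALSE)
  }
  if (abs(rho_eff) > 1) stop("rho_eff must be in [-1, 1]", call. = FALSE)
  n_causal_ses <- n_causal_ses %||% min(500, n_snps)
  n_causal_iq <- n_causal_iq %||% min(500, n_snps)
  if (n_causal_ses < 1 || n_causal_ses > n_snps ||
      n_causal_iq < 1 || n_causal_iq > n_snps) {
    stop("causal SNP counts must be in [1, n_snps]", call. = FALSE)
  }
  if (n_subpop < 1) stop("n_subpop must be >= 1", call. = FALSE)
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)", call. = FALSE)
  structure(list(
    n_families = as.integer(n_families), n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    n_causal_ses = as.integer(n_causal_ses),
    n_causal_iq = as.integer(n_causal_iq),
    rho_eff = rho_eff, h2_ses = h2_ses, h2_iq = h2_iq,
    ses_mode = ses_mode, n_subpop = as.integer(n_subpop), fst = fst,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Simulate family-structured SNP genotypes
#'
#' Parents are drawn in Hardy-Weinberg proportions within their subpopulation;
#' each child receives one allele from each parent by Mendelian transmission
#' (the transmitted-allele indicators are stored so Mendelian consistency is
#' checkable).  With \code{n_subpop > 1} and \code{fst > 0}, subpopulation
#' allele frequencies diverge from the ancestral frequency by Balding-Nichols
#' Beta draws, planting a leading eigenvalue for the Tracy-Widom test to find.
#'
#' Dosages count copies of allele 1 (the allele whose ancestral frequency was
#' drawn from \code{maf_range}).
#'
#' @param params a [sim_params()] object.
#' @return a \code{genotype_panel}: list with \code{ids}, \code{fid},
#'   \code{role} (mother/father/child), \code{sex} (1 = male, 0 = female),
#'   \code{subpop}, integer dosage matrix \code{X} (individuals x SNPs, NA =
#'   missing), SNP table \code{snps} (id, chr, pos, alleles, per-subpopulation
#'   frequency columns), and \code{transmission} (per-family transmitted
#'   allele counts from mother and father).
#' @export
simulate_genotypes <- function(params) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  set.seed(params$seed)
  nf <- params$n_families
  m <- params$n_snps
  p_anc <- runif(m, params$maf_range[1], params$maf_range[2])

  freq <- matrix(p_anc, nrow = params$n_subpop, ncol = m, byrow = TRUE)
  if (params$n_subpop > 1 && params$fst > 0) {
    a <- p_anc * (1 - params$fst) / params$fst
    b <- (1 - p_anc) * (1 - params$fst) / params$fst
    for (s in seq_len(params$n_subpop)) {
      freq[s, ] <- pmin(pmax(rbeta(m, a, b), 1e-3), 1 - 1e-3)
    }
  }
  fam_pop <- rep_len(seq_len(params$n_subpop), nf)
  P <- freq[fam_pop, , drop = FALSE]              # nf x m generating freqs

  mo <- matrix(rbinom(nf * m, 2L, as.vector(P)), nf, m)
  fa <- matrix(rbinom(nf * m, 2L, as.vector(P)), nf, m)
  tm <- matrix(rbinom(nf * m, 1L, as.vector(mo) / 2), nf, m)
  tf <- matrix(rbinom(nf * m, 1L, as.vector(fa) / 2), nf, m)
  ch <- tm + tf

  fid <- sprintf("F%05d", seq_len(nf))
  ids <- c(paste0(fid, "_MO"), paste0(fid, "_FA"), paste0(fid, "_CH"))
  role <- rep(c("mother", "father", "child"), each = nf)
  sex <- c(rep(0L, nf), rep(1L, nf), rbinom(nf, 1L, 0.5))
  X <- rbind(mo, fa, ch)
  storage.mode(X) <- "integer"
  snp_id <- sprintf("snp%05d", seq_len(m))
  rownames(X) <- ids
  colnames(X) <- snp_id

  snps <- data.frame(id = snp_id, chr = 1L, pos = seq_len(m) * 1000L,
                     a1 = "A", a2 = "C", stringsAsFactors = FALSE)
  fq <- t(freq)
  colnames(fq) <- paste0("freq", seq_len(params$n_subpop))
  snps <- cbind(snps, as.data.frame(fq))

  structure(list(
    ids = ids, fid = rep(fid, 3), role = role, sex = sex,
    subpop = rep(fam_pop, 3), X = X, snps = snps,
    transmission = list(mother = tm, father = tf),
    params = params
  ), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d SNPs", nrow(x$X),
              ncol(x$X)))
  if (!all(is.na(x$role))) {
    cat(sprintf(" (%d children)", sum(x$role == "child", na.rm = TRUE)))
  }
  cat(sprintf(", %d missing calls\n", sum(is.na(x$X))))
  invisible(x)
}

#' Subset a genotype panel by individuals and/or SNPs
#'
#' @param panel a \code{genotype_panel}.
#' @param individuals character ids or logical/integer index over rows.
#' @param snps character SNP ids or logical/integer index over columns.
#' @return the subset \code{genotype_panel} (transmission records are dropped
#'   unless all three family members survive the subset unchanged).
#' @export
subset_panel <- function(panel, individuals = NULL, snps = NULL) {
  stop_if_not_panel(panel)
  ri <- seq_along(panel$ids)
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) match(individuals, panel$ids)
          else ri[individuals]
    if (anyNA(ri)) stop("unknown individual ids in subset", call. = FALSE)
  }
  ci <- seq_len(ncol(panel$X))
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, panel$snps$id) else ci[snps]
    if (anyNA(ci)) stop("unknown SNP ids in subset", call. = FALSE)
  }
  out <- panel
  out$ids <- panel$ids[ri]
  out$fid <- panel$fid[ri]
  out$role <- panel$role[ri]
  out$sex <- panel$sex[ri]
  out$subpop <- panel$subpop[ri]
  out$X <- panel$X[ri, ci, drop = FALSE]
  out$snps <- panel$snps[ci, , drop = FALSE]
  if (!identical(ri, seq_along(panel$ids)) ||
      !identical(ci, seq_len(ncol(panel$X)))) {
    out$transmission <- NULL
  }
  out
}

#' Children-only view of a family panel
#'
#' @param panel a \code{genotype_panel} containing child rows.
#' @return the panel restricted to children (the analysis sample: one child
#'   per family, conventionally unrelated across families).
#' @export
children_panel <- function(panel) {
  stop_if_not_panel(panel)
  subset_panel(panel, individuals = which(panel$role == "child"))
}

# child-side additive genetic scores for a set of causal columns, using the
# generating (subpopulation) allele frequencies for standardization
additive_scores <- function(panel, causal, beta) {
  fq <- as.matrix(panel$snps[, grep("^freq", names(panel$snps)), drop = FALSE])
  p <- fq[causal, panel$subpop, drop = FALSE]        # snps x individuals
  Xc <- t(panel$X[, causal, drop = FALSE])           # snps x individuals
  Z <- (Xc - 2 * p) / sqrt(2 * p * (1 - p))
  as.vector(crossprod(Z, beta))
}

#' Simulate SES and IQ phenotypes with known genetic truth
#'
#' Effect sizes are standard normal at causal SNPs applied to dosages
#' standardized by \code{sqrt(2p(1-p))}, matching the GRM weighting so the
#' generating heritability equals the GREML estimand in child-genic mode.
#' Effects over the shared causal set are a bivariate-normal draw with
#' correlation \code{rho_eff}.  SES is a family-level trait: in
#' midparent-genic mode its genetic value is the mean of the parents'
#' additive scores, in child-genic mode the child's own score; IQ is always
#' the child's score.  Genetic values and residuals are empirically rescaled
#' so each trait has variance ~1 and genetic fraction equal to the target
#' heritability; the per-family genetic truths are stored for recovery tests.
#'
#' Beyond the latent traits, observable indicator columns are emitted so the
#' phenotype-preparation stage is exercisable: five SES indicators loading
#' 0.8 on the SES composite, and four IQ test scores loading 0.8 on latent IQ
#' with small age and sex effects (removed downstream by regression).
#'
#' @param panel the \code{genotype_panel} the params generated.
#' @param params the same [sim_params()] object.
#' @return a \code{data.frame} of class \code{phenotype_table} with one row
#'   per family keyed by the child's id: \code{fid, iid, age, sex},
#'   latent \code{ses, iq}, genetic truths \code{g_ses, g_iq}, indicators
#'   \code{ses1..ses5}, test scores \code{iq1..iq4}.
#' @export
simulate_phenotypes <- function(panel, params) {
  stop_if_not_panel(panel)
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  if (ncol(panel$X) != params$n_snps) {
    stop("panel and params disagree on SNP count", call. = FALSE)
  }
  set.seed(params$seed + 500009L)
  m <- params$n_snps
  n_sh <- min(params$n_causal_ses, params$n_causal_iq)
  causal_sh <- sample.int(m, n_sh)
  rest <- setdiff(seq_len(m), causal_sh)
  extra_ses <- params$n_causal_ses - n_sh
  extra_iq <- params$n_causal_iq - n_sh
  causal_ses <- c(causal_sh,
                  if (extra_ses > 0) sample(rest, extra_ses) else integer(0))
  rest2 <- setdiff(rest, causal_ses)
  causal_iq <- c(causal_sh,
                 if (extra_iq > 0) sample(rest2, extra_iq) else integer(0))

  z1 <- rnorm(n_sh); z2 <- rnorm(n_sh)
  b_sh_ses <- z1
  b_sh_iq <- params$rho_eff * z1 + sqrt(1 - params$rho_eff^2) * z2
  beta_ses <- c(b_sh_ses, rnorm(extra_ses))
  beta_iq <- c(b_sh_iq, rnorm(extra_iq))

  kids <- children_panel(panel)
  nf <- length(kids$ids)
  g_iq_raw <- additive_scores(kids, causal_iq, beta_iq)
  g_ses_raw <- if (params$ses_mode == "child-genic") {
    additive_scores(kids, causal_ses, beta_ses)
  } else {
    mo <- subset_panel(panel, which(panel$role == "mother"))
    fa <- subset_panel(panel, which(panel$role == "father"))
    (additive_scores(mo, causal_ses, beta_ses) +
     additive_scores(fa, causal_ses, beta_ses)) / 2
  }

  scale_trait <- function(g, h2) {
    gs <- if (h2 > 0 && sd(g) > 0) g * sqrt(h2) / sd(g) else rep(0, length(g))
    e <- rnorm(length(g))
    es <- if (h2 < 1) e * sqrt(1 - h2) / sd(e) else rep(0, length(g))
    y <- gs + es
    s <- sd(y)
    list(y = y / s, g = gs / s)
  }
  ses <- scale_trait(g_ses_raw, params$h2_ses)
  iq <- scale_trait(g_iq_raw, params$h2_iq)

  age <- rnorm(nf, 7.04, 0.25)
  sex <- kids$sex
  lam <- 0.8
  noise_load <- sqrt(1 - lam^2)
  ind <- sapply(1:5, function(j) lam * ses$y + noise_load * rnorm(nf))
  tests <- sapply(1:4, function(j) {
    lam * iq$y + noise_load * rnorm(nf) +
      0.15 * as.vector(scale(age)) + 0.10 * sex
  })
  colnames(ind) <- paste0("ses", 1:5)
  colnames(tests) <- paste0("iq", 1:4)

  out <- data.frame(fid = kids$fid, iid = kids$ids, age = age, sex = sex,
                    ses = ses$y, iq = iq$y, g_ses = ses$g, g_iq = iq$g,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ind), as.data.frame(tests))
  attr(out, "truth") <- list(h2_ses = params$h2_ses, h2_iq = params$h2_iq,
                             rho_eff = params$rho_eff,
                             ses_mode = params$ses_mode,
                             causal_ses = causal_ses, causal_iq = causal_iq)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Check Mendelian consistency of a family panel
#'
#' Verifies that every child dosage equals the sum of the stored transmitted
#' alleles and that each transmitted allele is reachable from the parent's
#' dosage (a parent with dosage 0 cannot transmit allele 1, and with dosage 2
#' must).
#'
#' @param panel a \code{genotype_panel} with transmission records.
#' @return TRUE invisibly, or an error describing the first violation.
#' @export
check_mendelian <- function(panel) {
  stop_if_not_panel(panel)
  tr <- panel$transmission
  if (is.null(tr)) stop("panel has no transmission records", call. = FALSE)
  mo <- panel$X[panel$role == "mother", , drop = FALSE]
  fa <- panel$X[panel$role == "father", , drop = FALSE]
  ch <- panel$X[panel$role == "child", , drop = FALSE]
  if (!all(ch == tr$mother + tr$father, na.rm = TRUE)) {
    stop("child dosage != transmitted allele sum", call. = FALSE)
  }
  bad <- (tr$mother == 1 & mo == 0) | (tr$mother == 0 & mo == 2) |
         (tr$father == 1 & fa == 0) | (tr$father == 0 & fa == 2)
  if (any(bad, na.rm = TRUE)) {
    stop("transmitted allele impossible given parental dosage", call. = FALSE)
  }
  invisible(TRUE)
}
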