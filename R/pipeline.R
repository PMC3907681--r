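#' Pipeline configuration with every threshold explicit
#'
#' A single flat configuration carrying every analysis constant, so each
#' threshold is auditable and overridable: QC (MAF floor 0.01, SNP
#' missingness ceiling 0.05, heterozygosity 3 SD), relatedness cutoff 0.025,
#' LD pruning r-squared 0.2, Tracy-Widom alpha 0.05, phenotype outlier limit
#' 3 SD, minimum 3 of 4 tests for the IQ composite.  Round-trips unchanged
#' through YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param input_mode \code{"simulate"} or \code{"plink"}.
#' @param plink_prefix bed/bim/fam prefix when \code{input_mode = "plink"}.
#' @param sim named list of [sim_params()] arguments for simulate mode.
#' @param maf_min,snp_missing_max,het_sd QC thresholds.
#' @param relatedness relatedness pruning cutoff.
#' @param r2_max,ld_window,ld_step LD pruning controls.
#' @param tw_alpha,n_pcs Tracy-Widom level and the number of candidate axes
#'   scored (selection may also be overridden to a fixed count with
#'   \code{n_pcs_fixed}).
#' @param n_pcs_fixed optional fixed number of ancestry covariate axes,
#'   bypassing the Tracy-Widom selection (a cohort-specific convention).
#' @param sd_limit,min_present phenotype preparation controls.
#' @param min_overlap smallest non-zero bivariate overlap accepted.
#' @param seed integer seed controlling every stochastic stage.
#' @param out_dir output directory for artifacts and reports.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(input_mode = c("simulate", "plink"),
                            plink_prefix = NULL, sim = list(),
                            maf_min = 0.01, snp_missing_max = 0.05,
                            het_sd = 3, relatedness = 0.025,
                            r2_max = 0.2, ld_window = 50, ld_step = 20,
                            tw_alpha = 0.05, n_pcs = 10, n_pcs_fixed = NULL,
                            sd_limit = 3, min_present = 3, min_overlap = 30,
                            seed = 1, out_dir = tempfile("famgreml_run_")) {
  input_mode <- match.arg(input_mode)
  stopifnot(maf_min >= 0, maf_min < 0.5, snp_missing_max >= 0,
            snp_missing_max <= 1, het_sd > 0, relatedness > 0,
            r2_max > 0, r2_max <= 1, ld_window >= 2, ld_step >= 1,
            tw_alpha >= 0, tw_alpha < 1, n_pcs >= 0, sd_limit > 0,
            min_present >= 1, min_present <= 4)
  structure(list(
    input_mode = input_mode, plink_prefix = plink_prefix, sim = sim,
    maf_min = maf_min, snp_missing_max = snp_missing_max, het_sd = het_sd,
    relatedness = relatedness, r2_max = r2_max, ld_window = ld_window,
    ld_step = ld_step, tw_alpha = tw_alpha, n_pcs = n_pcs,
    n_pcs_fixed = n_pcs_fixed, sd_limit = sd_limit,
    min_present = min_present, min_overlap = min_overlap,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> QC -> GRM -> relatedness pruning ->
#' LD pruning + PCA + Tracy-Widom covariates -> phenotype preparation ->
#' univariate GREML per trait with the boundary LRT -> bivariate GREML ->
#' derived statistics (genetic, residual and phenotypic correlations,
#' genetically mediated share).  Deterministic given the config seed.  All
#' intermediate artifacts are written to \code{config$out_dir}: the PLINK
#' triplet, the GCTA GRM triplet, the covariate and phenotype tables,
#' hsq-style univariate reports, the bivariate table, and a consolidated
#' JSON report; a log records every threshold applied and every id excluded.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (they always go to the log file).
#' @return a \code{run_report} list (also written as \code{report.json}).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stop("expected a 'pipeline_config'", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "log.txt")
  cat("", file = logfile)
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  counts <- list()

  # --- genotypes ------------------------------------------------------
  panel <- stage("input", {
    if (config$input_mode == "simulate") {
      sim_args <- config$sim
      sim_args$seed <- sim_args$seed %||% config$seed
      params <- do.call(sim_params, sim_args)
      say("simulate: %d families x %d SNPs (seed %d)", params$n_families,
          params$n_snps, params$seed)
      p <- simulate_genotypes(params)
      pheno_raw <- simulate_phenotypes(p, params)
      write_plink(p, file.path(config$out_dir, "panel"))
      attr(p, "pheno_raw") <- pheno_raw
      p
    } else {
      say("reading PLINK triplet %s", config$plink_prefix)
      read_plink(config$plink_prefix)
    }
  })
  counts$input <- c(individuals = length(panel$ids), snps = ncol(panel$X))

  qc <- stage("qc", qc_filter(panel, config$maf_min, config$snp_missing_max,
                              config$het_sd))
  say("qc: %d -> %d SNPs, %d -> %d individuals (removed ids: %s)",
      qc$report$n_snps_in, qc$report$n_snps_out, qc$report$n_ind_in,
      qc$report$n_ind_out,
      if (length(qc$report$removed_ids)) {
        paste(qc$report$removed_ids, collapse = ",")
      } else "none")
  counts$post_qc <- c(individuals = qc$report$n_ind_out,
                      snps = qc$report$n_snps_out)

  kids <- stage("children", {
    k <- if (all(is.na(qc$panel$role))) qc$panel else children_panel(qc$panel)
    drop_monomorphic(k)
  })
  say("analysis sample: %d children, %d SNPs monomorphic within it dropped",
      length(kids$ids), attr(kids, "n_dropped"))

  grm <- stage("grm", compute_grm(kids))
  write_grm_gcta(grm, file.path(config$out_dir, "panel"))
  keep <- stage("prune", prune_related(grm, config$relatedness))
  removed <- attr(keep, "removed")
  say("relatedness pruning at %.3f: removed %d (%s)", config$relatedness,
      length(removed),
      if (length(removed)) paste(removed, collapse = ",") else "none")
  grm_p <- subset_grm(grm, keep)
  counts$post_prune <- c(individuals = length(keep))

  # --- stratification covariates -------------------------------------
  kept_panel <- drop_monomorphic(subset_panel(kids, keep))
  ld_keep <- stage("ld_prune",
                   ld_prune(kept_panel, config$r2_max, config$ld_window,
                            config$ld_step))
  say("ld pruning at r2 > %.2f: %d of %d SNPs retained", config$r2_max,
      length(ld_keep), ncol(kept_panel$X))
  pcs <- stage("pca", pca_axes(kept_panel, ld_keep,
                               k = min(config$n_pcs,
                                       length(keep) - 2)))
  sel <- if (!is.null(config$n_pcs_fixed)) {
    seq_len(min(config$n_pcs_fixed, ncol(pcs$scores)))
  } else {
    stage("tracy_widom", tracy_widom_select(pcs, config$tw_alpha))
  }
  say("ancestry axes selected: %d (alpha %.2f%s)", length(sel),
      config$tw_alpha,
      if (!is.null(config$n_pcs_fixed)) ", fixed override" else "")
  covar <- if (length(sel)) pcs$scores[, sel, drop = FALSE] else NULL
  write_covariates(pcs, file.path(config$out_dir, "covariates.tsv"),
                   axes = seq_len(ncol(pcs$scores)))

  # --- phenotypes -----------------------------------------------------
  pheno <- stage("phenotypes", {
    raw <- attr(panel, "pheno_raw")
    if (is.null(raw)) stop("plink input mode requires a phenotype table; ",
                           "supply one via config$sim or simulate mode")
    raw[raw$iid %in% keep, , drop = FALSE]
  })
  prep <- stage("pheno_prep", {
    ses_cols <- paste0("ses", 1:5)
    iq_cols <- paste0("iq", 1:4)
    ses_c <- ses_composite(pheno[, ses_cols])
    say("SES composite: first PC explains %.1f%% of indicator variance",
        100 * attr(ses_c, "variance_explained"))
    out_m <- exclude_outliers(ses_c, config$sd_limit)
    say("SES outliers beyond %.1f SD: %d", config$sd_limit, sum(out_m))
    ses_c[out_m] <- NA
    ses_final <- as.vector(scale(ses_c))
    tests <- sapply(iq_cols, function(cl) {
      prepare_trait(pheno[[cl]], pheno$age, pheno$sex, config$sd_limit)
    })
    iq_final <- as.vector(scale(iq_composite(tests, config$min_present,
                                             standardize = FALSE)))
    data.frame(fid = pheno$fid, iid = pheno$iid, ses = ses_final,
               iq = iq_final, stringsAsFactors = FALSE)
  })
  write.table(prep, file.path(config$out_dir, "phenotypes.tsv"),
              quote = FALSE, sep = "\t", row.names = FALSE)

  ses_v <- setNames(prep$ses, prep$iid)
  iq_v <- setNames(prep$iq, prep$iid)

  # --- univariate fits ------------------------------------------------
  uni <- list()
  for (tr in c("ses", "iq")) {
    yv <- if (tr == "ses") ses_v else iq_v
    fit <- stage(paste0("reml_", tr),
                 fit_univariate(yv, grm_p, covariates = covar))
    null <- fit_null(yv[fit$ids], covariates = if (is.null(covar)) NULL
                     else covar[fit$ids, , drop = FALSE])
    lr <- lrt(fit, null)
    write_hsq(fit, null, file.path(config$out_dir, paste0(tr, ".hsq")))
    say("%s: V(G)/Vp = %.3f (SE %.3f), LRT = %.2f, p = %.3g, n = %d",
        toupper(tr), fit$h2, fit$se["h2"], lr$lrt, lr$p, fit$n)
    uni[[tr]] <- list(fit = fit, null = null, lrt = lr)
  }

  # --- bivariate fit and derived statistics ---------------------------
  des <- stage("align", align_bivariate(ses_v, iq_v, grm_p,
                                        covariates1 = covar,
                                        covariates2 = covar,
                                        min_overlap = config$min_overlap))
  bfit <- stage("reml_bivar", fit_bivariate(des))
  write_bivar_report(bfit, file.path(config$out_dir, "bivariate.tsv"))
  rg <- genetic_correlation(bfit)
  re <- residual_correlation(bfit)
  rp <- phenotypic_correlation(ses_v, iq_v)
  med <- mediation_proportion(bfit, rp)
  say("bivariate: r_G = %.2f (SE %.2f)%s, r_E = %.2f, r_p = %.2f; %d%% of",
      rg$value, rg$se, if (rg$constrained) " [constrained]" else "",
      re$value, rp$value, round_half_up(med))
  say("  the phenotypic correlation is mediated genetically")
  decomposition <- list(
    phenotypic = rp$value,
    genetic_contribution = attr(med, "cg_scaled"),
    residual_contribution = rp$value - attr(med, "cg_scaled"),
    mediated_percent = round_half_up(as.numeric(med))
  )

  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  report <- structure(list(
    counts = counts,
    univariate = lapply(uni, function(u) list(
      vg = u$fit$vg, ve = u$fit$ve, vp = u$fit$vp, h2 = u$fit$h2,
      se = as.list(u$fit$se), logL = u$fit$logL, logL0 = u$null$logL,
      lrt = u$lrt$lrt, df = u$lrt$df, p = u$lrt$p, n = u$fit$n,
      converged = u$fit$converged)),
    bivariate = list(
      components = as.list(bfit$components), se = as.list(bfit$se),
      h2_1 = bfit$h2_1, h2_2 = bfit$h2_2, logL = bfit$logL,
      n1 = bfit$n1, n2 = bfit$n2, n_overlap = bfit$n_overlap,
      converged = bfit$converged),
    derived = list(
      r_G = rg$value, r_G_se = rg$se, r_G_constrained = rg$constrained,
      r_E = re$value, r_E_se = re$se,
      r_p = rp$value, mediated_percent = round_half_up(as.numeric(med))),
    decomposition = decomposition,
    n_axes = length(sel),
    version = as.character(utils::packageVersion("famgreml")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed
  ), class = "run_report")
  jsonlite::write_json(
    report[setdiff(names(report), character(0))],
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("famgreml run report\n")
  cat(sprintf("  sample funnel: %d -> %d -> %d individuals\n",
              x$counts$input[["individuals"]],
              x$counts$post_qc[["individuals"]],
              x$counts$post_prune[["individuals"]]))
  for (tr in names(x$univariate)) {
    u <- x$univariate[[tr]]
    cat(sprintf("  %s: h2 = %.3f (SE %.3f), LRT = %.2f, p = %.3g, n = %d\n",
                toupper(tr), u$h2, u$se$h2, u$lrt, u$p, u$n))
  }
  d <- x$derived
  cat(sprintf("  r_G = %.2f%s, r_E = %.2f, r_p = %.2f, mediated = %d%%\n",
              d$r_G, if (d$r_G_constrained) " [constrained]" else "",
              d$r_E, d$r_p, d$mediated_percent))
  invisible(x)
}
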