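#' Align two phenotypes and a GRM into a stacked bivariate design
#'
#' Builds the stacked response of length \code{n1 + n2} with trait-specific
#' fixed-effect blocks and the GRM sub-blocks for (trait1, trait1),
#' (trait2, trait2) and the cross-trait pairs.  Individuals measured on both
#' traits are ordered first within each block, so the residual-covariance
#' structure (which applies only to them) is contiguous and auditable.  The
#' two samples may differ and need not overlap completely; with zero overlap
#' the residual covariance is inestimable and is flagged as fixed to zero.
#'
#' @param pheno1,pheno2 named numeric phenotype vectors (names = ids; NAs
#'   dropped).  Every phenotyped id must be present in the GRM.
#' @param grm a \code{grm} object (already relatedness-pruned).
#' @param covariates1,covariates2 optional per-trait covariate matrices with
#'   row names as ids (intercepts are always added per trait).
#' @param min_overlap smallest acceptable non-zero overlap (default 30);
#'   overlaps in (0, min_overlap) raise an error.
#' @return a \code{bivariate_design}.
#' @export
align_bivariate <- function(pheno1, pheno2, grm, covariates1 = NULL,
                            covariates2 = NULL, min_overlap = 30) {
  if (!inherits(grm, "grm")) stop("expected a 'grm' object", call. = FALSE)
  p1 <- pheno1[!is.na(pheno1)]
  p2 <- pheno2[!is.na(pheno2)]
  if (is.null(names(p1)) || is.null(names(p2))) {
    stop("phenotypes must be named by individual id", call. = FALSE)
  }
  missing_ids <- setdiff(c(names(p1), names(p2)), grm$ids)
  if (length(missing_ids)) {
    stop("phenotyped ids absent from the GRM: ",
         paste(head(missing_ids), collapse = ", "), call. = FALSE)
  }
  shared <- intersect(names(p1), names(p2))
  n_ov <- length(shared)
  if (n_ov > 0 && n_ov < min_overlap) {
    stop(sprintf(
      "only %d individuals have both traits (< min_overlap = %d); the
residual covariance would be poorly identified", n_ov, min_overlap),
      call. = FALSE)
  }
  ids1 <- c(shared, setdiff(names(p1), shared))
  ids2 <- c(shared, setdiff(names(p2), shared))
  mkX <- function(ids, cov, tag) {
    X <- matrix(1, length(ids), 1,
                dimnames = list(ids, paste0("intercept_", tag)))
    if (!is.null(cov)) {
      C <- as.matrix(cov)
      if (!all(ids %in% rownames(C))) {
        stop("covariates missing for some phenotyped ids", call. = FALSE)
      }
      C <- C[ids, , drop = FALSE]
      colnames(C) <- paste0(colnames(C), "_", tag)
      X <- cbind(X, C)
    }
    X
  }
  X1 <- mkX(ids1, covariates1, "tr1")
  X2 <- mkX(ids2, covariates2, "tr2")
  n1 <- length(ids1)
  n2 <- length(ids2)
  X <- rbind(cbind(X1, matrix(0, n1, ncol(X2))),
             cbind(matrix(0, n2, ncol(X1)), X2))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariates", call. = FALSE)
  structure(list(
    y = c(as.numeric(p1[ids1]), as.numeric(p2[ids2])),
    X = X, ids1 = ids1, ids2 = ids2, n1 = n1, n2 = n2, n_overlap = n_ov,
    A11 = grm$A[ids1, ids1, drop = FALSE],
    A12 = grm$A[ids1, ids2, drop = FALSE],
    A22 = grm$A[ids2, ids2, drop = FALSE],
    ce_fixed = n_ov == 0
  ), class = "bivariate_design")
}

# V_k %*% M for the six component derivative matrices, exploiting the block
# structure (overlap individuals sit first in both blocks)
.bv_mulVk <- function(k, M, des) {
  i1 <- seq_len(des$n1)
  i2 <- des$n1 + seq_len(des$n2)
  nov <- des$n_overlap
  M1 <- M[i1, , drop = FALSE]
  M2 <- M[i2, , drop = FALSE]
  Z1 <- matrix(0, des$n1, ncol(M))
  Z2 <- matrix(0, des$n2, ncol(M))
  switch(k,
    vg1 = rbind(des$A11 %*% M1, Z2),
    vg2 = rbind(Z1, des$A22 %*% M2),
    cg  = rbind(des$A12 %*% M2, crossprod(des$A12, M1)),
    ve1 = rbind(M1, Z2),
    ve2 = rbind(Z1, M2),
    ce  = {
      if (nov > 0) {
        Z1[seq_len(nov), ] <- M2[seq_len(nov), , drop = FALSE]
        Z2[seq_len(nov), ] <- M1[seq_len(nov), , drop = FALSE]
      }
      rbind(Z1, Z2)
    })
}

.bv_buildV <- function(th, des) {
  n1 <- des$n1; n2 <- des$n2
  nov <- des$n_overlap
  V11 <- th["vg1"] * des$A11
  diag(V11) <- diag(V11) + th["ve1"]
  V22 <- th["vg2"] * des$A22
  diag(V22) <- diag(V22) + th["ve2"]
  V12 <- th["cg"] * des$A12
  if (nov > 0) {
    ii <- cbind(seq_len(nov), seq_len(nov))
    V12[ii] <- V12[ii] + th["ce"]
  }
  rbind(cbind(V11, V12), cbind(t(V12), V22))
}

# cheap evaluation: log-likelihood only (Cholesky + a few solves)
.bv_loglik <- function(th, des) {
  V <- .bv_buildV(th, des)
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  y <- des$y
  X <- des$X
  Vy <- backsolve(cV, forwardsolve(t(cV), y))
  VX <- backsolve(cV, forwardsolve(t(cV), X))
  B <- crossprod(X, VX)
  cB <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(cB)) return(NULL)
  Xty <- crossprod(X, Vy)
  beta <- backsolve(cB, forwardsolve(t(cB), Xty))
  yPy <- sum(y * Vy) - sum(Xty * beta)
  ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cB))) + yPy)
  list(ll = ll, cV = cV, beta = beta)
}

#' Bivariate GREML fit by AI-REML
#'
#' Jointly estimates the six (co)variance components of two traits measured
#' on overlapping but possibly unequal samples: genetic variances
#' \code{vg1, vg2} and covariance \code{cg}, residual variances
#' \code{ve1, ve2} and covariance \code{ce} (the latter only identified from
#' individuals with both traits; it is fixed at 0 for disjoint samples).
#' Average-information updates with step-halving keep accepted iterations
#' monotone; variances are floored at \code{1e-6 * Vp} and covariances kept
#' inside the positive-definite cone.  The 6x6 sampling covariance of the
#' components comes from the inverse AI matrix at the optimum.
#'
#' @param design a \code{bivariate_design} from [align_bivariate()].
#' @param constrain floor variance components at zero (default TRUE).
#' @param max_iter,tol_ll iteration controls.
#' @return a \code{bivariate_fit}: \code{components} (named vector),
#'   \code{vcov}, per-trait \code{vp}, \code{h2} and their SEs, \code{logL},
#'   sample sizes, PSD indicators for the 2x2 genetic and residual
#'   covariance matrices, \code{converged}, \code{ll_trace}.
#' @export
fit_bivariate <- function(design, constrain = TRUE, max_iter = 100,
                          tol_ll = 1e-6) {
  if (!inherits(design, "bivariate_design")) {
    stop("expected a 'bivariate_design'", call. = FALSE)
  }
  des <- design
  y1 <- des$y[seq_len(des$n1)]
  y2 <- des$y[des$n1 + seq_len(des$n2)]
  vp1 <- var(y1)
  vp2 <- var(y2)
  covp <- if (des$n_overlap >= 2) {
    cov(y1[seq_len(des$n_overlap)], y2[seq_len(des$n_overlap)])
  } else 0
  th <- c(vg1 = vp1 / 2, vg2 = vp2 / 2, cg = covp / 2,
          ve1 = vp1 / 2, ve2 = vp2 / 2, ce = covp / 2)
  if (des$ce_fixed) th["ce"] <- 0
  active <- if (des$ce_fixed) c("vg1", "vg2", "cg", "ve1", "ve2")
            else names(th)
  floor1 <- 1e-6 * vp1
  floor2 <- 1e-6 * vp2
  hit_boundary <- FALSE
  clamp <- function(th) {
    hit <- FALSE
    if (constrain && th["vg1"] < floor1) { th["vg1"] <- floor1; hit <- TRUE }
    if (constrain && th["vg2"] < floor2) { th["vg2"] <- floor2; hit <- TRUE }
    if (th["ve1"] < floor1) { th["ve1"] <- floor1; hit <- TRUE }
    if (th["ve2"] < floor2) { th["ve2"] <- floor2; hit <- TRUE }
    # keep each 2x2 covariance matrix inside the PD cone by a fixed additive
    # margin (a multiplicative margin would let a degenerate pair, e.g. a
    # duplicated trait, drive all components to zero)
    eps <- 1e-5 * sqrt(vp1 * vp2)
    root_g <- sqrt(max(th["vg1"] * th["vg2"], 0))
    cap_g <- max(root_g - eps, 0.9 * root_g)
    if (abs(th["cg"]) > cap_g) { th["cg"] <- sign(th["cg"]) * cap_g
                                 hit <- TRUE }
    root_e <- sqrt(max(th["ve1"] * th["ve2"], 0))
    cap_e <- max(root_e - eps, 0.9 * root_e)
    if (abs(th["ce"]) > cap_e) { th["ce"] <- sign(th["ce"]) * cap_e
                                 hit <- TRUE }
    if (des$ce_fixed) th["ce"] <- 0
    attr(th, "hit") <- hit
    th
  }
  th <- clamp(th)
  ev <- .bv_loglik(th, des)
  if (is.null(ev)) stop("starting covariance matrix not positive definite",
                        call. = FALSE)
  ll_trace <- ev$ll
  converged <- FALSE
  iter <- 0
  X <- des$X
  score_ai <- function(th, ev) {
    Vinv <- chol2inv(ev$cV)
    W <- Vinv %*% X                             # Vinv X, N x p
    B <- crossprod(X, W)
    Py <- as.vector(Vinv %*% des$y - W %*% ev$beta)
    i1 <- seq_len(des$n1)
    i2 <- des$n1 + seq_len(des$n2)
    nov <- des$n_overlap
    trVV <- c(
      vg1 = sum(Vinv[i1, i1] * des$A11),
      vg2 = sum(Vinv[i2, i2] * des$A22),
      cg  = 2 * sum(Vinv[i1, i2] * des$A12),
      ve1 = sum(diag(Vinv)[i1]),
      ve2 = sum(diag(Vinv)[i2]),
      ce  = if (nov > 0)
        2 * sum(Vinv[cbind(seq_len(nov), des$n1 + seq_len(nov))]) else 0
    )
    k <- length(active)
    Tm <- matrix(0, length(des$y), k)
    score <- numeric(k)
    for (j in seq_len(k)) {
      nm <- active[j]
      VkW <- .bv_mulVk(nm, W, des)
      # tr(P V_k) = tr(Vinv V_k) - tr(B^-1 W' V_k W)
      trPVk <- trVV[nm] - sum(diag(solve(B, crossprod(W, VkW))))
      tk <- as.vector(.bv_mulVk(nm, matrix(Py), des))
      Tm[, j] <- tk
      score[j] <- -0.5 * (trPVk - sum(Py * tk))
    }
    PT <- Vinv %*% Tm - W %*% solve(B, crossprod(W, Tm))
    AI <- 0.5 * crossprod(Tm, PT)
    dimnames(AI) <- list(active, active)
    list(score = setNames(score, active), AI = AI)
  }
  sa <- NULL
  stalled <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1
    sa <- score_ai(th, ev)
    # Levenberg-style damping keeps an ascent direction when the AI matrix
    # is (near-)singular, e.g. for degenerate duplicated traits
    lam <- if (rcond(sa$AI) < 1e-10) 1e-6 * mean(diag(sa$AI)) else 0
    repeat {
      delta <- tryCatch(solve(sa$AI + lam * diag(nrow(sa$AI)), sa$score),
                        error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) break
      lam <- max(lam * 10, 1e-8 * mean(diag(sa$AI)))
    }
    step <- if (iter == 1) 0.5 else 1           # damped first step
    repeat {
      cand <- th
      cand[active] <- th[active] + step * delta
      cand <- clamp(cand)
      newev <- .bv_loglik(cand, des)
      if (!is.null(newev) && newev$ll >= ev$ll - 1e-10) break
      step <- step / 2
      if (step < 1e-8) { cand <- th; newev <- ev; stalled <- TRUE; break }
    }
    hit_boundary <- hit_boundary || isTRUE(attr(cand, "hit"))
    dll <- newev$ll - ev$ll
    th <- setNames(as.numeric(cand), names(th))
    ev <- newev
    ll_trace <- c(ll_trace, ev$ll)
    if (dll < tol_ll) { converged <- TRUE; break }
  }

  # When a covariance component sits on its positive-definiteness cap (or the
  # projected AI line search stalled), the optimum lies along the moving
  # boundary, which a projected Newton step cannot track.  A derivative-free
  # polish in a smooth parameterization (log variances, tanh-scaled
  # covariances) walks the boundary instead.
  cap_active <- function(th) {
    eps <- 1e-5 * sqrt(vp1 * vp2)
    rg <- sqrt(max(th["vg1"] * th["vg2"], 0))
    re <- sqrt(max(th["ve1"] * th["ve2"], 0))
    (abs(th["cg"]) >= max(rg - eps, 0.9 * rg) - 1e-12) ||
      (!des$ce_fixed && abs(th["ce"]) >= max(re - eps, 0.9 * re) - 1e-12)
  }
  if (constrain && (stalled || cap_active(th))) {
    to_th <- function(u) {
      thn <- th
      thn["vg1"] <- exp(u[1]); thn["vg2"] <- exp(u[2])
      thn["ve1"] <- exp(u[4]); thn["ve2"] <- exp(u[5])
      eps <- 1e-5 * sqrt(vp1 * vp2)
      rg <- sqrt(thn["vg1"] * thn["vg2"])
      thn["cg"] <- tanh(u[3]) * max(rg - eps, 0.9 * rg)
      re <- sqrt(thn["ve1"] * thn["ve2"])
      thn["ce"] <- if (des$ce_fixed) 0 else tanh(u[6]) * max(re - eps,
                                                             0.9 * re)
      clamp(thn)
    }
    ratio0 <- function(c, v1, v2) {
      r <- c / sqrt(max(v1 * v2, 1e-300))
      atanh(min(max(r / 0.99999, -1 + 1e-10), 1 - 1e-10))
    }
    u0 <- c(log(th["vg1"]), log(th["vg2"]),
            ratio0(th["cg"], th["vg1"], th["vg2"]),
            log(th["ve1"]), log(th["ve2"]),
            if (des$ce_fixed) 0 else ratio0(th["ce"], th["ve1"], th["ve2"]))
    negll <- function(u) {
      e <- .bv_loglik(to_th(u), des)
      if (is.null(e)) 1e10 else -e$ll
    }
    maxit <- if (length(des$y) > 3000) 200 else 800
    # restarting resets the simplex, which matters in the narrow curved
    # valley along the constraint surface
    best <- list(value = Inf, par = u0)
    for (restart in 1:4) {
      opt <- stats::optim(best$par, negll, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-12))
      improved <- best$value - opt$value
      if (opt$value < best$value) best <- opt
      if (restart > 1 && improved < 1e-8) break
      if (length(des$y) > 3000) break
    }
    opt <- best
    if (-opt$value > ev$ll) {
      th <- setNames(as.numeric(to_th(opt$par)), names(th))
      ev <- .bv_loglik(th, des)
      ll_trace <- c(ll_trace, ev$ll)
      converged <- TRUE
      hit_boundary <- TRUE
    }
  }
  sa <- score_ai(th, ev)
  vcov <- matrix(NA_real_, 6, 6,
                 dimnames = list(names(th), names(th)))
  if (rcond(sa$AI) > 1e-12) {
    vcov[active, active] <- solve(sa$AI)
  }
  h2se <- function(vg, ve, sub) {
    vp <- vg + ve
    g <- c(ve, -vg) / vp^2
    sqrt(max(as.numeric(t(g) %*% vcov[sub, sub] %*% g), 0))
  }
  eigG <- eigen(matrix(th[c("vg1", "cg", "cg", "vg2")], 2), symmetric = TRUE,
                only.values = TRUE)$values
  eigE <- eigen(matrix(th[c("ve1", "ce", "ce", "ve2")], 2), symmetric = TRUE,
                only.values = TRUE)$values
  structure(list(
    components = th, vcov = vcov,
    vp1 = unname(th["vg1"] + th["ve1"]), vp2 = unname(th["vg2"] + th["ve2"]),
    h2_1 = unname(th["vg1"] / (th["vg1"] + th["ve1"])),
    h2_2 = unname(th["vg2"] / (th["vg2"] + th["ve2"])),
    se = c(sapply(names(th), function(nm) sqrt(vcov[nm, nm])),
           vp1 = sqrt(sum(vcov[c("vg1", "ve1"), c("vg1", "ve1")])),
           vp2 = sqrt(sum(vcov[c("vg2", "ve2"), c("vg2", "ve2")])),
           h2_1 = h2se(th["vg1"], th["ve1"], c("vg1", "ve1")),
           h2_2 = h2se(th["vg2"], th["ve2"], c("vg2", "ve2"))),
    logL = ev$ll, n1 = des$n1, n2 = des$n2, n_overlap = des$n_overlap,
    psd_G = all(eigG >= -1e-8), psd_E = all(eigE >= -1e-8),
    ce_fixed = des$ce_fixed, constrained = hit_boundary,
    converged = converged, iterations = iter, ll_trace = ll_trace
  ), class = "bivariate_fit")
}

#' Assemble a bivariate fit object from published component estimates
#'
#' Derived statistics ([genetic_correlation()], [residual_correlation()],
#' [mediation_proportion()]) only need the component estimates and,
#' for standard errors, their sampling covariance.  This constructor lets
#' them be applied to estimates printed in a report table.
#'
#' @param vg1,vg2,cg,ve1,ve2,ce component estimates.
#' @param vcov optional 6x6 sampling covariance with dimnames
#'   \code{c("vg1","vg2","cg","ve1","ve2","ce")}.
#' @param n1,n2 optional sample sizes.
#' @return a minimal \code{bivariate_fit}.
#' @export
bivariate_components <- function(vg1, vg2, cg, ve1, ve2, ce, vcov = NULL,
                                 n1 = NA_integer_, n2 = NA_integer_) {
  th <- c(vg1 = vg1, vg2 = vg2, cg = cg, ve1 = ve1, ve2 = ve2, ce = ce)
  if (is.null(vcov)) {
    vcov <- matrix(NA_real_, 6, 6, dimnames = list(names(th), names(th)))
  }
  structure(list(components = th, vcov = vcov,
                 vp1 = vg1 + ve1, vp2 = vg2 + ve2,
                 h2_1 = vg1 / (vg1 + ve1), h2_2 = vg2 / (vg2 + ve2),
                 logL = NA_real_, n1 = n1, n2 = n2, n_overlap = NA_integer_,
                 ce_fixed = FALSE, converged = NA, iterations = NA_integer_),
            class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat("Bivariate GREML fit (AI-REML)\n")
  cat(sprintf("  n1 = %s, n2 = %s, overlap = %s, logL = %s, converged: %s\n",
              x$n1, x$n2, x$n_overlap,
              ifelse(is.na(x$logL), "NA", sprintf("%.4f", x$logL)),
              x$converged))
  th <- x$components
  for (nm in names(th)) {
    se <- if (!is.null(x$se)) x$se[[nm]] else NA_real_
    cat(sprintf("  %-4s %8.4f (SE %s)\n", nm, th[nm],
                ifelse(is.na(se), "NA", sprintf("%.4f", se))))
  }
  invisible(x)
}

new_derived_corr <- function(kind, value, se, constrained, note = "") {
  structure(list(kind = kind, value = value, se = se,
                 constrained = constrained, note = note),
            class = "derived_corr")
}

#' @export
print.derived_corr <- function(x, ...) {
  cat(sprintf("%s correlation: %.4f (SE %s)%s%s\n", x$kind, x$value,
              ifelse(is.na(x$se), "NA", sprintf("%.4f", x$se)),
              if (x$constrained) " [constrained]" else "",
              if (nzchar(x$note)) paste0(" - ", x$note) else ""))
  invisible(x)
}

#' Genetic correlation from a bivariate fit
#'
#' \eqn{r_G = C(G)_{12} / \sqrt{V(G)_1 V(G)_2}}.  With \code{constrain}
#' (the reporting convention for this statistic) the point estimate is
#' clipped into [0, 1] and flagged; the delta-method SE is always computed
#' from the unclipped ratio and reported unclipped.
#'
#' @param fit a \code{bivariate_fit} (fitted or from
#'   [bivariate_components()]).
#' @param constrain clip the estimate into [0, 1] (default TRUE).
#' @return a \code{derived_corr} (kind "genetic").
#' @export
genetic_correlation <- function(fit, constrain = TRUE) {
  th <- fit$components
  if (th["vg1"] <= 0 || th["vg2"] <= 0) {
    stop("genetic variances must be positive for a genetic correlation",
         call. = FALSE)
  }
  raw <- unname(th["cg"] / sqrt(th["vg1"] * th["vg2"]))
  sub <- c("vg1", "vg2", "cg")
  se <- NA_real_
  if (all(is.finite(fit$vcov[sub, sub]))) {
    g <- c(-raw / (2 * th["vg1"]), -raw / (2 * th["vg2"]),
           1 / sqrt(th["vg1"] * th["vg2"]))
    se <- sqrt(max(as.numeric(t(g) %*% fit$vcov[sub, sub] %*% g), 0))
  }
  val <- raw
  clipped <- FALSE
  if (constrain) {
    val <- min(max(raw, 0), 1)
    clipped <- val != raw
  }
  new_derived_corr("genetic", val, se, clipped,
                   if (clipped) sprintf("unconstrained estimate %.4f", raw)
                   else "")
}

#' Residual correlation with the delta-method standard error
#'
#' \eqn{r_E = C(e)_{12} / \sqrt{V(e)_1 V(e)_2}}; its sampling variance is the
#' delta-method expansion in the residual components
#' \deqn{Var(r_E) = r_E^2\Big(\frac{Var V_{e1}}{4V_{e1}^2} +
#'   \frac{Var V_{e2}}{4V_{e2}^2} + \frac{Var C_e}{C_e^2} +
#'   \frac{Cov(V_{e1},V_{e2})}{2V_{e1}V_{e2}} -
#'   \frac{Cov(V_{e1},C_e)}{V_{e1}C_e} -
#'   \frac{Cov(V_{e2},C_e)}{V_{e2}C_e}\Big),}
#' which is singular at \eqn{C_e = 0}; in that case the value 0 is returned
#' with the SE from the general delta method (only the \eqn{C_e} term
#' survives) and a note.
#'
#' @param fit a \code{bivariate_fit}.
#' @return a \code{derived_corr} (kind "residual").
#' @export
residual_correlation <- function(fit) {
  th <- fit$components
  ve1 <- unname(th["ve1"]); ve2 <- unname(th["ve2"]); ce <- unname(th["ce"])
  if (ve1 <= 0 || ve2 <= 0) {
    stop("residual variances must be positive", call. = FALSE)
  }
  re <- ce / sqrt(ve1 * ve2)
  sub <- c("ve1", "ve2", "ce")
  Vc <- fit$vcov[sub, sub]
  se <- NA_real_
  note <- ""
  if (all(is.finite(Vc))) {
    if (ce == 0) {
      se <- sqrt(Vc["ce", "ce"] / (ve1 * ve2))
      note <- "Ce = 0: SE from the general delta method"
    } else {
      v <- re * re * (Vc["ve1", "ve1"] / (4 * ve1 * ve1) +
                      Vc["ve2", "ve2"] / (4 * ve2 * ve2) +
                      Vc["ce", "ce"] / (ce * ce) +
                      Vc["ve1", "ve2"] / (2 * ve1 * ve2) -
                      Vc["ve1", "ce"] / (ve1 * ce) -
                      Vc["ve2", "ce"] / (ve2 * ce))
      se <- sqrt(max(v, 0))
    }
  }
  new_derived_corr("residual", re, se, FALSE, note)
}

#' Phenotypic correlation over the doubly-phenotyped sample
#'
#' Product-moment correlation restricted to individuals with both traits.
#'
#' @param pheno1,pheno2 named numeric vectors (names = ids).
#' @return a \code{derived_corr} (kind "phenotypic"; SE by the Fisher
#'   large-sample approximation \eqn{(1-r^2)/\sqrt{n-3}}).
#' @export
phenotypic_correlation <- function(pheno1, pheno2) {
  p1 <- pheno1[!is.na(pheno1)]
  p2 <- pheno2[!is.na(pheno2)]
  shared <- intersect(names(p1), names(p2))
  n <- length(shared)
  if (n < 3) stop("need at least 3 overlapping individuals", call. = FALSE)
  a <- as.numeric(p1[shared])
  b <- as.numeric(p2[shared])
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance in overlap sample",
                                     call. = FALSE)
  r <- cor(a, b)
  se <- if (n > 3) (1 - r^2) / sqrt(n - 3) else NA_real_
  out <- new_derived_corr("phenotypic", r, se, FALSE,
                          sprintf("n = %d overlap", n))
  out$n <- n
  out
}

#' Percentage of a phenotypic correlation mediated genetically
#'
#' On standardized traits the genetic contribution to the phenotypic
#' correlation is the genetic covariance itself, so the genetically mediated
#' share is \eqn{C(G)_{12} / r_p}.  The traits are asserted to be on the
#' correlation scale (both Vp within 10% of 1); otherwise \eqn{C(G)} is
#' rescaled by \eqn{\sqrt{V_{p1} V_{p2}}}.  Sampling noise can push the share
#' beyond 100%; values outside [0, 110%] raise a warning, never a silent
#' clip.
#'
#' @param fit a \code{bivariate_fit}.
#' @param phenotypic_correlation the phenotypic correlation (number or a
#'   \code{derived_corr}).
#' @return the mediated share in percent, with the scaled genetic covariance
#'   as attribute \code{"cg_scaled"}.
#' @export
mediation_proportion <- function(fit, phenotypic_correlation) {
  rp <- if (inherits(phenotypic_correlation, "derived_corr")) {
    phenotypic_correlation$value
  } else {
    as.numeric(phenotypic_correlation)
  }
  if (rp == 0) stop("phenotypic correlation must be non-zero", call. = FALSE)
  cg <- unname(fit$components["cg"])
  if (abs(fit$vp1 - 1) > 0.1 || abs(fit$vp2 - 1) > 0.1) {
    cg <- cg / sqrt(fit$vp1 * fit$vp2)
  }
  pct <- 100 * cg / rp
  if (pct < 0 || pct > 110) {
    warning(sprintf("mediated share %.1f%% outside [0%%, 110%%]; ",
                    pct), "interpret with care", call. = FALSE)
  }
  structure(pct, cg_scaled = cg)
}

#' Write a bivariate fit as a report table
#'
#' One row per quantity with estimate and SE, mirroring the usual bivariate
#' GREML report: genetic and residual (co)variances, per-trait Vp and
#' heritability, the derived genetic and residual correlations, and sample
#' sizes.
#'
#' @param fit a \code{bivariate_fit}.
#' @param path output file (tab-delimited).
#' @return the path, invisibly.
#' @export
write_bivar_report <- function(fit, path) {
  rg <- genetic_correlation(fit)
  re <- residual_correlation(fit)
  th <- fit$components
  rows <- rbind(
    data.frame(Source = c("V(G)_tr1", "V(G)_tr2", "C(G)_tr12", "V(e)_tr1",
                          "V(e)_tr2", "C(e)_tr12"),
               Estimate = as.numeric(th[c("vg1", "vg2", "cg", "ve1", "ve2",
                                          "ce")]),
               SE = as.numeric(fit$se[c("vg1", "vg2", "cg", "ve1", "ve2",
                                        "ce")])),
    data.frame(Source = c("Vp_tr1", "Vp_tr2", "V(G)/Vp_tr1", "V(G)/Vp_tr2",
                          "r_G", "r_E"),
               Estimate = c(fit$vp1, fit$vp2, fit$h2_1, fit$h2_2, rg$value,
                            re$value),
               SE = c(fit$se[["vp1"]], fit$se[["vp2"]], fit$se[["h2_1"]],
                      fit$se[["h2_2"]], rg$se, re$se)),
    data.frame(Source = c("n_tr1", "n_tr2", "n_overlap"),
               Estimate = c(fit$n1, fit$n2, fit$n_overlap), SE = NA)
  )
  write.table(format(rows, digits = 6), path, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(path)
}
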