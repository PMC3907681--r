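#' REML log-likelihood of the single-GRM mixed model
#'
#' Evaluates \deqn{\ell = -\tfrac12\left(\log|V| + \log|X^\top V^{-1}X| +
#' y^\top P y\right), \qquad V = \sigma^2_g A + \sigma^2_e I,}
#' with \eqn{P} the REML projection.  The additive constant
#' \eqn{-(n-p)/2\,\log 2\pi} is omitted (the convention GREML reports use);
#' likelihood differences and ratio tests are unaffected.  This dense direct
#' evaluation is exposed so grid searches can audit the optimizer.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (full column rank; pass a one-column
#'   matrix of ones for an intercept-only model).
#' @param A symmetric positive semidefinite relatedness matrix.
#' @param vg,ve genetic and residual variance components (\code{vg >= 0},
#'   \code{ve > 0}).
#' @return the REML log-likelihood (scalar).
#' @export
reml_loglik <- function(y, X, A, vg, ve) {
  n <- length(y)
  X <- as.matrix(X)
  if (vg < 0 || ve <= 0) stop("need vg >= 0 and ve > 0", call. = FALSE)
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-8))) {
    stop("A must be symmetric", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) stop("X must have full column rank",
                                 call. = FALSE)
  V <- vg * A + diag(ve, n)
  cV <- tryCatch(chol(V), error = function(e) stop("singular V",
                                                   call. = FALSE))
  logdetV <- 2 * sum(log(diag(cV)))
  Vinv_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vinv_X <- backsolve(cV, forwardsolve(t(cV), X))
  B <- crossprod(X, Vinv_X)
  cB <- chol(B)
  logdetB <- 2 * sum(log(diag(cB)))
  Xty <- crossprod(X, Vinv_y)
  beta <- backsolve(cB, forwardsolve(t(cB), Xty))
  yPy <- sum(y * Vinv_y) - sum(Xty * beta)
  -0.5 * (logdetV + logdetB + yPy)
}

# rotated-basis machinery: with A = U D U', transform once and every REML
# iteration is O(n p^2) instead of O(n^3)
.rot_loglik_parts <- function(vg, ve, d, yt, Xt) {
  w <- vg * d + ve
  if (any(w <= 0)) return(NULL)
  wi <- 1 / w
  Xw <- Xt * wi
  B <- crossprod(Xt, Xw)
  cB <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(cB)) return(NULL)
  rhs <- crossprod(Xt, wi * yt)
  beta <- backsolve(cB, forwardsolve(t(cB), rhs))
  r <- wi * (yt - as.vector(Xt %*% beta))      # = rotated P y
  yPy <- sum(yt * r)
  ll <- -0.5 * (sum(log(w)) + 2 * sum(log(diag(cB))) + yPy)
  list(ll = ll, w = w, wi = wi, r = r, beta = beta, cB = cB, Xw = Xw)
}

.rot_applyP <- function(t, parts, Xt) {
  wt <- parts$wi * t
  wt - parts$Xw %*% backsolve(parts$cB, forwardsolve(t(parts$cB),
                                                     crossprod(Xt, wt)))
}

.rot_score_ai <- function(parts, d, Xt) {
  wi <- parts$wi
  r <- parts$r
  # tr(P A) and tr(P I), A diagonal d in the rotated basis
  Binv_f <- function(M) backsolve(parts$cB, forwardsolve(t(parts$cB), M))
  M1 <- crossprod(Xt, (d * wi^2) * Xt)
  M2 <- crossprod(Xt, wi^2 * Xt)
  trPA <- sum(d * wi) - sum(diag(Binv_f(M1)))
  trP <- sum(wi) - sum(diag(Binv_f(M2)))
  t1 <- d * r
  yPAPy <- sum(r * t1)
  yPPy <- sum(r * r)
  score <- -0.5 * c(trPA - yPAPy, trP - yPPy)
  Pt1 <- .rot_applyP(t1, parts, Xt)
  Pt2 <- .rot_applyP(r, parts, Xt)
  AI <- 0.5 * matrix(c(sum(t1 * Pt1), sum(t1 * Pt2),
                       sum(t1 * Pt2), sum(r * Pt2)), 2, 2)
  list(score = score, AI = AI, trPA = trPA, trP = trP,
       yPAPy = yPAPy, yPPy = yPPy)
}

#' Univariate GREML fit by AI-REML
#'
#' Estimates the genetic and residual variance components of a single trait
#' from a GRM over conventionally unrelated individuals.  The GRM is
#' eigendecomposed once; iterations then run in the rotated basis.  The first
#' update is an EM step, subsequent updates are average-information steps
#' with step-halving whenever the log-likelihood would decrease, so accepted
#' iterations are monotone.  Components are constrained non-negative by
#' projection to \code{1e-6 * Vp} (GREML practice) unless
#' \code{constrain = FALSE}.  Standard errors come from the inverse AI matrix
#' at the optimum, the heritability SE by the delta method.
#'
#' @param y named numeric phenotype vector (names = individual ids; NAs are
#'   dropped).  Unnamed vectors must match the GRM ids in order.
#' @param grm a \code{grm} object (already relatedness-pruned).
#' @param covariates optional numeric matrix/data.frame of fixed covariates
#'   (e.g. ancestry PCs) with row names as ids; an intercept is always added.
#' @param constrain keep components non-negative (default TRUE).
#' @param max_iter,tol_ll,tol_par iteration controls: stop when the
#'   log-likelihood improves by less than \code{tol_ll} (1e-6) or components
#'   move less than \code{tol_par} (1e-8).
#' @param eig optional precomputed \code{eigen()} of the aligned GRM (an
#'   optimization for repeated fits on the same sample).
#' @return a \code{univariate_fit}: components \code{vg}, \code{ve},
#'   \code{vp}, ratio \code{h2}, standard errors \code{se}, 2x2 sampling
#'   covariance \code{vcov}, \code{logL}, fixed effects \code{beta},
#'   \code{n}, \code{iterations}, \code{converged}, \code{identifiable},
#'   \code{constrained}, log-likelihood trace \code{ll_trace}, \code{ids}.
#' @export
fit_univariate <- function(y, grm, covariates = NULL, constrain = TRUE,
                           max_iter = 100, tol_ll = 1e-6, tol_par = 1e-8,
                           eig = NULL) {
  if (!inherits(grm, "grm")) stop("expected a 'grm' object", call. = FALSE)
  if (is.null(names(y))) {
    if (length(y) != length(grm$ids)) {
      stop("unnamed y must match the GRM dimension", call. = FALSE)
    }
    names(y) <- grm$ids
  }
  if (!all(names(y) %in% grm$ids)) {
    stop("phenotype ids absent from the GRM: ",
         paste(head(setdiff(names(y), grm$ids)), collapse = ", "),
         call. = FALSE)
  }
  y <- y[!is.na(y)]
  ids <- grm$ids[grm$ids %in% names(y)]         # GRM order
  yv <- as.numeric(y[ids])
  n <- length(yv)
  X <- matrix(1, n, 1, dimnames = list(ids, "intercept"))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (is.null(rownames(C))) {
      if (nrow(C) != n) stop("covariates without row names must match y",
                             call. = FALSE)
      rownames(C) <- ids
    }
    if (!all(ids %in% rownames(C))) {
      stop("covariates missing for some phenotyped ids", call. = FALSE)
    }
    X <- cbind(X, C[ids, , drop = FALSE])
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariates", call. = FALSE)

  if (is.null(eig)) {
    A <- grm$A[ids, ids]
    eig <- eigen(A, symmetric = TRUE)
  } else if (length(eig$values) != n) {
    stop("precomputed eigendecomposition does not match the sample",
         call. = FALSE)
  }
  d <- eig$values
  yt <- as.vector(crossprod(eig$vectors, yv))
  Xt <- crossprod(eig$vectors, X)

  vp <- var(yv)
  floor_v <- 1e-6 * vp
  theta <- c(vg = vp / 2, ve = vp / 2)
  clamp <- function(th) {
    hit <- FALSE
    if (constrain && th[1] < floor_v) { th[1] <- floor_v; hit <- TRUE }
    if (th[2] < floor_v) { th[2] <- floor_v; hit <- TRUE }
    attr(th, "hit") <- hit
    th
  }
  parts <- .rot_loglik_parts(theta[1], theta[2], d, yt, Xt)
  ll_trace <- parts$ll
  converged <- FALSE
  identifiable <- TRUE
  hit_boundary <- FALSE
  sa <- NULL
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    sa <- .rot_score_ai(parts, d, Xt)
    if (rcond(sa$AI) < 1e-10) {
      identifiable <- FALSE
      break
    }
    delta <- if (iter == 1) {
      c(theta[1]^2 * (sa$yPAPy - sa$trPA) / n,    # EM first step
        theta[2]^2 * (sa$yPPy - sa$trP) / n)
    } else {
      solve(sa$AI, sa$score)
    }
    step <- 1
    repeat {
      cand <- clamp(theta + step * delta)
      newparts <- .rot_loglik_parts(cand[1], cand[2], d, yt, Xt)
      if (!is.null(newparts) && newparts$ll >= parts$ll - 1e-10) break
      step <- step / 2
      if (step < 1e-8) {                        # no uphill step found
        cand <- theta
        newparts <- parts
        break
      }
    }
    hit_boundary <- hit_boundary || isTRUE(attr(cand, "hit"))
    dll <- newparts$ll - parts$ll
    dpar <- max(abs(cand - theta))
    theta <- c(vg = unname(cand[1]), ve = unname(cand[2]))
    parts <- newparts
    ll_trace <- c(ll_trace, parts$ll)
    if (dll < tol_ll || dpar < tol_par) {
      converged <- TRUE
      break
    }
  }
  sa <- .rot_score_ai(parts, d, Xt)
  vcov <- if (identifiable && rcond(sa$AI) > 1e-12) solve(sa$AI)
          else matrix(NA_real_, 2, 2)
  dimnames(vcov) <- list(c("vg", "ve"), c("vg", "ve"))
  vp_hat <- sum(theta)
  h2 <- theta[1] / vp_hat
  g <- c(theta[2], -theta[1]) / vp_hat^2        # d h2 / d(vg, ve)
  se <- c(vg = sqrt(vcov[1, 1]), ve = sqrt(vcov[2, 2]),
          vp = sqrt(sum(vcov)),
          h2 = sqrt(max(as.numeric(t(g) %*% vcov %*% g), 0)))
  beta <- setNames(as.vector(parts$beta), colnames(X))
  structure(list(
    vg = unname(theta[1]), ve = unname(theta[2]), vp = vp_hat,
    h2 = unname(h2), se = se, vcov = vcov, logL = parts$ll, beta = beta,
    n = n, iterations = iter, converged = converged && identifiable,
    identifiable = identifiable, constrained = hit_boundary,
    ll_trace = ll_trace, ids = ids
  ), class = "univariate_fit")
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat("Univariate GREML fit (AI-REML)\n")
  cat(sprintf("  n = %d, logL = %.4f, %d iterations, converged: %s\n",
              x$n, x$logL, x$iterations, x$converged))
  est <- c(x$vg, x$ve, x$vp, x$h2)
  lab <- c("V(G)", "V(e)", "Vp", "V(G)/Vp")
  for (i in 1:4) {
    cat(sprintf("  %-8s %8.4f (SE %.4f)\n", lab[i], est[i], x$se[i]))
  }
  if (!x$identifiable) cat("  WARNING: model not identifiable (AI singular)\n")
  invisible(x)
}

#' Null model: no genetic component
#'
#' REML fit of intercept plus covariates with i.i.d. residuals; the
#' log-likelihood uses the same constant convention as [reml_loglik()], so it
#' is directly comparable with the genetic model for the ratio test.
#'
#' @param y named numeric phenotype vector (NAs dropped).
#' @param covariates optional matrix/data.frame with row names as ids.
#' @return a \code{null_fit}: \code{ve}, \code{logL}, \code{beta}, \code{n}.
#' @export
fit_null <- function(y, covariates = NULL) {
  y <- y[!is.na(y)]
  n <- length(y)
  X <- matrix(1, n, 1, dimnames = list(names(y), "intercept"))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (!is.null(rownames(C)) && !is.null(names(y))) {
      if (!all(names(y) %in% rownames(C))) {
        stop("covariates missing for some phenotyped ids", call. = FALSE)
      }
      C <- C[names(y), , drop = FALSE]
    }
    X <- cbind(X, C)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient covariates", call. = FALSE)
  fit <- lm.fit(X, as.numeric(y))
  rss <- sum(fit$residuals^2)
  ve <- rss / (n - p)
  logdetXtX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  logL <- -0.5 * ((n - p) * log(ve) + logdetXtX + (n - p))
  structure(list(ve = ve, logL = logL,
                 beta = setNames(fit$coefficients, colnames(X)), n = n),
            class = "null_fit")
}

#' Boundary likelihood-ratio test of the genetic variance component
#'
#' \eqn{LRT = 2(\log L - \log L_0)}, clamped at zero; because the null pins
#' the variance component to the boundary of its parameter space, the null
#' distribution is the mixture \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1} and
#' the p-value is half the \eqn{\chi^2_1} tail (equal to 0.5 when LRT = 0).
#'
#' @param fit a \code{univariate_fit}, or the model log-likelihood as a
#'   number.
#' @param null a \code{null_fit}, or the null log-likelihood as a number.
#' @return an \code{lrt_result}: \code{lrt}, \code{df} (1), \code{p},
#'   \code{n} (NA when raw log-likelihoods were supplied).
#' @export
lrt <- function(fit, null) {
  logL <- if (inherits(fit, "univariate_fit")) fit$logL else as.numeric(fit)
  logL0 <- if (inherits(null, "null_fit")) null$logL else as.numeric(null)
  n <- NA_integer_
  if (inherits(fit, "univariate_fit") && inherits(null, "null_fit")) {
    if (fit$n != null$n) stop("fit and null use different samples",
                              call. = FALSE)
    n <- fit$n
  }
  stat <- max(0, 2 * (logL - logL0))
  p <- 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(lrt = stat, df = 1L, p = p, n = n), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT = %.2f, df = %d, p = %.3g (half-chi-square boundary test)",
              x$lrt, x$df, x$p))
  if (!is.na(x$n)) cat(sprintf(", n = %d", x$n))
  cat("\n")
  invisible(x)
}

#' Write a univariate fit as an hsq-style report
#'
#' Mirrors the GCTA \code{.hsq} layout: estimate/SE rows for V(G), V(e), Vp
#' and V(G)/Vp, then logL, logL0, LRT, df, Pval and n.
#'
#' @param fit a \code{univariate_fit}.
#' @param null a \code{null_fit} on the same sample.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_hsq <- function(fit, null, path) {
  lr <- lrt(fit, null)
  lines <- c(
    "Source\tVariance\tSE",
    sprintf("V(G)\t%.6f\t%.6f", fit$vg, fit$se["vg"]),
    sprintf("V(e)\t%.6f\t%.6f", fit$ve, fit$se["ve"]),
    sprintf("Vp\t%.6f\t%.6f", fit$vp, fit$se["vp"]),
    sprintf("V(G)/Vp\t%.6f\t%.6f", fit$h2, fit$se["h2"]),
    sprintf("logL\t%.4f", fit$logL),
    sprintf("logL0\t%.4f", null$logL),
    sprintf("LRT\t%.4f", lr$lrt),
    sprintf("df\t%d", lr$df),
    sprintf("Pval\t%.4g", lr$p),
    sprintf("n\t%d", fit$n)
  )
  writeLines(lines, path)
  invisible(path)
}
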