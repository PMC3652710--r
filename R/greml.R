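# Internal: rotated representation of the single-GRM mixed model.
# With A = U D U', V = sigma2_g A + sigma2_e I is diagonal after rotating
# y and X by U', making every REML quantity O(n p^2) per evaluation.
rotate_model <- function(A, y, X) {
  eg <- eigen(A, symmetric = TRUE)
  list(d = eg$values, yt = crossprod(eg$vectors, y),
       Xt = crossprod(eg$vectors, X), n = length(y), p = ncol(X))
}

# Internal: REML quantities at (sg, se) from a rotated model.
# Returns loglik, gradient, AI matrix, Py and traces.
reml_parts <- function(rot, sg, se) {
  w <- sg * rot$d + se
  if (any(w <= 1e-12)) return(NULL)  # V not positive definite here
  Vi <- 1 / w
  Xt <- rot$Xt; yt <- rot$yt
  ViX <- Xt * Vi
  M <- crossprod(Xt, ViX)                     # X'V^-1X (p x p)
  Mi <- solve(M)
  Viy <- Vi * yt
  beta <- Mi %*% crossprod(Xt, Viy)
  Py <- drop(Viy - ViX %*% beta)
  Pv <- function(v) {                         # apply P to a vector
    Viv <- Vi * v
    drop(Viv - ViX %*% (Mi %*% crossprod(Xt, Viv)))
  }
  yPy <- sum(yt * Py)
  ld_V <- sum(log(w))
  ld_M <- determinant(M, logarithm = TRUE)$modulus[1]
  ll <- -0.5 * ((rot$n - rot$p) * log(2 * pi) + ld_V + ld_M + yPy)
  # tr(P A) and tr(P I) with A diagonal (d) in the rotated basis
  tr_P_diag <- function(d) {
    T1 <- sum(d * Vi)
    W <- crossprod(Xt, Xt * (Vi^2 * d))       # X'V^-1 D V^-1 X
    T1 - sum(diag(Mi %*% W))
  }
  trPA <- tr_P_diag(rot$d)
  trPI <- tr_P_diag(rep(1, rot$n))
  APy <- rot$d * Py
  PAPy <- Pv(APy); PPy <- Pv(Py)
  grad <- c(g = -0.5 * (trPA - sum(Py * APy)),
            e = -0.5 * (trPI - sum(Py * Py)))
  AI <- 0.5 * matrix(c(sum(APy * PAPy), sum(APy * PPy),
                       sum(APy * PPy), sum(Py * PPy)), 2, 2)
  list(ll = ll, grad = grad, AI = AI, yPAPy = sum(Py * APy),
       yPPy = sum(Py * Py), trPA = trPA, trPI = trPI)
}

#' Restricted log-likelihood of the single-GRM model
#'
#' Evaluates the restricted (residual) log-likelihood of
#' `y ~ N(X beta, sigma2_g A + sigma2_e I)`, profiled over the fixed
#' effects:
#' `-0.5 * [(n - p) log(2 pi) + log|V| + log|X'V^-1 X| + y'Py]`.
#'
#' @param sigma2_g,sigma2_e genetic and residual variance components.
#' @param grm a [grm()] object.
#' @param y numeric phenotype vector aligned with the GRM.
#' @param X fixed-effect design matrix (default intercept only).
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(sigma2_g, sigma2_e, grm, y, X = NULL) {
  stopifnot(inherits(grm, "grm"))
  n <- length(y)
  if (n != nrow(grm$A)) stop_param("phenotype length must match the GRM")
  if (is.null(X)) X <- matrix(1, n, 1)
  rot <- rotate_model(grm$A, y, X)
  parts <- reml_parts(rot, sigma2_g, sigma2_e)
  if (is.null(parts)) stop_param("V not positive definite at this point")
  parts$ll
}

#' Fit the GREML variance-component model
#'
#' Estimates the variance captured by the SNPs behind a genetic
#' relationship matrix by restricted maximum likelihood under
#' `y ~ N(X beta, sigma2_g A + sigma2_e I)`. Starts from
#' `sigma2_g = sigma2_e = var(y)/2`, takes one EM step, then
#' average-information (AI) updates; if the AI matrix is singular or an AI
#' step would decrease the likelihood, the iteration falls back to an EM
#' step (whose likelihood never decreases). Components that go negative
#' are bent to `1e-6 * var(y)`. The standard error of
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)` comes from the inverse AI
#' matrix via the delta method; the 95% CI is Wald, truncated to [0, 1].
#'
#' @param grm a [grm()] object.
#' @param phen phenotype: numeric vector aligned with the GRM, or a
#'   data.frame with `fid`, `iid`, `phenotype` (matched to the GRM ids;
#'   individuals absent from either side are dropped).
#' @param covariates optional numeric design matrix of fixed effects; an
#'   intercept column is always included.
#' @param algorithm `"ai"` (default) or `"em"` (EM steps only).
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-8; parameter changes below 1e-8 also stop).
#' @param max_iter iteration cap (default 100); hitting it flags
#'   `converged = FALSE` rather than raising an error.
#' @return an object of class `greml_fit`: `sigma2_g`, `sigma2_e`,
#'   `h2_snp`, `se_h2`, `ci95`, `loglik`, `n_iter`, `converged`, `n`,
#'   plus the variance-component covariance matrix `vcov`.
#' @export
fit_greml <- function(grm, phen, covariates = NULL,
                      algorithm = c("ai", "em"), tol = 1e-8,
                      max_iter = 100L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(grm, "grm"))
  if (is.data.frame(phen)) {
    key_g <- paste(grm$fid, grm$iid, sep = "\r")
    key_p <- paste(phen$fid, phen$iid, sep = "\r")
    ok <- !is.na(phen$phenotype)
    common <- intersect(key_g, key_p[ok])
    rows_g <- match(common, key_g)
    y <- phen$phenotype[match(common, key_p)]
    G <- subset_grm(grm, rows_g)
  } else {
    y <- as.numeric(phen)
    if (anyNA(y)) {
      keep <- !is.na(y)
      y <- y[keep]; G <- subset_grm(grm, which(keep))
    } else G <- grm
  }
  n <- length(y)
  if (n < 30) stop_param("need at least 30 phenotyped individuals")
  vy <- stats::var(y)
  if (vy <= 0) stop_param("phenotype variance must be positive")
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  rot <- rotate_model(G$A, y, X)
  floor_v <- 1e-6 * vy
  bend <- function(th) pmax(th, floor_v)

  th <- c(vy / 2, vy / 2)
  parts <- reml_parts(rot, th[1], th[2])
  em_step <- function(th, parts) {
    bend(c(th[1] + th[1]^2 * (parts$yPAPy - parts$trPA) / n,
           th[2] + th[2]^2 * (parts$yPPy - parts$trPI) / n))
  }
  # one EM step from the variance-halving start
  th_new <- em_step(th, parts)
  parts_new <- reml_parts(rot, th_new[1], th_new[2])
  if (!is.null(parts_new)) { th <- th_new; parts <- parts_new }
  converged <- FALSE
  iter <- 1L
  trace <- parts$ll
  while (iter < max_iter) {
    iter <- iter + 1L
    step_ok <- FALSE
    if (algorithm == "ai") {
      AIi <- tryCatch(solve(parts$AI), error = function(e) NULL)
      if (!is.null(AIi)) {
        cand <- bend(th + drop(AIi %*% parts$grad))
        parts_c <- reml_parts(rot, cand[1], cand[2])
        if (!is.null(parts_c) && parts_c$ll >= parts$ll - 1e-10) {
          step_ok <- TRUE
        }
      }
    }
    if (!step_ok) {  # EM safeguard (or algorithm = "em")
      cand <- em_step(th, parts)
      parts_c <- reml_parts(rot, cand[1], cand[2])
      if (is.null(parts_c)) break
    }
    d_ll <- parts_c$ll - parts$ll
    d_th <- max(abs(cand - th))
    th <- cand; parts <- parts_c
    trace <- c(trace, parts$ll)
    if (abs(d_ll) < tol || d_th < 1e-8) { converged <- TRUE; break }
  }
  h2 <- th[1] / sum(th)
  vc <- tryCatch(solve(parts$AI), error = function(e) matrix(NA_real_, 2, 2))
  gr <- c(th[2], -th[1]) / sum(th)^2
  se_h2 <- sqrt(max(0, drop(t(gr) %*% vc %*% gr)))
  ci <- c(max(0, h2 - 1.96 * se_h2), min(1, h2 + 1.96 * se_h2))
  structure(list(sigma2_g = th[1], sigma2_e = th[2], h2_snp = h2,
                 se_h2 = se_h2, ci95 = ci, loglik = parts$ll,
                 n_iter = iter, converged = converged, n = n, vcov = vc,
                 trace = trace),
            class = "greml_fit")
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf(
    paste0("GREML fit (n = %d)%s\n",
           "  sigma2_g = %.4f, sigma2_e = %.4f\n",
           "  h2_snp = %.3f (se %.3f), 95%% CI [%.2f, %.2f]\n",
           "  restricted logLik = %.3f after %d iterations\n"),
    x$n, if (x$converged) "" else "  [NOT CONVERGED]",
    x$sigma2_g, x$sigma2_e, x$h2_snp, x$se_h2, x$ci95[1], x$ci95[2],
    x$loglik, x$n_iter))
  invisible(x)
}

#' SNP-heritability pipeline
#'
#' Convenience wrapper running GRM construction (unless a `grm` is given),
#' greedy relatedness filtering, and [fit_greml()], with a short log of
#' each stage.
#'
#' @param geno a [genotype_matrix()] (ignored when `grm` is supplied).
#' @param phen phenotype data.frame (`fid`, `iid`, `phenotype`) or vector.
#' @param grm optional precomputed [grm()].
#' @param cutoff relatedness cutoff passed to [filter_related()].
#' @param ... further arguments passed to [fit_greml()].
#' @return a `greml_fit` with attribute `log` (character vector of stage
#'   messages).
#' @export
estimate_h2_snp <- function(geno = NULL, phen, grm = NULL, cutoff = 0.025,
                            ...) {
  log <- character(0)
  if (is.null(grm)) {
    if (is.null(geno)) stop_param("supply genotypes or a GRM")
    grm <- compute_grm(geno)
    log <- c(log, sprintf("GRM: %d individuals, %d SNPs used",
                          nrow(grm$A), grm$m_used))
  }
  fl <- filter_related(grm, cutoff = cutoff)
  log <- c(log, sprintf("relatedness filter (cutoff %.3f): removed %d of %d",
                        cutoff, nrow(grm$A) - length(fl$keep), nrow(grm$A)))
  grm_f <- subset_grm(grm, fl$keep)
  fit <- fit_greml(grm_f, phen, ...)
  log <- c(log, sprintf("GREML: h2_snp = %.3f (se %.3f), converged = %s",
                        fit$h2_snp, fit$se_h2, fit$converged))
  attr(fit, "log") <- log
  fit
}
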