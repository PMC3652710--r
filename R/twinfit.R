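# Internal: per-zygosity sufficient statistics of the ordered twin pairs
# (n, mean vector, MLE covariance). The ACE likelihood depends on the data
# only through swap-invariant combinations of these, so estimates are
# exactly invariant to relabelling twin 1 / twin 2.
twin_suffstats <- function(cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  out <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    d <- cohort$pairs[cohort$pairs$zygosity == z, c("trait1", "trait2")]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    n <- nrow(d)
    if (n < 2) stop_param("need at least 2 complete pairs per zygosity")
    mu <- colMeans(d)
    S <- crossprod(sweep(as.matrix(d), 2, mu)) / n
    list(n = n, mean = as.numeric(mu), S = S)
  })
  out
}

# Internal: Gaussian log-likelihood of ordered pairs from sufficient stats
# under a 2x2 covariance with common variance v and covariance c_z.
ll_pairs <- function(st, mu, v, cv) {
  det2 <- v^2 - cv^2
  if (det2 <= 0 || v <= 0) return(-Inf)
  # inverse of [[v, cv], [cv, v]]
  a <- v / det2; b <- -cv / det2
  d1 <- st$mean[1] - mu; d2 <- st$mean[2] - mu
  quad_mean <- a * (d1^2 + d2^2) + 2 * b * d1 * d2
  tr <- a * (st$S[1, 1] + st$S[2, 2]) + 2 * b * st$S[1, 2]
  -st$n * (log(2 * pi) + 0.5 * log(det2) + 0.5 * (tr + quad_mean))
}

ace_loglik_stats <- function(stats, mu, vtot, a2, c2) {
  ll_pairs(stats$MZ, mu, vtot, vtot * (a2 + c2)) +
    ll_pairs(stats$DZ, mu, vtot, vtot * (a2 / 2 + c2))
}

#' Twin intraclass correlations
#'
#' Double-entry Pearson correlation per zygosity group: each pair enters
#' twice, once in each order, which is the intraclass estimator used to
#' compare the phenotypic similarity of MZ and DZ pairs.
#'
#' @param cohort a `twin_cohort` (at least 2 complete pairs per zygosity).
#' @return list with `r_mz`, `r_dz` and per-group pair counts `n_mz`,
#'   `n_dz`.
#' @export
twin_correlations <- function(cohort) {
  st <- twin_suffstats(cohort)
  icc <- function(s) {
    # double entry: mean and variance pool the two columns
    mu <- mean(s$mean)
    v <- (s$S[1, 1] + s$S[2, 2]) / 2 +
      (s$mean[1] - mu)^2 / 2 + (s$mean[2] - mu)^2 / 2
    cv <- s$S[1, 2] + (s$mean[1] - mu) * (s$mean[2] - mu)
    cv / v
  }
  list(r_mz = icc(st$MZ), r_dz = icc(st$DZ),
       n_mz = st$MZ$n, n_dz = st$DZ$n)
}

#' Falconer decomposition of twin correlations
#'
#' Moment estimator built on the genetic similarities of roughly 1.00 for
#' MZ and .50 for DZ pairs: `a2 = 2 (r_mz - r_dz)`, `c2 = 2 r_dz - r_mz`,
#' `e2 = 1 - r_mz`. Raw values are preserved; the reported components are
#' clipped to [0, 1] and renormalised to sum to 1 (with a message when
#' clipping bites). When group sizes are supplied, delta-method standard
#' errors and Wald CIs are attached.
#'
#' @param r_mz,r_dz twin correlations in `[-1, 1]`.
#' @param n_mz,n_dz optional pair counts for standard errors.
#' @return an object of class `ace_fit` with `a2`, `c2`, `e2`, `raw`
#'   (unclipped values), `r_mz`, `r_dz`, `method = "falconer"`, and `se`
#'   / `ci95` when counts are given.
#' @export
#' @examples
#' falconer(0.46, 0.23)  # fully additive reading of r_dz = r_mz / 2
falconer <- function(r_mz, r_dz, n_mz = NULL, n_dz = NULL) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1) {
    stop_param("correlations must lie in [-1, 1]")
  }
  raw <- c(a2 = 2 * (r_mz - r_dz), c2 = 2 * r_dz - r_mz, e2 = 1 - r_mz)
  comp <- pmin(pmax(raw, 0), 1)
  if (any(comp != raw)) {
    message("falconer: components clipped to [0, 1] and renormalised")
  }
  comp <- comp / sum(comp)
  se <- ci <- NULL
  if (!is.null(n_mz) && !is.null(n_dz)) {
    # var of a correlation ~ (1 - r^2)^2 / n; components are linear in r
    v_mz <- (1 - r_mz^2)^2 / n_mz
    v_dz <- (1 - r_dz^2)^2 / n_dz
    se <- c(a2 = sqrt(4 * v_mz + 4 * v_dz),
            c2 = sqrt(v_mz + 4 * v_dz),
            e2 = sqrt(v_mz))
    ci <- rbind(a2 = comp["a2"] + c(-1.96, 1.96) * se["a2"],
                c2 = comp["c2"] + c(-1.96, 1.96) * se["c2"],
                e2 = comp["e2"] + c(-1.96, 1.96) * se["e2"])
    ci <- pmin(pmax(ci, 0), 1)
  }
  structure(list(a2 = unname(comp["a2"]), c2 = unname(comp["c2"]),
                 e2 = unname(comp["e2"]), raw = raw, r_mz = r_mz,
                 r_dz = r_dz, se = se, ci95 = ci, method = "falconer",
                 loglik = NA_real_),
            class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("ACE fit (%s): a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$method, x$a2, x$c2, x$e2))
  if (!is.null(x$ci95)) {
    cat(sprintf("  a2 95%% CI [%.2f, %.2f]\n", x$ci95["a2", 1],
                x$ci95["a2", 2]))
  }
  if (is.finite(x$loglik)) cat(sprintf("  logLik = %.3f\n", x$loglik))
  invisible(x)
}

# Internal: profile log-likelihood over (mu, vtot, c2) at fixed a2.
profile_ll_a2 <- function(stats, a2, start) {
  obj <- function(par) {
    -ace_loglik_stats(stats, par[1], exp(par[2]),
                      a2, (1 - a2) * stats::plogis(par[3]))
  }
  op <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 2000))
  -op$value
}

#' Maximum-likelihood ACE model for twin pairs
#'
#' Fits the bivariate-normal twin model with equal means and variances
#' across twin order and zygosity, MZ covariance `a2 + c2` and DZ
#' covariance `a2/2 + c2` (on the scale of the total variance), by
#' maximising the ordered-pair Gaussian likelihood over path coefficients
#' (so all variance components stay non-negative). Confidence intervals for
#' the variance proportions are by profile likelihood (likelihood-ratio
#' threshold 3.84, bisection to 1e-4) or Wald via the numerical Hessian.
#'
#' @param cohort a `twin_cohort` with both zygosities present.
#' @param ci `"profile"` (default) or `"wald"`.
#' @return an object of class `ace_fit` with components `a2`, `c2`, `e2`
#'   (proportions of the fitted total variance `vtot`), `mu`, `se`,
#'   `ci95` (matrix, rows a2/c2/e2), `r_mz`, `r_dz`, `loglik`,
#'   `converged`, `method = "ml"`.
#' @export
fit_ace_ml <- function(cohort, ci = c("profile", "wald")) {
  ci <- match.arg(ci)
  stats <- twin_suffstats(cohort)
  tc <- twin_correlations(cohort)
  # start from the (clipped) Falconer point
  f0 <- suppressMessages(falconer(tc$r_mz, tc$r_dz))
  v0 <- (stats$MZ$n * (stats$MZ$S[1, 1] + stats$MZ$S[2, 2]) +
           stats$DZ$n * (stats$DZ$S[1, 1] + stats$DZ$S[2, 2])) /
    (2 * (stats$MZ$n + stats$DZ$n))
  mu0 <- (stats$MZ$n * mean(stats$MZ$mean) + stats$DZ$n * mean(stats$DZ$mean)) /
    (stats$MZ$n + stats$DZ$n)
  # parameters: mu, log vtot, and path coefficients sqrt(a2), sqrt(c2)
  # relative to vtot; e2 = 1 - a2 - c2 via square-root simplex coords
  obj <- function(par) {
    a <- sin(par[3])^2
    c_ <- (1 - a) * sin(par[4])^2
    -ace_loglik_stats(stats, par[1], exp(par[2]), a, c_)
  }
  start <- c(mu0, log(max(v0, 1e-8)),
             asin(sqrt(min(max(f0$a2, 1e-4), 1 - 1e-4))),
             asin(sqrt(min(max(f0$c2 / max(1 - f0$a2, 1e-4), 1e-4), 1 - 1e-4))))
  op <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 5000))
  op <- stats::optim(op$par, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 5000))
  par <- op$par
  a2 <- sin(par[3])^2
  c2 <- (1 - a2) * sin(par[4])^2
  e2 <- 1 - a2 - c2
  vtot <- exp(par[2])
  llmax <- -op$value
  # Wald machinery on (a2, c2) via numerical Hessian of the
  # unconstrained-proportion parameterisation around the optimum
  nll_prop <- function(q) -ace_loglik_stats(stats, q[1], exp(q[2]), q[3], q[4])
  q_hat <- c(par[1], par[2], a2, c2)
  H <- tryCatch(stats::optimHess(q_hat, nll_prop), error = function(e) NULL)
  se <- c(a2 = NA_real_, c2 = NA_real_, e2 = NA_real_)
  if (!is.null(H)) {
    Vq <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vq)) {
      va <- Vq[3, 3]; vc <- Vq[4, 4]; vac <- Vq[3, 4]
      se <- c(a2 = sqrt(max(va, 0)), c2 = sqrt(max(vc, 0)),
              e2 = sqrt(max(va + vc + 2 * vac, 0)))
    }
  }
  ci95 <- rbind(a2 = pmin(pmax(a2 + c(-1.96, 1.96) * se["a2"], 0), 1),
                c2 = pmin(pmax(c2 + c(-1.96, 1.96) * se["c2"], 0), 1),
                e2 = pmin(pmax(e2 + c(-1.96, 1.96) * se["e2"], 0), 1))
  if (ci == "profile") {
    ci95["a2", ] <- profile_ci_a2(stats, a2, c2, llmax,
                                  c(par[1], par[2]))
  }
  structure(list(a2 = a2, c2 = c2, e2 = e2, mu = par[1], vtot = vtot,
                 se = se, ci95 = ci95, r_mz = tc$r_mz, r_dz = tc$r_dz,
                 loglik = llmax, converged = op$convergence == 0,
                 method = "ml"),
            class = "ace_fit")
}

# Internal: profile-likelihood CI for a2 by bisection on the LRT statistic
# at the chi-square(1) 95% threshold 3.84.
profile_ci_a2 <- function(stats, a2_hat, c2_hat, llmax, muv_start,
                          thresh = 3.84, tol = 1e-4) {
  start3 <- c(muv_start,
              stats::qlogis(min(max(c2_hat / max(1 - a2_hat, 1e-6), 1e-4),
                                1 - 1e-4)))
  lrt <- function(a2) {
    a2 <- min(max(a2, 0), 1 - 1e-10)
    2 * (llmax - profile_ll_a2(stats, a2, start3))
  }
  bisect <- function(lo, hi, increasing) {
    # find a2 with lrt(a2) = thresh between lo and hi
    repeat {
      mid <- (lo + hi) / 2
      if (hi - lo < tol) return(mid)
      up <- lrt(mid) > thresh
      if (up == increasing) hi <- mid else lo <- mid
    }
  }
  lo <- if (lrt(0) <= thresh) 0 else bisect(0, a2_hat, increasing = FALSE)
  hi <- if (lrt(1) <= thresh) 1 else bisect(a2_hat, 1, increasing = TRUE)
  c(lo, hi)
}
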