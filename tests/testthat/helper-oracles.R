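# Independent oracles used by the test-suite. These deliberately avoid the
# package's computational paths: dense linear algebra instead of the
# eigen-rotation used internally, direct enumeration instead of greedy
# heuristics, and closed-form expectations instead of fitted models.

# Dense restricted log-likelihood of y ~ N(X b, sg*A + se*I), the same
# definitional form as reml_loglik but evaluated with solve()/determinant()
# on the full covariance matrix.
dense_reml_loglik <- function(sg, se, A, y, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- ncol(X)
  V <- sg * A + se * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * ((n - p) * log(2 * pi) +
            determinant(V, logarithm = TRUE)$modulus[1] +
            determinant(XtViX, logarithm = TRUE)$modulus[1] +
            drop(t(y) %*% P %*% y))
}

# Grid-search REML maximiser over (sigma2_g, sigma2_e) using the dense
# oracle; returns the arg-max and the grid step.
grid_search_reml <- function(A, y, n_grid = 200) {
  vy <- var(y)
  eg <- eigen(A, symmetric = TRUE)  # base eigen, independent rotation
  yt <- drop(crossprod(eg$vectors, y))
  Xt <- crossprod(eg$vectors, matrix(1, length(y), 1))
  ll <- function(sg, se) {
    w <- sg * eg$values + se
    if (any(w <= 0)) return(-Inf)
    Vi <- 1 / w
    M <- sum(Xt^2 * Vi)
    b <- sum(Xt * Vi * yt) / M
    r <- yt - Xt * b
    -0.5 * ((length(yt) - 1) * log(2 * pi) + sum(log(w)) + log(M) +
              sum(r^2 * Vi))
  }
  step <- 2.5 * vy / n_grid
  grid <- seq(step, 2.5 * vy, by = step)
  best <- c(NA, NA); best_ll <- -Inf
  for (sg in grid) {
    lls <- vapply(grid, function(se) ll(sg, se), numeric(1))
    i <- which.max(lls)
    if (lls[i] > best_ll) { best_ll <- lls[i]; best <- c(sg, grid[i]) }
  }
  list(sigma2_g = best[1], sigma2_e = best[2], loglik = best_ll,
       step = step)
}

# Exhaustive search for the smallest removal sets that leave no pair above
# the cutoff (oracle for the greedy relatedness filter on tiny inputs).
brute_force_unrelated <- function(A, cutoff) {
  n <- nrow(A)
  adj <- A > cutoff; diag(adj) <- FALSE
  best <- list()
  for (size in 0:n) {
    for (rm in combn_list(n, size)) {
      keep <- setdiff(seq_len(n), rm)
      if (!any(adj[keep, keep])) best[[length(best) + 1]] <- keep
    }
    if (length(best)) return(best)  # all maximum retained sets
  }
  best
}

combn_list <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  asplit(utils::combn(n, k), 2)
}

# Build a twin cohort whose per-zygosity sample moments equal the given
# covariance matrices exactly (empirical whitening + recolouring).
cohort_with_exact_moments <- function(n_per_zyg, cov_mz, cov_dz, seed) {
  set.seed(seed)
  make <- function(n, S) {
    X <- matrix(rnorm(2 * n), n, 2)
    X <- sweep(X, 2, colMeans(X))
    X <- X %*% solve(chol(crossprod(X) / n))  # exact identity moments
    X %*% chol(S)
  }
  mz <- make(n_per_zyg, cov_mz)
  dz <- make(n_per_zyg, cov_dz)
  structure(list(pairs = data.frame(
    pair_id = paste0("p", seq_len(2 * n_per_zyg)),
    zygosity = rep(c("MZ", "DZ"), each = n_per_zyg),
    trait1 = c(mz[, 1], dz[, 1]), trait2 = c(mz[, 2], dz[, 2]),
    genotyped_twin = 1L, stringsAsFactors = FALSE),
    genotypes = NULL, effects = NULL), class = "twin_cohort")
}

# Simulate a plain ACE cohort directly from the bivariate normal (no
# genotypes) — the distributional oracle for the ACE fitters.
gaussian_ace_cohort <- function(n_mz, n_dz, a2, c2, seed) {
  set.seed(seed)
  e2 <- 1 - a2 - c2
  draw <- function(n, rr) {
    z1 <- rnorm(n); z2 <- rr * z1 + sqrt(1 - rr^2) * rnorm(n)
    cbind(z1, z2)
  }
  mz <- draw(n_mz, a2 + c2)
  dz <- draw(n_dz, a2 / 2 + c2)
  structure(list(pairs = data.frame(
    pair_id = paste0("p", seq_len(n_mz + n_dz)),
    zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
    trait1 = c(mz[, 1], dz[, 1]), trait2 = c(mz[, 2], dz[, 2]),
    genotyped_twin = 1L, stringsAsFactors = FALSE),
    genotypes = NULL, effects = NULL), class = "twin_cohort")
}

# First-m-SNPs view of a genotype matrix (tests only).
subset_genotypes_for_test <- function(G, m) {
  genotype_matrix(G$dosages[, seq_len(m), drop = FALSE], G$fid, G$iid,
                  G$snp_ids[seq_len(m)])
}

# Subset view of a grm (tests only).
subset_grm_for_test <- function(A, keep) {
  grm(A$A[keep, keep, drop = FALSE], A$fid[keep], A$iid[keep], A$m_used)
}
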