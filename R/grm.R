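new_grm <- function(A, fid, iid, m_used = NA_real_, n_dropped = 0L) {
  structure(list(A = A, fid = as.character(fid), iid = as.character(iid),
                 m_used = m_used, n_dropped = n_dropped),
            class = "grm")
}

#' Genetic relationship matrix
#'
#' Construct a `grm` object directly from a symmetric similarity matrix,
#' mostly useful in tests; see [compute_grm()] for the estimator.
#'
#' @param A symmetric numeric matrix of pairwise genomic similarities.
#' @param fid,iid individual ids (unique pairs).
#' @param m_used number of SNPs that contributed.
#' @return a `grm` object.
#' @export
grm <- function(A, fid, iid, m_used = NA_real_) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop_param("A must be square")
  if (length(fid) != n || length(iid) != n) {
    stop_param("one (fid, iid) per individual required")
  }
  if (anyDuplicated(paste(fid, iid, sep = "\r"))) {
    stop_param("(fid, iid) pairs must be unique")
  }
  if (any(!is.finite(A))) stop_param("A must be finite")
  if (max(abs(A - t(A))) > 1e-8) stop_param("A must be symmetric")
  new_grm((A + t(A)) / 2, fid, iid, m_used)
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$A)
  off <- x$A[upper.tri(x$A)]
  cat(sprintf(
    "grm: %d individuals, %s SNPs; diag mean %.3f; off-diag mean %.2e (sd %.4f)\n",
    n, format(x$m_used), mean(diag(x$A)),
    if (n > 1) mean(off) else NA, if (n > 1) stats::sd(off) else NA))
  invisible(x)
}

#' Compute the genetic relationship matrix
#'
#' Standardised-dosage cross-product estimator of pairwise genomic
#' similarity: with allele frequency `p_i` for SNP i,
#' `A_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`.
#' Missing dosages are mean-imputed per SNP before standardisation (which
#' preserves the row-sum-zero identity under sample frequencies);
#' monomorphic SNPs and SNPs below the call-rate threshold are dropped with
#' a message. For unrelated individuals the off-diagonals concentrate
#' tightly around zero with standard deviation about `1/sqrt(m)`.
#'
#' @param G a [genotype_matrix()].
#' @param freq_source `"sample"` (allele frequencies re-estimated from the
#'   data) or `"provided"` (use `G$maf`).
#' @param min_call_rate SNPs with a lower fraction of non-missing calls are
#'   dropped (default 0.95).
#' @param block_size number of SNPs per accumulation block (memory control
#'   only; the result is identical for any block size).
#' @return a `grm` object; `n_dropped` records how many SNPs were excluded.
#' @export
#' @examples
#' G <- simulate_founders(50, 200, 0.1, 0.5, seed = 1)
#' A <- compute_grm(G)
#' max(abs(rowSums(A$A)))  # ~0: standardised columns sum to zero
compute_grm <- function(G, freq_source = c("sample", "provided"),
                        min_call_rate = 0.95, block_size = 10000L) {
  freq_source <- match.arg(freq_source)
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages
  n <- nrow(X); m <- ncol(X)
  if (n < 2) stop_param("need at least 2 individuals")
  if (m < 1) stop_param("need at least 1 SNP")
  call_rate <- 1 - colMeans(is.na(X))
  keep <- call_rate >= min_call_rate
  p_all <- if (freq_source == "provided") G$maf else colMeans(X, na.rm = TRUE) / 2
  poly <- is.finite(p_all) & p_all > 0 & p_all < 1
  keep <- keep & poly
  n_dropped <- sum(!keep)
  if (!any(keep)) stop_param("all SNPs monomorphic or low call rate: empty GRM")
  if (n_dropped > 0) {
    message(sprintf("compute_grm: dropped %d of %d SNPs (monomorphic or call rate < %.2f)",
                    n_dropped, m, min_call_rate))
  }
  idx_keep <- which(keep)
  A <- matrix(0, n, n)
  for (start in seq(1L, length(idx_keep), by = block_size)) {
    j <- idx_keep[start:min(start + block_size - 1L, length(idx_keep))]
    Xb <- X[, j, drop = FALSE]
    storage.mode(Xb) <- "double"
    if (anyNA(Xb)) {
      # mean imputation per SNP
      mu <- colMeans(Xb, na.rm = TRUE)
      na_idx <- which(is.na(Xb), arr.ind = TRUE)
      Xb[na_idx] <- mu[na_idx[, 2]]
    }
    p <- if (freq_source == "provided") G$maf[j] else colMeans(Xb) / 2
    Z <- sweep(Xb, 2L, 2 * p, "-")
    Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
    A <- A + tcrossprod(Z)
  }
  A <- A / length(idx_keep)
  new_grm(A, G$fid, G$iid, m_used = length(idx_keep), n_dropped = n_dropped)
}

#' Greedy relatedness filter
#'
#' Repeatedly removes the individual involved in the largest number of
#' pairwise similarities above the cutoff (ties broken by id order) until
#' no above-cutoff pair remains — the usual preprocessing step for keeping
#' a maximal set of mutually "unrelated" individuals.
#'
#' @param grm a `grm` object.
#' @param cutoff relationship cutoff, must be positive (default 0.025).
#' @return list with `keep` (retained row indices), `ids` (retained
#'   id data.frame in original order) and `removed` (data.frame log of
#'   removals with the above-cutoff pair count at removal time).
#' @export
filter_related <- function(grm, cutoff = 0.025) {
  stopifnot(inherits(grm, "grm"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop_param("cutoff must be > 0")
  A <- grm$A
  n <- nrow(A)
  adj <- A > cutoff
  diag(adj) <- FALSE
  active <- rep(TRUE, n)
  removed_idx <- integer(0); removed_deg <- integer(0)
  repeat {
    deg <- rowSums(adj[, active, drop = FALSE]) * active
    if (all(deg == 0)) break
    worst <- which.max(deg)  # first index on ties = id order
    active[worst] <- FALSE
    adj[worst, ] <- FALSE; adj[, worst] <- FALSE
    removed_idx <- c(removed_idx, worst)
    removed_deg <- c(removed_deg, deg[worst])
  }
  if (!any(active)) warning("all individuals removed by relatedness filter")
  list(keep = which(active),
       ids = data.frame(fid = grm$fid[active], iid = grm$iid[active],
                        stringsAsFactors = FALSE),
       removed = data.frame(fid = grm$fid[removed_idx],
                            iid = grm$iid[removed_idx],
                            n_pairs = removed_deg,
                            stringsAsFactors = FALSE))
}

# Subset a grm to a set of row indices.
subset_grm <- function(grm, keep) {
  new_grm(grm$A[keep, keep, drop = FALSE], grm$fid[keep], grm$iid[keep],
          grm$m_used, grm$n_dropped)
}

#' Summarise the pairwise genomic-similarity distribution
#'
#' Statistics over the `n(n-1)/2` off-diagonal entries of a GRM: mean,
#' standard deviation, and the fraction of pairs whose similarity lies
#' within `±window` of the mean (the concentration-of-chance-similarity
#' display: for tens of thousands of independent SNPs well over 90% of
#' unrelated pairs fall within ±0.01 of the mean). "Within 1%" is
#' interpreted as an absolute ±0.01 on the relationship scale; the window
#' is a parameter precisely because that reading is a convention.
#'
#' @param grm a `grm` object with at least 2 individuals.
#' @param window half-width of the concentration window (default 0.01).
#' @param bins number of histogram bins.
#' @return an object of class `similarity_summary`: `n`, `n_pairs`,
#'   `mean_offdiag`, `sd_offdiag`, `window`, `fraction_within_window`,
#'   `histogram` (data.frame `mid`, `count`).
#' @export
similarity_summary <- function(grm, window = 0.01, bins = 60L) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$A)
  if (n < 2) stop_param("need at least 2 individuals")
  off <- grm$A[upper.tri(grm$A)]
  mu <- mean(off)
  h <- graphics::hist(off, breaks = bins, plot = FALSE)
  structure(list(
    n = n, n_pairs = length(off), mean_offdiag = mu,
    sd_offdiag = stats::sd(off), window = window,
    fraction_within_window = mean(abs(off - mu) <= window),
    histogram = data.frame(mid = h$mids, count = h$counts)),
    class = "similarity_summary")
}

#' @export
print.similarity_summary <- function(x, ...) {
  cat(sprintf(
    paste0("similarity_summary: %d individuals, %d pairwise comparisons\n",
           "  off-diagonal mean %.2e, sd %.4f\n",
           "  %.1f%% of pairs within +/-%.3g of the mean\n"),
    x$n, x$n_pairs, x$mean_offdiag, x$sd_offdiag,
    100 * x$fraction_within_window, x$window))
  invisible(x)
}
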