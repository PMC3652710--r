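#' Per-trait ratio table of SNP-based to twin-based heritability
#'
#' For each trait, tabulates the SNP-based (GREML) estimate, the
#' twin-design estimate, and their ratio rounded half-up to two decimals,
#' together with the unweighted mean ratio over a designated set of
#' cognitive traits (also rounded half-up to two decimals). Full precision
#' is retained internally; only the displayed columns are rounded. Rows
#' whose twin estimate is not positive are flagged and excluded from the
#' mean with a warning.
#'
#' @param estimates data.frame with columns `trait`, `gcta_h2`, `twin_a2`
#'   and optionally `gcta_lo`, `gcta_hi`, `twin_lo`, `twin_hi` (95% CI
#'   bounds). Use [comparison_row()] to build rows from fitted objects.
#' @param cognitive_traits character vector of trait labels entering the
#'   mean cognitive ratio; all must be present.
#' @return an object of class `comparison_table`: `table` (the input plus
#'   `ratio` and `ratio_raw` columns), `mean_cognitive_ratio`,
#'   `mean_cognitive_ratio_raw`, `cognitive_traits`.
#' @export
#' @examples
#' est <- data.frame(
#'   trait = c("weight", "height", "g"),
#'   gcta_h2 = c(0.42, 0.35, 0.35),
#'   twin_a2 = c(0.84, 0.80, 0.46))
#' ratio_table(est, cognitive_traits = "g")
ratio_table <- function(estimates, cognitive_traits = character(0)) {
  need <- c("trait", "gcta_h2", "twin_a2")
  if (!all(need %in% names(estimates))) {
    stop_param("estimates needs columns ", paste(need, collapse = ", "))
  }
  if (!all(cognitive_traits %in% estimates$trait)) {
    stop_param("every cognitive trait must be present in the estimates")
  }
  tab <- as.data.frame(estimates)
  ok <- tab$twin_a2 > 0
  if (any(!ok)) {
    warning(sprintf("%d trait(s) with non-positive twin estimate: ratio NA, excluded from the mean",
                    sum(!ok)))
  }
  tab$ratio_raw <- ifelse(ok, tab$gcta_h2 / tab$twin_a2, NA_real_)
  tab$ratio <- round_half_up(tab$ratio_raw, 2)
  cog <- tab$trait %in% cognitive_traits & ok
  mean_raw <- if (any(cog)) mean(tab$ratio_raw[cog]) else NA_real_
  structure(list(table = tab,
                 mean_cognitive_ratio = round_half_up(mean_raw, 2),
                 mean_cognitive_ratio_raw = mean_raw,
                 cognitive_traits = cognitive_traits),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  fmt_ci <- function(lo, hi) {
    if (is.null(lo) || is.null(hi) || all(is.na(lo))) return(NULL)
    sprintf("[%.2f, %.2f]", lo, hi)
  }
  tab <- x$table
  out <- data.frame(Trait = tab$trait,
                    `SNP-based` = sprintf("%.2f", tab$gcta_h2),
                    Twin = sprintf("%.2f", tab$twin_a2),
                    Ratio = ifelse(is.na(tab$ratio), "-",
                                   sprintf("%.2f", tab$ratio)),
                    check.names = FALSE)
  ci_g <- fmt_ci(tab$gcta_lo, tab$gcta_hi)
  if (!is.null(ci_g)) out$`SNP-based` <- paste(out$`SNP-based`, ci_g)
  ci_t <- fmt_ci(tab$twin_lo, tab$twin_hi)
  if (!is.null(ci_t)) out$Twin <- paste(out$Twin, ci_t)
  print(out, row.names = FALSE)
  if (length(x$cognitive_traits)) {
    cat(sprintf("Mean cognitive ratio (%s): %.2f\n",
                paste(x$cognitive_traits, collapse = ", "),
                x$mean_cognitive_ratio))
  }
  invisible(x)
}

#' Build a comparison-table row from fitted objects
#'
#' @param trait trait label.
#' @param gcta a `greml_fit` from [fit_greml()].
#' @param twin an `ace_fit` from [fit_ace_ml()] or [falconer()].
#' @return one-row data.frame suitable for [ratio_table()].
#' @export
comparison_row <- function(trait, gcta, twin) {
  stopifnot(inherits(gcta, "greml_fit"), inherits(twin, "ace_fit"))
  tw_ci <- if (!is.null(twin$ci95)) twin$ci95["a2", ] else c(NA, NA)
  data.frame(trait = trait, gcta_h2 = gcta$h2_snp,
             gcta_lo = gcta$ci95[1], gcta_hi = gcta$ci95[2],
             twin_a2 = twin$a2, twin_lo = tw_ci[1], twin_hi = tw_ci[2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spouse-pair genomic-similarity index
#'
#' Mean GRM-style similarity (standardised-dosage cross-product with
#' sample allele frequencies) over a set of spouse pairs, restricted to a
#' chosen SNP set, with a one-sided permutation p value from random
#' re-pairings of the same individuals. Under phenotypic assortative
#' mating on a heritable trait, spouses are more genetically similar than
#' random pairs at trait-associated SNPs, so the index is elevated at
#' causal SNPs but not at null SNPs.
#'
#' @param G a [genotype_matrix()] containing all paired individuals.
#' @param spouse_pairs two-column matrix or data.frame of row indices into
#'   `G` (or of "fid:iid" id strings); pairs must be disjoint.
#' @param null_reps number of random re-pairings (>= 100).
#' @param snp_set `"all"`, or an integer vector of SNP column indices
#'   (e.g. the causal set of an `effect_model`).
#' @param seed integer RNG seed for the permutations.
#' @return list with `index` (mean spousal similarity), `null_mean`,
#'   `null_q95`, `permutation_p` (one-sided, upper tail, with the +1
#'   correction), `n_pairs`, `m_used`.
#' @export
spouse_similarity_index <- function(G, spouse_pairs, null_reps = 1000L,
                                    snp_set = "all", seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (null_reps < 100) stop_param("null_reps must be at least 100")
  sp <- as.matrix(spouse_pairs)
  if (ncol(sp) != 2) stop_param("spouse_pairs must have two columns")
  if (is.character(sp)) {
    key <- paste(G$fid, G$iid, sep = ":")
    sp <- matrix(match(sp, key), ncol = 2)
    if (anyNA(sp)) stop_param("unknown ids in spouse_pairs")
  }
  idx <- as.integer(sp)
  if (anyDuplicated(idx)) stop_param("spouse pairs must be disjoint")
  j <- if (identical(snp_set, "all")) seq_len(ncol(G$dosages)) else
    as.integer(snp_set)
  X <- G$dosages[idx, j, drop = FALSE]
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  Z <- sweep(X[, keep, drop = FALSE], 2, 2 * p[keep], "-")
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  k <- nrow(sp)
  pos1 <- seq_len(k); pos2 <- k + seq_len(k)  # rows of Z per pair member
  rows <- match(as.integer(sp), idx)
  r1 <- rows[pos1]; r2 <- rows[pos2]
  pair_index <- function(i1, i2) mean(rowSums(Z[i1, , drop = FALSE] *
                                                Z[i2, , drop = FALSE])) /
    sum(keep)
  obs <- pair_index(r1, r2)
  with_seed(seed, {
    null <- replicate(null_reps, {
      perm <- sample.int(2 * k)
      pair_index(perm[pos1], perm[pos2])
    })
  })
  list(index = obs, null_mean = mean(null),
       null_q95 = stats::quantile(null, 0.95, names = FALSE),
       permutation_p = (1 + sum(null >= obs)) / (null_reps + 1),
       n_pairs = k, m_used = sum(keep))
}
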