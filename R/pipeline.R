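#' Simulate one full SNP-vs-twin study replicate
#'
#' Runs the whole in-silico design: founders with a polygenic architecture
#' only partially tagged by the array, optional generations of phenotypic
#' assortative mating, a twin cohort whose parents are the (possibly
#' assorted) couples of the final generation, then both estimators — GREML
#' on the array view of one genotyped twin per pair, and twin-design ACE
#' on all pairs — and their ratio. With `tagged_fraction < 1` the SNP-based
#' estimate is a lower limit of the twin estimate; assortative mating
#' builds up cross-locus correlations between tagged and hidden causal
#' variants, which raises the SNP/twin ratio.
#'
#' @param n_founders founder population size (even).
#' @param m number of SNPs.
#' @param n_causal number of causal SNPs.
#' @param tagged_fraction fraction of causal SNPs on the array.
#' @param h2 narrow-sense heritability of the trait (equals the twin `a2`).
#' @param c2 shared-environment proportion for the twin cohort
#'   (`e2 = 1 - h2 - c2`).
#' @param spouse_corr spousal phenotypic correlation (0 = random mating).
#' @param n_generations generations of mating before the twin generation.
#' @param n_pairs number of twin pairs.
#' @param mz_fraction fraction of MZ pairs.
#' @param seed integer RNG seed.
#' @param cutoff relatedness cutoff for the GREML stage. The conventional
#'   0.025 presumes hundreds of thousands of markers; with m array SNPs the
#'   chance similarity of truly unrelated pairs has standard deviation
#'   about `1/sqrt(m)`, so the default `max(0.025, 6/sqrt(m))` removes
#'   genuine relatives without decimating the unrelated sample.
#' @param ci CI method for the ACE fit (`"wald"` is markedly faster).
#' @return list with `gcta` (`greml_fit`), `twin` (`ace_fit`), `ratio`
#'   (`h2_snp / a2`), `var_g` (genetic variance by generation), and
#'   `cohort` (the simulated `twin_cohort`).
#' @export
simulate_design_replicate <- function(n_founders = 1200, m = 800,
                                      n_causal = 300, tagged_fraction = 0.5,
                                      h2 = 0.5, c2 = 0.2, spouse_corr = 0,
                                      n_generations = 3, n_pairs = 500,
                                      mz_fraction = 0.5, seed = 1,
                                      cutoff = NULL, ci = "wald") {
  e2 <- 1 - h2 - c2
  if (e2 < 0) stop_param("h2 + c2 must not exceed 1")
  G0 <- simulate_founders(n_founders, m, 0.05, 0.5, seed = seed)
  eff <- assign_effects(G0, n_causal, tagged_fraction, h2, seed = seed + 1L)
  scheme <- if (spouse_corr > 0) "assortative" else "random"
  des <- mating_design(scheme, spouse_corr,
                       n_generations = max(0L, n_generations - 1L),
                       seed = seed + 2L)
  st <- if (des$n_generations > 0) {
    simulate_generations(G0, eff, des)
  } else {
    list(genotypes = G0, var_g = stats::var(genetic_values(G0, eff)))
  }
  Gp <- st$genotypes
  # final mating round supplies the twin parents' couples
  phen_p <- simulate_phenotype(Gp, eff, seed = seed + 3L)
  des_f <- mating_design(scheme, spouse_corr, 1L, seed = seed + 4L)
  off <- mate_and_reproduce(Gp, phen_p, des_f, n_offspring = 1)
  sp <- attr(off, "spouse_pairs")
  couples <- as.matrix(sp[, c("idx1", "idx2")])
  if (nrow(couples) < n_pairs) stop_param("not enough couples for n_pairs")
  couples <- couples[seq_len(n_pairs), , drop = FALSE]
  cohort <- simulate_twin_cohort(Gp, n_pairs, mz_fraction,
                                 a2 = h2, c2 = c2, e2 = e2,
                                 seed = seed + 5L, effects = eff,
                                 couples = couples)
  gv <- genotyped_twin_view(cohort, effects = eff)
  if (is.null(cutoff)) cutoff <- max(0.025, 6 / sqrt(ncol(gv$genotypes$dosages)))
  gfit <- estimate_h2_snp(geno = gv$genotypes, phen = gv$phenotype,
                          cutoff = cutoff)
  tfit <- fit_ace_ml(cohort, ci = ci)
  list(gcta = gfit, twin = tfit,
       ratio = if (tfit$a2 > 0) gfit$h2_snp / tfit$a2 else NA_real_,
       var_g = st$var_g, cohort = cohort)
}
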