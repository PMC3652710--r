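#' Genotype matrix container
#'
#' A light container for an individuals-by-SNPs dosage matrix (0/1/2 copies
#' of the counted allele, `NA` for missing calls) with individual ids
#' (family id, individual id), SNP ids and per-SNP allele frequencies.
#'
#' @param dosages integer matrix, n individuals x m SNPs, values 0/1/2 or NA.
#' @param fid,iid character vectors of family and individual ids; the pair
#'   (fid, iid) must be unique per row.
#' @param snp_ids character vector of SNP labels (default `snp1..snpm`).
#' @param maf optional per-SNP frequency of the counted allele in `[0, 1]`;
#'   estimated from the sample (mean dosage / 2, missing ignored) when NULL.
#' @return an object of class `genotype_matrix` with elements `dosages`,
#'   `fid`, `iid`, `snp_ids`, `maf`.
#' @export
genotype_matrix <- function(dosages, fid, iid, snp_ids = NULL, maf = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- NULL
  n <- nrow(dosages); m <- ncol(dosages)
  if (!all(dosages %in% c(0L, 1L, 2L) | is.na(dosages))) {
    stop_param("dosages must be 0, 1, 2 or NA")
  }
  fid <- as.character(fid); iid <- as.character(iid)
  if (length(fid) != n || length(iid) != n) {
    stop_param("fid and iid must have one entry per individual")
  }
  key <- paste(fid, iid, sep = "\r")
  if (anyDuplicated(key)) stop_param("(fid, iid) pairs must be unique")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  if (length(snp_ids) != m) stop_param("snp_ids must have one entry per SNP")
  if (is.null(maf)) {
    maf <- colMeans(dosages, na.rm = TRUE) / 2
  } else if (length(maf) != m || any(maf < 0 | maf > 1, na.rm = TRUE)) {
    stop_param("maf must be one frequency in [0, 1] per SNP")
  }
  structure(list(dosages = dosages, fid = fid, iid = iid,
                 snp_ids = as.character(snp_ids), maf = as.numeric(maf)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs, %d missing calls\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Subset a genotype_matrix by individuals (i) and/or SNPs (j).
subset_genotypes <- function(G, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(G$dosages))
  if (is.null(j)) j <- seq_len(ncol(G$dosages))
  genotype_matrix(G$dosages[i, j, drop = FALSE], G$fid[i], G$iid[i],
                  G$snp_ids[j], G$maf[j])
}

#' Simulate founder genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP is assigned an allele frequency drawn uniformly on
#' `[maf_low, maf_high]`; dosages are two independent allele draws at that
#' frequency (binomial with size 2), independently across loci — the
#' "unrelated individuals" starting point for every downstream analysis.
#'
#' @param n number of individuals.
#' @param m number of SNPs.
#' @param maf_low,maf_high bounds of the allele-frequency distribution,
#'   `0 < maf_low <= maf_high < 1`.
#' @param seed integer RNG seed; the result is a pure function of the
#'   arguments including the seed.
#' @return a [genotype_matrix()].
#' @export
#' @examples
#' G <- simulate_founders(100, 50, 0.1, 0.5, seed = 1)
simulate_founders <- function(n, m, maf_low = 0.05, maf_high = 0.5, seed = 1) {
  if (!is.numeric(n) || n < 1 || !is.numeric(m) || m < 1) {
    stop_param("n and m must be positive counts")
  }
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high < 1)) {
    stop_param("need 0 < maf_low <= maf_high < 1")
  }
  n <- as.integer(n); m <- as.integer(m)
  with_seed(seed, {
    p <- runif(m, maf_low, maf_high)
    dos <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
    genotype_matrix(dos, fid = paste0("fam", seq_len(n)),
                    iid = rep("1", n))
  })
}

#' Assign additive effects to causal SNPs
#'
#' Draws zero-mean normal effects with equal per-SNP variance for a random
#' set of causal SNPs and rescales them so the sample variance of the
#' genetic values equals `h2_target` (the phenotype being standardised to
#' unit variance). A fraction of causal SNPs is flagged as "tagged", i.e.
#' present on the genotyping array: untagged causal SNPs still shape the
#' phenotype but are hidden from the array view handed to GRM construction
#' — the mechanism by which SNP-based heritability becomes a lower limit
#' of the full narrow-sense heritability.
#'
#' @param G a [genotype_matrix()] (complete calls required).
#' @param n_causal number of causal SNPs (`<= m`).
#' @param tagged_fraction fraction of causal SNPs visible to the array;
#'   exactly `round(tagged_fraction * n_causal)` are flagged.
#' @param h2_target narrow-sense heritability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return an object of class `effect_model`: `causal_idx`, `beta`,
#'   `tagged_mask`, `h2_target`, `m` (SNP count of the source matrix).
#' @export
assign_effects <- function(G, n_causal, tagged_fraction = 1, h2_target = 0.5,
                           seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- ncol(G$dosages)
  if (n_causal < 1 || n_causal > m) {
    stop_param("n_causal must be between 1 and the number of SNPs")
  }
  check_proportion(tagged_fraction, "tagged_fraction")
  check_proportion(h2_target, "h2_target")
  with_seed(seed, {
    causal_idx <- sort(sample.int(m, n_causal))
    beta <- rnorm(n_causal)
    if (h2_target == 0) {
      beta[] <- 0
    } else {
      g <- as.vector(G$dosages[, causal_idx, drop = FALSE] %*% beta)
      v <- stats::var(g)
      if (v <= 0) stop_param("causal SNPs carry no variance; cannot scale")
      beta <- beta * sqrt(h2_target / v)
    }
    n_tag <- round(tagged_fraction * n_causal)
    tagged_mask <- rep(FALSE, n_causal)
    if (n_tag > 0) tagged_mask[sample.int(n_causal, n_tag)] <- TRUE
    structure(list(causal_idx = causal_idx, beta = beta,
                   tagged_mask = tagged_mask, h2_target = h2_target, m = m),
              class = "effect_model")
  })
}

#' Genetic values under an effect model
#'
#' @param G a [genotype_matrix()].
#' @param effects an `effect_model` from [assign_effects()].
#' @return numeric vector of additive genetic values (trait units of the
#'   population the effects were scaled in).
#' @export
genetic_values <- function(G, effects) {
  stopifnot(inherits(effects, "effect_model"))
  if (ncol(G$dosages) != effects$m) {
    stop_param("effect model refers to a different SNP panel")
  }
  as.vector(G$dosages[, effects$causal_idx, drop = FALSE] %*% effects$beta)
}

#' Array view of a genotype matrix
#'
#' Drops the untagged causal SNPs, i.e. returns the SNPs a genotyping array
#' would deliver. Null (non-causal) SNPs and tagged causal SNPs remain.
#'
#' @inheritParams genetic_values
#' @return a [genotype_matrix()] restricted to array SNPs.
#' @export
array_view <- function(G, effects) {
  stopifnot(inherits(effects, "effect_model"))
  hidden <- effects$causal_idx[!effects$tagged_mask]
  keep <- setdiff(seq_len(ncol(G$dosages)), hidden)
  subset_genotypes(G, j = keep)
}

#' Add visible tag proxies for hidden causal SNPs
#'
#' For each untagged causal SNP, appends a visible proxy SNP correlated with
#' it at approximately the requested r-squared (each proxy allele copies the
#' causal allele with probability `sqrt(r2)`, otherwise is a fresh draw at
#' the causal allele frequency). Gives finer control over partial tagging
#' than the all-or-nothing hidden-SNP mechanism.
#'
#' @inheritParams genetic_values
#' @param r2 target squared correlation between proxy and causal dosages.
#' @param seed integer RNG seed.
#' @return a [genotype_matrix()] with the proxies appended (ids
#'   `proxy_<causal snp id>`).
#' @export
add_tag_proxies <- function(G, effects, r2 = 0.5, seed = 1) {
  check_proportion(r2, "r2")
  hidden <- effects$causal_idx[!effects$tagged_mask]
  if (length(hidden) == 0) return(G)
  n <- nrow(G$dosages)
  delta <- sqrt(r2)
  with_seed(seed, {
    prox <- sapply(hidden, function(j) {
      x <- G$dosages[, j]
      p <- mean(x) / 2
      # phase the unphased dosage into two alleles, then copy each allele
      # with probability delta (copying a transmission draw instead would
      # attenuate the realized correlation)
      al1 <- as.integer(x == 2L | (x == 1L & runif(n) < 0.5))
      al2 <- x - al1
      a1 <- ifelse(runif(n) < delta, al1, rbinom(n, 1L, p))
      a2 <- ifelse(runif(n) < delta, al2, rbinom(n, 1L, p))
      a1 + a2
    })
    genotype_matrix(cbind(G$dosages, prox), G$fid, G$iid,
                    c(G$snp_ids, paste0("proxy_", G$snp_ids[hidden])))
  })
}

#' Simulate a polygenic phenotype
#'
#' Phenotype = centred genetic value + independent normal environmental
#' noise with variance `1 - h2_target`, so the phenotype has mean 0 and
#' variance close to 1. With `h2_target = 1` the phenotype equals the
#' centred (unit-variance) genetic value exactly.
#'
#' @inheritParams genetic_values
#' @param seed integer RNG seed for the environmental noise.
#' @return data.frame with columns `fid`, `iid`, `phenotype`,
#'   `genetic_value`.
#' @export
simulate_phenotype <- function(G, effects, seed = 1) {
  g <- genetic_values(G, effects)
  n <- length(g)
  with_seed(seed, {
    e_sd <- sqrt(max(0, 1 - effects$h2_target))
    y <- (g - mean(g)) + rnorm(n, 0, e_sd)
    data.frame(fid = G$fid, iid = G$iid, phenotype = y, genetic_value = g,
               stringsAsFactors = FALSE)
  })
}

#' Mating design
#'
#' @param scheme `"random"` or `"assortative"` (phenotypic assortment).
#' @param spouse_corr target spousal phenotypic correlation in `[0, 1)`;
#'   0 reduces assortative to random mating.
#' @param n_generations number of generations for [simulate_generations()].
#' @param seed integer RNG seed.
#' @return a `mating_design` list.
#' @export
mating_design <- function(scheme = c("assortative", "random"),
                          spouse_corr = 0, n_generations = 1, seed = 1) {
  scheme <- match.arg(scheme)
  if (spouse_corr < 0 || spouse_corr >= 1) {
    stop_param("spouse_corr must lie in [0, 1)")
  }
  if (scheme == "random") spouse_corr <- 0
  structure(list(scheme = scheme, spouse_corr = spouse_corr,
                 n_generations = as.integer(n_generations),
                 seed = as.integer(seed)),
            class = "mating_design")
}

# Pair two phenotype vectors to a target correlation by latent rank
# matching: couples inherit the rank pattern of a bivariate normal sample
# with latent correlation rho. rho starts at the analytic de-attenuation
# 2 sin(pi * target / 6) (rank matching of normal margins realises a
# Pearson correlation of (6/pi) asin(rho/2)) and is recalibrated until the
# realized correlation is within tol of the target; tol cannot beat the
# sampling noise of a correlation at k pairs, hence the 3/sqrt(k) floor.
rank_match_pairs <- function(y1, y2, target, tol = NULL, max_retry = 25) {
  k <- length(y1)
  o1 <- order(y1); o2 <- order(y2)
  if (target == 0) {
    return(list(pairs = cbind(o1, sample(o2)), realized = NA_real_))
  }
  if (is.null(tol)) tol <- max(0.01, 3 / sqrt(k))
  rho <- 2 * sin(pi * min(target, 0.99) / 6)
  for (it in seq_len(max_retry)) {
    u <- rnorm(k)
    v <- rho * u + sqrt(1 - rho^2) * rnorm(k)
    # couples inherit the joint rank pattern of the latent normal sample
    pairs <- cbind(o1[rank(u, ties.method = "first")],
                   o2[rank(v, ties.method = "first")])
    r <- stats::cor(y1[pairs[, 1]], y2[pairs[, 2]])
    if (abs(r - target) <= tol) {
      return(list(pairs = pairs, realized = r))
    }
    rho <- max(0.001, min(0.999, rho * target / max(r, 1e-3)))
  }
  stop_param(sprintf(
    "could not calibrate spousal correlation to %.2f after %d retries",
    target, max_retry))
}

#' Mate parents and produce one offspring generation
#'
#' Parents are split at random into two mating pools; spouses are paired
#' either at random or by noisy phenotype rank-matching calibrated so the
#' realized spousal phenotypic correlation approximates
#' `design$spouse_corr`. Each offspring receives one allele per SNP from
#' each parent (independent loci; no recombination map). Under assortative
#' mating, children receive correlated genetic influences from both
#' parents, which inflates additive genetic variance generation after
#' generation.
#'
#' @param G parental [genotype_matrix()] (even number of individuals,
#'   complete calls).
#' @param phen parental phenotypes: numeric vector aligned with `G`, or a
#'   data.frame with a `phenotype` column as from [simulate_phenotype()].
#' @param design a [mating_design()].
#' @param n_offspring offspring per couple (default 2 keeps the census size).
#' @param id_prefix prefix for offspring individual ids.
#' @return offspring [genotype_matrix()] with attributes `spouse_pairs`
#'   (data.frame of parental index and id pairs) and `realized_corr`
#'   (realized spousal phenotypic correlation, NA under random mating).
#' @export
mate_and_reproduce <- function(G, phen, design, n_offspring = 2,
                               id_prefix = "o") {
  stopifnot(inherits(G, "genotype_matrix"), inherits(design, "mating_design"))
  if (is.data.frame(phen)) phen <- phen$phenotype
  n <- nrow(G$dosages)
  if (length(phen) != n) stop_param("phenotype length must match G")
  if (n %% 2L != 0L) stop_param("need an even number of parents")
  if (anyNA(G$dosages)) stop_param("parental genotypes must be complete")
  with_seed(design$seed, {
    perm <- sample.int(n)
    g1 <- perm[seq_len(n / 2)]; g2 <- perm[(n / 2 + 1):n]
    mp <- rank_match_pairs(phen[g1], phen[g2], design$spouse_corr)
    p1 <- g1[mp$pairs[, 1]]; p2 <- g2[mp$pairs[, 2]]
    k <- length(p1)
    m <- ncol(G$dosages)
    Gm <- G$dosages[p1, , drop = FALSE]
    Gf <- G$dosages[p2, , drop = FALSE]
    kids <- vector("list", n_offspring)
    for (c_i in seq_len(n_offspring)) {
      a1 <- matrix(runif(k * m), k, m) < Gm / 2
      a2 <- matrix(runif(k * m), k, m) < Gf / 2
      kids[[c_i]] <- a1 + a2
    }
    dos <- do.call(rbind, kids)
    fid <- rep(paste0(id_prefix, "fam", seq_len(k)), times = n_offspring)
    iid <- rep(as.character(seq_len(n_offspring)), each = k)
    out <- genotype_matrix(dos, fid, iid, G$snp_ids)
    attr(out, "spouse_pairs") <- data.frame(
      idx1 = p1, idx2 = p2,
      fid1 = G$fid[p1], iid1 = G$iid[p1],
      fid2 = G$fid[p2], iid2 = G$iid[p2],
      stringsAsFactors = FALSE)
    attr(out, "realized_corr") <- mp$realized
    out
  })
}

#' Evolve a population for several generations
#'
#' Repeatedly recomputes phenotypes under a fixed effect model (environmental
#' variance held at `1 - h2_target` in founder trait units) and applies
#' [mate_and_reproduce()], tracking the additive genetic variance of each
#' generation. Under phenotypic assortative mating the genetic variance is
#' expected to increase across generations.
#'
#' @param G founder [genotype_matrix()].
#' @param effects an `effect_model` scaled in the founder generation.
#' @param design a [mating_design()] whose `n_generations` controls the
#'   number of rounds.
#' @param n_offspring offspring per couple.
#' @return list with `genotypes` (final generation), `var_g` (additive
#'   genetic variance per generation, founders first), `spouse_pairs` and
#'   `realized_corr` of the final round, and `phenotype` of the final
#'   generation.
#' @export
simulate_generations <- function(G, effects, design, n_offspring = 2) {
  var_g <- numeric(design$n_generations + 1)
  var_g[1] <- stats::var(genetic_values(G, effects))
  pairs <- NULL; rc <- rep(NA_real_, design$n_generations)
  phen <- NULL
  for (gen in seq_len(design$n_generations)) {
    gen_seed <- design$seed + 7919L * gen
    phen <- simulate_phenotype(G, effects, seed = gen_seed)
    d <- design; d$seed <- gen_seed + 1L
    G <- mate_and_reproduce(G, phen, d, n_offspring = n_offspring,
                            id_prefix = paste0("g", gen))
    pairs <- attr(G, "spouse_pairs")
    rc[gen] <- attr(G, "realized_corr")
    var_g[gen + 1] <- stats::var(genetic_values(G, effects))
  }
  list(genotypes = G, var_g = var_g, spouse_pairs = pairs,
       realized_corr = rc, phenotype = phen)
}

#' Simulate an MZ/DZ twin cohort
#'
#' Twin pairs are offspring of distinct parental couples. MZ co-twins share
#' one genome draw (genetic similarity 1.00); DZ co-twins are full siblings
#' (expected additive relationship .50). Traits follow the ACE model:
#' additive genetic value (variance `a2`, via an effect model scaled on the
#' parents unless one is supplied), a shared-environment deviate common to
#' the pair (variance `c2`), and a unique deviate per twin (variance `e2`).
#' One twin per pair is flagged as genotyped, mirroring designs where a
#' single member of each pair enters the SNP analysis.
#'
#' @param parents parental [genotype_matrix()].
#' @param n_pairs number of twin pairs.
#' @param mz_fraction fraction of pairs that are monozygotic
#'   (`round(mz_fraction * n_pairs)` MZ pairs).
#' @param a2,c2,e2 additive-genetic, shared-environment and nonshared
#'   variance proportions; must sum to 1 (tolerance 1e-8).
#' @param seed integer RNG seed.
#' @param effects optional `effect_model` in trait units; when supplied it is
#'   used as-is (its scale defines the genetic variance, allowing e.g.
#'   assortment-inflated cohorts), otherwise effects with
#'   `h2_target = a2` are drawn on the parents.
#' @param couples optional k x 2 matrix of parental row indices; by default
#'   `2 * n_pairs` distinct parents are drawn at random.
#' @return an object of class `twin_cohort`: `pairs` (data.frame `pair_id`,
#'   `zygosity`, `trait1`, `trait2`, `genotyped_twin`), `genotypes`
#'   (both twins; fid = pair id, iid = "1"/"2"), `effects`.
#' @export
simulate_twin_cohort <- function(parents, n_pairs, mz_fraction = 0.5,
                                 a2 = 0.5, c2 = 0.0, e2 = 0.5, seed = 1,
                                 effects = NULL, couples = NULL) {
  stopifnot(inherits(parents, "genotype_matrix"))
  if (abs(a2 + c2 + e2 - 1) > 1e-8) {
    stop_param("a2 + c2 + e2 must equal 1")
  }
  if (anyNA(parents$dosages)) stop_param("parental genotypes must be complete")
  n_par <- nrow(parents$dosages)
  with_seed(seed, {
    if (is.null(effects)) {
      effects <- assign_effects(parents, n_causal = ncol(parents$dosages),
                                tagged_fraction = 1, h2_target = a2,
                                seed = sample.int(2^30, 1))
    }
    if (is.null(couples)) {
      if (n_par < 2 * n_pairs) {
        stop_param("need at least 2 * n_pairs parents")
      }
      idx <- sample.int(n_par, 2 * n_pairs)
      couples <- cbind(idx[seq_len(n_pairs)], idx[(n_pairs + 1):(2 * n_pairs)])
    }
    n_mz <- round(mz_fraction * n_pairs)
    zyg <- c(rep("MZ", n_mz), rep("DZ", n_pairs - n_mz))
    m <- ncol(parents$dosages)
    Gm <- parents$dosages[couples[, 1], , drop = FALSE]
    Gf <- parents$dosages[couples[, 2], , drop = FALSE]
    meiosis <- function() {
      (matrix(runif(n_pairs * m), n_pairs, m) < Gm / 2) +
        (matrix(runif(n_pairs * m), n_pairs, m) < Gf / 2)
    }
    t1 <- meiosis()
    t2 <- meiosis()
    mz <- zyg == "MZ"
    t2[mz, ] <- t1[mz, ]
    dos <- rbind(t1, t2)
    pair_id <- paste0("pair", seq_len(n_pairs))
    Gt <- genotype_matrix(dos, fid = rep(pair_id, 2),
                          iid = rep(c("1", "2"), each = n_pairs),
                          snp_ids = parents$snp_ids)
    g <- genetic_values(Gt, effects)
    g1 <- g[seq_len(n_pairs)]; g2 <- g[(n_pairs + 1):(2 * n_pairs)]
    C <- rnorm(n_pairs, 0, sqrt(c2))
    trait1 <- g1 + C + rnorm(n_pairs, 0, sqrt(e2))
    trait2 <- g2 + C + rnorm(n_pairs, 0, sqrt(e2))
    genotyped <- sample(1:2, n_pairs, replace = TRUE)
    structure(list(
      pairs = data.frame(pair_id = pair_id, zygosity = zyg,
                         trait1 = trait1, trait2 = trait2,
                         genotyped_twin = genotyped,
                         stringsAsFactors = FALSE),
      genotypes = Gt, effects = effects), class = "twin_cohort")
  })
}

#' @export
print.twin_cohort <- function(x, ...) {
  tab <- table(x$pairs$zygosity)
  cat(sprintf("twin_cohort: %d pairs (%s)\n", nrow(x$pairs),
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' One-genotyped-twin view of a cohort
#'
#' Extracts the genotyped twin of each pair together with that twin's trait
#' value — the sampling convention in which one random member per pair
#' enters the SNP-based analysis while both enter the twin analysis.
#'
#' @param cohort a `twin_cohort`.
#' @param effects optional `effect_model`; when supplied the genotypes are
#'   restricted to the [array_view()] SNPs.
#' @return list with `genotypes` (one row per pair) and `phenotype`
#'   (data.frame `fid`, `iid`, `phenotype`).
#' @export
genotyped_twin_view <- function(cohort, effects = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"))
  n_pairs <- nrow(cohort$pairs)
  gt <- cohort$pairs$genotyped_twin
  rows <- ifelse(gt == 1, seq_len(n_pairs), n_pairs + seq_len(n_pairs))
  G <- subset_genotypes(cohort$genotypes, i = rows)
  if (!is.null(effects)) G <- array_view(G, effects)
  y <- ifelse(gt == 1, cohort$pairs$trait1, cohort$pairs$trait2)
  list(genotypes = G,
       phenotype = data.frame(fid = G$fid, iid = G$iid, phenotype = y,
                              stringsAsFactors = FALSE))
}
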