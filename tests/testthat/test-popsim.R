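test_that("founder genotypes follow Hardy-Weinberg proportions", {
  G <- simulate_founders(10000, 1, maf_low = 0.2, maf_high = 0.2, seed = 7)
  counts <- tabulate(G$dosages + 1L, nbins = 3)
  # exact trinomial oracle at p = 0.2: (0.64, 0.32, 0.04)
  p_hw <- c(0.8^2, 2 * 0.8 * 0.2, 0.2^2)
  se <- sqrt(p_hw * (1 - p_hw) / 10000)
  expect_true(all(abs(counts / 10000 - p_hw) < 3 * se))
  gof <- chisq.test(counts, p = p_hw)
  expect_gt(gof$p.value, 1e-4)
})

test_that("simulation operations are deterministic in the seed and leave the RNG alone", {
  G1 <- simulate_founders(200, 50, 0.1, 0.5, seed = 11)
  set.seed(999); before <- rnorm(1)
  set.seed(999)
  G2 <- simulate_founders(200, 50, 0.1, 0.5, seed = 11)
  after <- rnorm(1)
  expect_identical(G1$dosages, G2$dosages)
  expect_identical(before, after)  # caller RNG state untouched
  E1 <- assign_effects(G1, 20, 0.5, 0.4, seed = 3)
  E2 <- assign_effects(G2, 20, 0.5, 0.4, seed = 3)
  expect_identical(E1$beta, E2$beta)
  expect_identical(E1$tagged_mask, E2$tagged_mask)
})

test_that("dosage mean is symmetric at allele frequency one half", {
  G <- simulate_founders(10000, 5, 0.5, 0.5, seed = 13)
  mu <- colMeans(G$dosages)
  se <- sqrt(0.5 / 10000)  # var of a dosage at p = .5 is 2pq = .5
  expect_true(all(abs(mu - 1) < 3 * se))
})

test_that("bad simulation parameters are rejected", {
  expect_error(simulate_founders(0, 10, 0.1, 0.5), "positive")
  expect_error(simulate_founders(10, 10, 0, 0.5), "maf_low")
  expect_error(simulate_founders(10, 10, 0.5, 0.1), "maf_low")
  expect_error(assign_effects(simulate_founders(10, 5, seed = 1), 6), "n_causal")
  expect_error(simulate_twin_cohort(simulate_founders(10, 5, seed = 1),
                                    2, a2 = 0.5, c2 = 0.5, e2 = 0.5),
               "equal 1")
  expect_error(mate_and_reproduce(simulate_founders(11, 5, seed = 1),
                                  rnorm(11), mating_design("random")),
               "even")
})

test_that("effect assignment scales genetic variance and flags tagging", {
  G <- simulate_founders(5000, 2000, 0.05, 0.5, seed = 17)
  E <- assign_effects(G, 1000, tagged_fraction = 1, h2_target = 0.5, seed = 18)
  expect_true(all(E$tagged_mask))
  expect_identical(ncol(array_view(G, E)$dosages), 2000L)
  g <- genetic_values(G, E)
  expect_gt(var(g), 0.45); expect_lt(var(g), 0.55)
  E0 <- assign_effects(G, 1000, 1, h2_target = 0, seed = 18)
  expect_true(all(E0$beta == 0))
  Eh <- assign_effects(G, 100, tagged_fraction = 0.3, h2_target = 0.5, seed = 19)
  expect_identical(sum(Eh$tagged_mask), 30L)
  expect_identical(ncol(array_view(G, Eh)$dosages), 2000L - 70L)
})

test_that("phenotype equals signal plus noise with the target heritability", {
  G <- simulate_founders(5000, 1000, 0.05, 0.5, seed = 21)
  E0 <- assign_effects(G, 500, 1, h2_target = 0, seed = 22)
  ph0 <- simulate_phenotype(G, E0, seed = 23)
  expect_lt(abs(cor(ph0$phenotype, rnorm(5000))), 3 / sqrt(5000))
  E1 <- assign_effects(G, 500, 1, h2_target = 1, seed = 22)
  ph1 <- simulate_phenotype(G, E1, seed = 23)
  g1 <- genetic_values(G, E1)
  expect_equal(ph1$phenotype, g1 - mean(g1))
  E5 <- assign_effects(G, 500, 1, h2_target = 0.5, seed = 22)
  ph5 <- simulate_phenotype(G, E5, seed = 23)
  expect_equal(cor(ph5$phenotype, ph5$genetic_value)^2, 0.5,
               tolerance = 0.05 / 0.5)
})

test_that("random mating realizes a null spousal correlation", {
  G <- simulate_founders(2000, 100, 0.1, 0.5, seed = 25)
  E <- assign_effects(G, 100, 1, 0.5, seed = 26)
  ph <- simulate_phenotype(G, E, seed = 27)
  off <- mate_and_reproduce(G, ph, mating_design("random", seed = 28))
  sp <- attr(off, "spouse_pairs")
  r <- cor(ph$phenotype[sp$idx1], ph$phenotype[sp$idx2])
  expect_lt(abs(r), 3 / sqrt(nrow(sp)))
})

test_that("assortative mating calibrates to the target spousal correlation", {
  G <- simulate_founders(10000, 200, 0.1, 0.5, seed = 31)
  E <- assign_effects(G, 200, 1, 0.5, seed = 32)
  ph <- simulate_phenotype(G, E, seed = 33)
  off <- mate_and_reproduce(G, ph, mating_design("assortative", 0.45, seed = 34))
  sp <- attr(off, "spouse_pairs")
  r <- cor(ph$phenotype[sp$idx1], ph$phenotype[sp$idx2])
  expect_gt(r, 0.40); expect_lt(r, 0.50)
})

test_that("assortative mating inflates additive genetic variance across generations", {
  up <- vapply(1:12, function(rep) {
    G <- simulate_founders(4000, 300, 0.1, 0.5, seed = 40 + rep)
    E <- assign_effects(G, 300, 1, 0.5, seed = 140 + rep)
    d <- mating_design("assortative", 0.45, n_generations = 3,
                       seed = 240 + rep)
    v <- simulate_generations(G, E, d)$var_g
    all(diff(v) > 0)
  }, logical(1))
  expect_gte(mean(up), 0.9)
})

test_that("tagged genetic variance is monotone in the tagged fraction", {
  G <- simulate_founders(3000, 1000, 0.05, 0.5, seed = 51)
  tagged_var <- function(tf, seed) {
    E <- assign_effects(G, 400, tagged_fraction = tf, h2_target = 0.5,
                        seed = seed)
    tag <- E$causal_idx[E$tagged_mask]
    if (!length(tag)) return(0)
    var(as.vector(G$dosages[, tag, drop = FALSE] %*% E$beta[E$tagged_mask]))
  }
  reps <- 20
  v0 <- mean(vapply(1:reps, function(s) tagged_var(0, s), numeric(1)))
  v5 <- mean(vapply(1:reps, function(s) tagged_var(0.5, s), numeric(1)))
  v1 <- mean(vapply(1:reps, function(s) tagged_var(1, s), numeric(1)))
  expect_identical(v0, 0)
  expect_gt(v5, v0); expect_gt(v1, v5)
  expect_equal(v1, 0.5, tolerance = 0.02)
})

test_that("MZ co-twins share genotypes and DZ co-twins are half-related", {
  par <- simulate_founders(6000, 1000, 0.05, 0.5, seed = 61)
  co_mz <- simulate_twin_cohort(par, 300, mz_fraction = 1,
                                a2 = 0.5, c2 = 0.2, e2 = 0.3, seed = 62)
  n <- 300
  expect_identical(co_mz$genotypes$dosages[1:n, ],
                   co_mz$genotypes$dosages[n + 1:n, ])
  # DZ: mean per-pair standardized relationship ~ 0.5 (pedigree oracle)
  co_dz <- simulate_twin_cohort(par, 2500, mz_fraction = 0,
                                a2 = 0.5, c2 = 0.2, e2 = 0.3, seed = 63)
  X <- co_dz$genotypes$dosages
  storage.mode(X) <- "double"
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  Z <- sweep(X[, keep], 2, 2 * p[keep], "-")
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  k <- 2500
  rel <- rowSums(Z[1:k, ] * Z[k + 1:k, ]) / sum(keep)
  expect_lt(abs(mean(rel) - 0.5), 3 * sd(rel) / sqrt(k))
})

test_that("twin trait correlations match the ACE expectations", {
  par <- simulate_founders(40000, 300, 0.05, 0.5, seed = 71)
  co <- simulate_twin_cohort(par, 20000, mz_fraction = 0.5,
                             a2 = 0.5, c2 = 0.3, e2 = 0.2, seed = 72)
  r <- twin_correlations(co)
  expect_equal(r$r_mz, 0.8, tolerance = 0.02 / 0.8)
  expect_equal(r$r_dz, 0.55, tolerance = 0.02 / 0.55)
  # variance bookkeeping: double-entered trait variance near 1
  expect_equal(var(c(co$pairs$trait1, co$pairs$trait2)), 1, tolerance = 0.05)
})

test_that("tag proxies correlate with hidden causal SNPs at the requested r2", {
  G <- simulate_founders(4000, 50, 0.2, 0.4, seed = 81)
  E <- assign_effects(G, 20, tagged_fraction = 0, h2_target = 0.5, seed = 82)
  Gp <- add_tag_proxies(G, E, r2 = 0.5, seed = 83)
  expect_identical(ncol(Gp$dosages), 70L)
  r2 <- vapply(seq_len(20), function(i) {
    cor(Gp$dosages[, E$causal_idx[i]], Gp$dosages[, 50 + i])^2
  }, numeric(1))
  expect_equal(mean(r2), 0.5, tolerance = 0.1)
})
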