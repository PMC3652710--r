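test_that("ratio table arithmetic is exact with half-up rounding", {
  est <- data.frame(
    trait = c("weight", "height", "g", "nonverbal", "verbal", "language"),
    gcta_h2 = c(0.42, 0.35, 0.35, 0.20, 0.26, 0.29),
    twin_a2 = c(0.84, 0.80, 0.46, 0.42, 0.40, 0.39))
  tab <- ratio_table(est, cognitive_traits = c("g", "nonverbal", "verbal",
                                               "language"))
  expect_equal(tab$table$ratio, c(0.50, 0.44, 0.76, 0.48, 0.65, 0.74))
  expect_equal(tab$mean_cognitive_ratio, 0.66)
  # .35/.80 = .4375 rounds up, not to even
  expect_equal(round_half_up(0.4375, 2), 0.44)
  expect_equal(round_half_up(0.655, 2), 0.66)
  # identical estimates -> all ratios 1
  same <- data.frame(trait = c("a", "b"), gcta_h2 = c(0.3, 0.5),
                     twin_a2 = c(0.3, 0.5))
  t2 <- ratio_table(same, cognitive_traits = c("a", "b"))
  expect_true(all(t2$table$ratio == 1))
  expect_equal(t2$mean_cognitive_ratio, 1)
})

test_that("non-positive twin estimates are flagged and excluded from the mean", {
  est <- data.frame(trait = c("a", "b"), gcta_h2 = c(0.3, 0.2),
                    twin_a2 = c(0.6, 0))
  expect_warning(tab <- ratio_table(est, cognitive_traits = c("a", "b")),
                 "non-positive")
  expect_true(is.na(tab$table$ratio[2]))
  expect_equal(tab$mean_cognitive_ratio, 0.5)
  expect_error(ratio_table(est, cognitive_traits = "zzz"), "present")
})

test_that("comparison rows are assembled from fitted objects", {
  G <- simulate_founders(200, 1200, 0.1, 0.5, seed = 51)
  E <- assign_effects(G, 300, 1, 0.5, seed = 52)
  y <- simulate_phenotype(G, E, seed = 53)$phenotype
  gfit <- fit_greml(compute_grm(G), y)
  tfit <- fit_ace_ml(gaussian_ace_cohort(800, 800, 0.5, 0.2, seed = 54),
                     ci = "wald")
  row <- comparison_row("toy", gfit, tfit)
  tab <- ratio_table(row, cognitive_traits = "toy")
  expect_equal(tab$table$ratio_raw, gfit$h2_snp / tfit$a2)
})

test_that("marrying duplicates maximises the spouse similarity index", {
  G <- simulate_founders(60, 800, 0.1, 0.5, seed = 55)
  Gdup <- genotype_matrix(rbind(G$dosages, G$dosages),
                          c(G$fid, paste0("d", G$fid)),
                          rep(c("1", "2"), each = 60))
  sp <- cbind(1:60, 61:120)
  res <- spouse_similarity_index(Gdup, sp, null_reps = 200, seed = 56)
  A <- compute_grm(Gdup)
  expect_equal(res$index, mean(diag(A$A)[1:60]), tolerance = 0.05)
  expect_lt(res$permutation_p, 0.01)
  expect_error(spouse_similarity_index(Gdup, rbind(sp, c(1, 2)),
                                       null_reps = 200), "disjoint")
  expect_error(spouse_similarity_index(Gdup, sp, null_reps = 10), "at least")
})

test_that("random pairings centre the index on the off-diagonal mean", {
  G <- simulate_founders(200, 1000, 0.1, 0.5, seed = 57)
  sp <- cbind(1:100, 101:200)
  res <- spouse_similarity_index(G, sp, null_reps = 500, seed = 58)
  expect_equal(res$null_mean, -1 / (200 - 1), tolerance = 0.5)
})

test_that("permutation p values are uniform under random mating", {
  ps <- vapply(1:30, function(r) {
    G <- simulate_founders(120, 400, 0.1, 0.5, seed = 600 + r)
    sp <- cbind(1:60, 61:120)
    spouse_similarity_index(G, sp, null_reps = 199, seed = 700 + r)$permutation_p
  }, numeric(1))
  # p values are discrete at 199 permutations, hence the ties warning
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.05)
})

test_that("assortative mating elevates spousal similarity at causal but not null SNPs", {
  # the index's detectable signal is rho * h2 / n_causal against permutation
  # noise ~ 1/sqrt(n_pairs * n_causal), so an adequately powered design
  # needs an oligogenic trait and many couples
  reps <- 25
  hits_causal <- logical(reps); hits_null <- logical(reps)
  for (r in seq_len(reps)) {
    G <- simulate_founders(5000, 200, 0.1, 0.5, seed = 800 + r)
    E <- assign_effects(G, 20, 1, 0.5, seed = 900 + r)
    ph <- simulate_phenotype(G, E, seed = 1000 + r)
    off <- mate_and_reproduce(G, ph, mating_design("assortative", 0.45,
                                                   seed = 1100 + r))
    sp <- attr(off, "spouse_pairs")
    pairs <- as.matrix(sp[, c("idx1", "idx2")])
    res_c <- spouse_similarity_index(G, pairs, null_reps = 199,
                                     snp_set = E$causal_idx, seed = 1200 + r)
    null_snps <- setdiff(seq_len(200), E$causal_idx)
    res_n <- spouse_similarity_index(G, pairs, null_reps = 199,
                                     snp_set = null_snps, seed = 1300 + r)
    hits_causal[r] <- res_c$index > res_c$null_q95
    hits_null[r] <- res_n$index > res_n$null_q95
  }
  expect_gte(mean(hits_causal), 0.8)  # directional power at causal SNPs
  expect_lt(mean(hits_null), 0.3)     # null SNPs stay at the 5% level
})
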