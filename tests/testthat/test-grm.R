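test_that("single-SNP GRM matches the hand-standardized cross-product", {
  G <- genotype_matrix(matrix(c(0L, 1L, 1L, 2L), 4, 1),
                       paste0("f", 1:4), rep("1", 4))
  A <- compute_grm(G)$A
  # sample p = 0.5, z = (x - 1)/sqrt(0.5)
  expect_equal(A[1, 4], -2.0)
  expect_equal(A[1, 1], 2.0)
  expect_equal(A[2, 3], 0.0)
})

test_that("a duplicated individual is genetically identical to its copy", {
  G <- simulate_founders(30, 400, 0.1, 0.5, seed = 11)
  Gdup <- genotype_matrix(rbind(G$dosages, G$dosages[1, ]),
                          c(G$fid, "dup"), c(G$iid, "1"))
  A <- compute_grm(Gdup)$A
  expect_equal(A[1, 31], A[1, 1])
  expect_equal(A[1, 31], A[31, 31])
  expect_gt(A[1, 31], 0.8)  # MZ-like pair near 1
})

test_that("row sums vanish under sample frequencies with mean imputation", {
  G <- simulate_founders(80, 600, 0.05, 0.5, seed = 12)
  G$dosages[sample(length(G$dosages), 300)] <- NA
  A <- compute_grm(G)
  expect_lt(max(abs(rowSums(A$A))), 1e-10)
  mu_off <- mean(A$A[upper.tri(A$A)])
  expect_equal(mu_off, -mean(diag(A$A)) / (nrow(A$A) - 1), tolerance = 1e-10)
})

test_that("monomorphic and low-call-rate SNPs are dropped, empty GRM errors", {
  dos <- cbind(c(0L, 1L, 2L, 1L), rep(2L, 4), c(0L, NA, NA, NA))
  G <- genotype_matrix(dos, paste0("f", 1:4), rep("1", 4))
  expect_message(A <- compute_grm(G), "dropped 2 of 3")
  expect_identical(A$m_used, 1L)
  mono <- genotype_matrix(matrix(2L, 4, 2), paste0("f", 1:4), rep("1", 4))
  expect_error(compute_grm(mono), "empty GRM")
})

test_that("blocked accumulation gives the same GRM as one pass", {
  G <- simulate_founders(40, 250, 0.1, 0.5, seed = 13)
  A1 <- compute_grm(G)$A
  A2 <- compute_grm(G, block_size = 64L)$A
  expect_equal(A1, A2, tolerance = 1e-12)
})

test_that("greedy relatedness filter keeps maximal unrelated sets", {
  # no pair above cutoff -> everyone retained
  G <- simulate_founders(25, 5000, 0.1, 0.5, seed = 14)
  A <- compute_grm(G)
  expect_identical(filter_related(A, 0.25)$keep, 1:25)
  # one near-identical pair -> exactly one of the two removed
  Gdup <- genotype_matrix(rbind(G$dosages, G$dosages[1, ]),
                          c(G$fid, "dup"), c(G$iid, "1"))
  fl <- filter_related(compute_grm(Gdup), 0.25)
  expect_identical(length(fl$keep), 25L)
  expect_identical(sum(c(1L, 26L) %in% fl$keep), 1L)
  # chain a-b, b-c related, a-c not: b removed, {a, c} kept
  Ach <- matrix(c(1, .5, 0, .5, 1, .5, 0, .5, 1), 3)
  gch <- grm(Ach, c("a", "b", "c"), rep("1", 3))
  flc <- filter_related(gch, 0.25)
  expect_identical(flc$keep, c(1L, 3L))
  # brute-force oracle on random small matrices
  set.seed(15)
  for (i in 1:20) {
    n <- 6
    S <- matrix(runif(n * n, -0.1, 0.45), n)
    S <- (S + t(S)) / 2; diag(S) <- 1
    gg <- grm(S, paste0("i", 1:n), rep("1", n))
    keep <- filter_related(gg, 0.25)$keep
    best <- brute_force_unrelated(S, 0.25)
    expect_identical(length(keep), length(best[[1]]))
    expect_true(!any(S[keep, keep][upper.tri(diag(length(keep)))] > 0.25))
  }
})

test_that("similarity summary counts pairs and measures concentration", {
  A <- grm(matrix(0.01, 4, 4) + diag(0.99, 4), paste0("f", 1:4), rep("1", 4))
  s <- similarity_summary(A)
  expect_identical(s$n_pairs, 6L)
  expect_identical(s$fraction_within_window, 1)  # all off-diagonals equal
  G <- simulate_founders(120, 3000, 0.05, 0.5, seed = 16)
  s2 <- similarity_summary(compute_grm(G), window = 0.01)
  expect_equal(s2$sd_offdiag, 1 / sqrt(3000), tolerance = 0.15)
  expect_identical(sum(s2$histogram$count), s2$n_pairs)
})

test_that("off-diagonal spread scales as one over the square root of m", {
  G <- simulate_founders(150, 50000, 0.05, 0.5, seed = 17)
  ms <- c(1000, 10000, 50000)
  sds <- vapply(ms, function(m) {
    A <- compute_grm(subset_genotypes_for_test(G, m))
    sd(A$A[upper.tri(A$A)])
  }, numeric(1))
  slope <- coef(lm(log(sds) ~ log(ms)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
  # unrelateds band: central 95% within about +/-.02 of zero for m >= 10000
  # (n large enough that the forced off-diagonal mean -1/(n-1) is negligible)
  G2 <- simulate_founders(300, 20000, 0.05, 0.5, seed = 18)
  A10 <- compute_grm(G2)
  q <- quantile(A10$A[upper.tri(A10$A)], c(0.025, 0.975))
  expect_gt(q[1], -0.02); expect_lt(q[2], 0.02)
})

test_that("full siblings show the expected half relationship in the GRM", {
  par <- simulate_founders(3000, 2000, 0.1, 0.5, seed = 18)
  co <- simulate_twin_cohort(par, 600, mz_fraction = 0,
                             a2 = 0.5, c2 = 0, e2 = 0.5, seed = 19)
  A <- compute_grm(co$genotypes)$A
  sib <- A[cbind(1:600, 600 + 1:600)]
  expect_equal(mean(sib), 0.5, tolerance = 3 * sd(sib) / sqrt(600) / 0.5)
})
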