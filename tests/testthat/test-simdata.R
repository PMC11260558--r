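test_that("zero divergence gives identical parental pools, diagnostic mode fixes them", {
  f0 <- simulate_parental_panels(200, 0, seed = 1, diagnostic_frac = 0)
  expect_equal(f0$p_a, f0$p_b)
  f1 <- simulate_parental_panels(200, 0.2, seed = 2, diagnostic_frac = 1)
  expect_true(all(abs(f1$p_a - f1$p_b) == 1))
  expect_true(all(f1$diagnostic))
  expect_error(simulate_parental_panels(10, 1), "divergence_d")
  expect_error(simulate_parental_panels(0, 0.1), "n_loci")
})

test_that("parental divergence matches the Balding-Nichols expectation", {
  # oracle: E|pA - pB| under d = 0.3 with ancestral p ~ U(0.05, 0.95),
  # computed by brute-force averaging over 2e6 independent draws
  oracle <- 0.2476
  f <- simulate_parental_panels(5000, 0.3, seed = 42, diagnostic_frac = 0)
  expect_lt(abs(mean(abs(f$p_a - f$p_b)) - oracle), 0.015)
})

test_that("simulators are bit-identical under a fixed seed", {
  a <- simulate_parental_panels(100, 0.3, seed = 7)
  b <- simulate_parental_panels(100, 0.3, seed = 7)
  expect_identical(a, b)
  ga <- simulate_cross(a, "F2", 5, seed = 3)
  gb <- simulate_cross(b, "F2", 5, seed = 3)
  expect_identical(ga$geno, gb$geno)
  ma <- apply_missingness(ga, 0.3, seed = 9)
  mb <- apply_missingness(gb, 0.3, seed = 9)
  expect_identical(ma$geno, mb$geno)
})

test_that("cross classes sit at their (q, Q) centroids", {
  f <- simulate_parental_panels(2000, 0.3, seed = 11)
  for (cl in names(class_centroids)) {
    gm <- simulate_cross(f, cl, 4, seed = 20 + match(cl, names(class_centroids)))
    tr <- sim_truth(gm)
    cent <- class_centroids[[cl]]
    # binomial concentration: 4 sd of a mean over 2000 loci
    expect_lt(max(abs(tr$true_q - cent[1])), 4 * sqrt(0.25 / 4000) + 1e-12)
    expect_lt(max(abs(tr$true_Q - cent[2])), 4 * sqrt(0.25 / 2000) + 1e-12)
  }
  expect_error(simulate_cross(f, "F3", 1), "unknown ancestry class")
})

test_that("F1 on diagnostic loci is heterozygous everywhere with q = 0.5, Q = 1", {
  f <- simulate_parental_panels(300, 0.3, seed = 5, diagnostic_frac = 1)
  gm <- simulate_cross(f, "F1", 3, seed = 6)
  expect_true(all(gm$geno == 1L))
  tr <- sim_truth(gm)
  expect_equal(tr$true_q, rep(0.5, 3))
  expect_equal(tr$true_Q, rep(1, 3))
  pa <- simulate_cross(f, "pureA", 2, seed = 7)
  expect_equal(sim_truth(pa)$true_q, c(0, 0))
  expect_equal(sim_truth(pa)$true_Q, c(0, 0))
})

test_that("realized F2 interspecific ancestry concentrates at 1/2", {
  f <- simulate_parental_panels(1e5, 0.3, seed = 13, n_chrom = 20)
  gm <- simulate_cross(f, "F2", 1, seed = 14)
  expect_lt(abs(sim_truth(gm)$true_Q - 0.5), 0.01)
})

test_that("missingness masking hits its target rate and validates inputs", {
  f <- simulate_parental_panels(1000, 0.3, seed = 21)
  gm <- simulate_cross(f, "F2", 100, seed = 22)
  expect_identical(apply_missingness(gm, 0, seed = 1)$geno, gm$geno)
  masked <- apply_missingness(gm, 0.2, seed = 23)
  expect_lt(abs(mean(is.na(masked$geno)) - 0.2), 0.01)
  expect_error(apply_missingness(gm, 1), "rates")
})

test_that("sex block planting differentiates the sexes at the planted loci only", {
  f <- simulate_parental_panels(800, 0.3, seed = 31)
  gm <- simulate_cross(f, "pureA", 60, seed = 32)
  chr <- names(which.max(table(gm$chrom)))
  sb <- simulate_sex_block(gm, chr, 20, 0.8, seed = 33)
  expect_length(sb$sex_loci, 20)
  expect_equal(sort(as.integer(table(sb$sex))), c(30L, 30L))
  m_rows <- sb$sex == "M"
  planted <- match(sb$sex_loci, locus_ids(sb$geno))
  fdiff <- colMeans(sb$geno$geno[m_rows, planted, drop = FALSE]) / 2 -
    colMeans(sb$geno$geno[!m_rows, planted, drop = FALSE]) / 2
  expect_gt(mean(fdiff), 0.6)  # effect 0.8 up to binomial noise
  untouched <- setdiff(seq_len(n_loci(gm)), planted)
  expect_identical(sb$geno$geno[, untouched], gm$geno[, untouched])
  expect_error(simulate_sex_block(gm, chr, 10000, 0.5), "only")
  expect_error(simulate_sex_block(gm, "chrX", 5, 0.5), "not present")
})

test_that("river simulation returns a consistent distance matrix", {
  rv <- simulate_river(4, 10, 0.05, 20, seed = 41, n_loci = 50,
                       deme_size = 50, n_sample = 5)
  expect_equal(dim(rv$dist_km), c(4, 4))
  expect_true(isSymmetric(rv$dist_km))
  expect_equal(diag(rv$dist_km), setNames(rep(0, 4), rownames(rv$dist_km)))
  expect_equal(rv$dist_km[1, 4], 30)
  expect_equal(n_samples(rv$geno), 20L)
  expect_error(simulate_river(2, 10, 0.05, 10), "n_pops")
})

test_that("population split rejects daughters larger than the ancestor", {
  expect_error(simulate_split(10, 100, 0.7, 0.5, 10, 4, 4), "exceed 1")
  expect_error(simulate_split(10, 100, 0.4, 0.4, 10, 3, 4), "even")
})

test_that("an unsplit population shows no significant differentiation", {
  sp <- simulate_split(500, 200, 0.5, 0.5, 0, 16, 16, seed = 51)
  fst <- fst_bootstrap(sp$geno, attr(sp$geno, "pops"), B = 200, seed = 52)
  expect_true(fst$ci_low <= 0.005 && fst$ci_high >= -0.005)
  expect_lt(abs(fst$estimate), 0.05)
})
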