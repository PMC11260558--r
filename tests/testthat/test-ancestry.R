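test_that("parental frequency estimation applies additive smoothing", {
  g2 <- matrix(2L, 4, 1)  # two diploids per panel, all homozygous alternate
  gm2 <- gmat(g2, "chr1", 10L)
  f2 <- estimate_parental_freqs(gm2, c("refA", "refA", "refB", "refB"))
  expect_equal(f2$p_a, (4 + 0.5) / (4 + 1))   # = 0.9
  f0 <- estimate_parental_freqs(gm2, c("refA", "refA", "refB", "refB"),
                                pseudocount = 0)
  expect_equal(f0$p_a, 1)
  expect_error(estimate_parental_freqs(gm2, rep("refA", 4)), "non-empty")
})

test_that("panel frequencies match brute-force counting on a random fixture", {
  set.seed(10)
  g <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 10, 20)
  gm <- gmat(g, rep("chr1", 20), seq_len(20) * 4L)
  panel <- rep(c("refA", "refB"), 5)
  f <- estimate_parental_freqs(gm, panel, pseudocount = 0.5)
  for (j in c(1, 7, 20)) {
    v <- g[panel == "refA", j]
    expect_equal(f$p_a[j],
                 (sum(v, na.rm = TRUE) + 0.5) / (2 * sum(!is.na(v)) + 1))
  }
})

test_that("EM hits the exact corners on diagnostic loci", {
  f <- simulate_parental_panels(400, 0.3, seed = 15, diagnostic_frac = 1)
  f$p_a <- ifelse(f$p_a == 1, 1, 0)  # already diagnostic; use as-is
  f1 <- simulate_cross(f, "F1", 2, seed = 16)
  est <- estimate_qQ(f1, f)
  expect_equal(est$q, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(est$Q, c(1, 1), tolerance = 1e-6)
  pa <- simulate_cross(f, "pureA", 2, seed = 17)
  est_a <- estimate_qQ(pa, f)
  expect_equal(est_a$q, c(0, 0), tolerance = 1e-6)
  expect_equal(est_a$Q, c(0, 0), tolerance = 1e-6)
  expect_true(all(est$converged))
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  set.seed(18)
  f <- simulate_parental_panels(600, 0.3, seed = 18)
  for (cl in c("F2", "BC_A")) {
    gm <- simulate_cross(f, cl, 1, seed = 19)
    m <- match(locus_ids(gm), f$locus)
    lik <- sanderpop:::qq_likelihoods(gm$geno[1, ], f$p_a[m], f$p_b[m])
    em <- sanderpop:::qq_em(lik)
    expect_true(all(diff(em$trace) >= -1e-10))
  }
})

test_that("the q-Q invariant holds and estimates flag degenerate input", {
  f <- simulate_parental_panels(500, 0.3, seed = 25)
  gm <- simulate_cross(f, "BC_B", 5, seed = 26)
  est <- estimate_qQ(gm, f)
  expect_true(all(est$Q <= 2 * pmin(est$q, 1 - est$q) + 1e-9))
  # all genotypes missing -> invalid estimate
  g_na <- gmat(matrix(NA_integer_, 1, nrow(f)), f$chrom, f$pos)
  est_na <- estimate_qQ(g_na, f)
  expect_false(est_na$valid)
  expect_equal(est_na$n_informative, 0L)
})

test_that("hybrid classification follows the documented threshold rules", {
  # survey individuals with printed (q, Q): the single F1, two backcross
  # arithmetic cases, and a below-threshold pure fish
  expect_equal(as.character(classify_hybrid(0.550, 0.899)), "F1")
  expect_equal(as.character(classify_hybrid(0.143, 0.286)), "BC_sauger")  # Q - 2q = 0
  expect_equal(as.character(classify_hybrid(0.884, 0.231)), "BC_walleye") # Q + 2q = 1.999
  expect_equal(as.character(classify_hybrid(0.05, 0)), "sauger")
  expect_equal(as.character(classify_hybrid(0.95, 0.05)), "walleye")
  expect_equal(as.character(classify_hybrid(0.5, 0.5)), "F2")
  expect_equal(as.character(classify_hybrid(0.3, 0.95)), "hybrid_unassigned")
  expect_error(classify_hybrid(1.2, 0.5), "0, 1")
})

test_that("every point of the q-Q plane receives exactly one label", {
  grid <- expand.grid(q = seq(0, 1, by = 0.05), Q = seq(0, 1, by = 0.05))
  cls <- classify_hybrid(grid$q, grid$Q)
  expect_false(any(is.na(cls)))
  expect_true(all(cls %in% c("sauger", "walleye", "F1", "F2", "BC_sauger",
                             "BC_walleye", "hybrid_unassigned")))
})

test_that("locus bootstrap gives tight intervals on clean data and validates B", {
  f <- simulate_parental_panels(300, 0.3, seed = 35, diagnostic_frac = 1)
  f1 <- simulate_cross(f, "F1", 1, seed = 36)
  ci <- bootstrap_qQ(f1, f, 1, B = 100, seed = 37)
  expect_lt(diff(ci$ci_q), 1e-9)
  expect_lt(diff(ci$ci_Q), 1e-9)
  expect_error(bootstrap_qQ(f1, f, 1, B = 1), "B")
  # informative loci: interval width < 0.05 for an F1 at realistic divergence
  f2 <- simulate_parental_panels(5000, 0.3, seed = 38)
  f1b <- simulate_cross(f2, "F1", 1, seed = 39)
  ci2 <- bootstrap_qQ(f1b, f2, 1, B = 100, seed = 40)
  expect_lt(diff(ci2$ci_q), 0.05)
})

test_that("q error shrinks monotonically with locus count", {
  mae <- vapply(c(500, 2000, 8000), function(L) {
    f <- simulate_parental_panels(L, 0.3, seed = 50 + L)
    gm <- simulate_cross(f, "BC_A", 20, seed = 51 + L)
    est <- estimate_qQ(gm, f)
    mean(abs(est$q - sim_truth(gm)$true_q))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})
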