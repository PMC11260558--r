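test_that("joint SFS tabulation matches direct counting", {
  # single site: alternate counts (1, 0) out of (4, 4) chromosomes
  g <- matrix(c(1L, 0L, 0L, 0L), 4, 1)
  gm <- gmat(g, "chr1", 10L)
  s <- joint_sfs(gm, c("p1", "p1", "p2", "p2"), fold = FALSE)
  expect_equal(s$counts["1", "0"], 1)
  expect_equal(sum(s$counts), 1)
  # 100-site random fixture vs brute-force tabulation (no missing data)
  set.seed(50)
  g2 <- matrix(sample(0:2, 8 * 100, replace = TRUE), 8, 100)
  gm2 <- gmat(g2, rep("chr1", 100), seq_len(100))
  pops <- rep(c("p1", "p2"), each = 4)
  s2 <- joint_sfs(gm2, pops, fold = FALSE)
  brute <- matrix(0, 9, 9)
  for (l in seq_len(100)) {
    i <- sum(g2[1:4, l]); j <- sum(g2[5:8, l])
    brute[i + 1, j + 1] <- brute[i + 1, j + 1] + 1
  }
  expect_equal(unname(s2$counts), brute)
})

test_that("folding merges complementary cells and masks the redundant half", {
  m <- matrix(0, 5, 5)
  m[2, 1] <- 3   # cell (1, 0)
  m[4, 5] <- 7   # cell (3, 4), complement of (1, 0) for n1 = n2 = 4
  s <- new_joint_sfs(m, 4, 4, folded = FALSE)
  f <- fold_sfs(s)
  expect_equal(f$counts["1", "0"], 10)
  expect_true(f$mask["3", "4"])
  expect_true(f$mask["0", "0"])
  # total mass (over all cells) is conserved by folding
  expect_equal(sum(f$counts), sum(m))
  expect_identical(fold_sfs(f), f)
})

test_that("projection is the hypergeometric identity it claims to be", {
  # same-size projection is the identity
  m <- matrix(runif(25), 5, 5)
  s <- new_joint_sfs(m, 4, 4)
  expect_equal(project_sfs(s, 4, 4)$counts, s$counts, tolerance = 1e-12)
  # single entry at frequency 2/4 projected to n = 2: {1/6, 4/6, 1/6}
  m1 <- matrix(0, 5, 1)
  m1[3, 1] <- 1
  s1 <- new_joint_sfs(m1, 4, 0)
  p <- project_sfs(s1, 2, 0)
  expect_equal(unname(p$counts[, 1]), c(1 / 6, 4 / 6, 1 / 6))
  # mass conserved before corner masking
  set.seed(51)
  m2 <- matrix(runif(63), 9, 7)
  s2 <- new_joint_sfs(m2, 8, 6)
  p2 <- project_sfs(s2, 4, 4)
  expect_equal(sum(p2$counts), sum(m2), tolerance = 1e-10)
  expect_error(project_sfs(s2, 10, 4), "down")
  expect_error(project_sfs(fold_sfs(s2), 4, 4), "fold")
})

test_that("the expected spectrum has the neutral equilibrium marginal at T = 0", {
  s <- expected_joint_sfs("split_nomig", list(nu1 = 0.5, nu2 = 0.5, T = 0),
                          10, 10, n_grid = 100, fold = FALSE,
                          extrapolate = TRUE)
  marg <- rowSums(s$counts)
  expect_equal(unname(marg[2:10]), 1 / (1:9), tolerance = 0.01)
})

test_that("swapping the daughter sizes transposes the spectrum", {
  a <- expected_joint_sfs("split_nomig", list(nu1 = 0.3, nu2 = 0.6, T = 0.1),
                          6, 6, n_grid = 40, fold = FALSE)
  b <- expected_joint_sfs("split_nomig", list(nu1 = 0.6, nu2 = 0.3, T = 0.1),
                          6, 6, n_grid = 40, fold = FALSE)
  expect_equal(a$counts, t(b$counts), tolerance = 1e-10)
})

test_that("the migration backend reduces to the no-migration backend at m = 0", {
  p <- list(nu1 = 0.37, nu2 = 0.45, T = 0.13)
  a <- expected_joint_sfs("split_nomig", p, 8, 8, n_grid = 40)
  b <- expected_joint_sfs("split_mig", c(p, m12 = 0, m21 = 0), 8, 8,
                          n_grid = 40)
  expect_equal(b$counts[!b$mask], a$counts[!a$mask], tolerance = 1e-3)
  # migration pulls the populations together: less mass in private cells
  c2 <- expected_joint_sfs("split_mig", c(p, m12 = 5, m21 = 5), 8, 8,
                           n_grid = 40)
  priv <- function(s) sum(s$counts[1, -1]) + sum(s$counts[-1, 1])
  expect_lt(priv(c2) / sum(c2$counts[!c2$mask]),
            priv(b) / sum(b$counts[!b$mask]))
})

test_that("profiled theta maximises the composite likelihood", {
  p <- list(nu1 = 0.4, nu2 = 0.4, T = 0.08)
  m <- expected_joint_sfs("split_nomig", p, 8, 8, n_grid = 30)
  obs <- sample_sfs(m, 500, seed = 52)
  cl <- sanderpop:::composite_loglik(obs, m)
  for (eps in c(-0.01, 0.01)) {
    th <- cl$theta * (1 + eps)
    use <- !(obs$mask | m$mask)
    ll <- sum(obs$counts[use] * log(th * pmax(m$counts[use], 1e-300)) -
                th * m$counts[use])
    expect_lt(ll, cl$loglik)
  }
})

test_that("fitting the no-migration model to its own spectrum recovers the truth", {
  truth <- c(nu1 = 0.35, nu2 = 0.45, T = 0.12)
  m <- expected_joint_sfs("split_nomig", as.list(truth), 10, 10, n_grid = 60)
  obs <- m
  obs$counts <- obs$counts * 500
  fit <- fit_model(obs, "split_nomig", n_restarts = 2, seed = 53, n_grid = 60,
                   init = list(c(nu1 = 0.5, nu2 = 0.5, T = 0.05)))
  expect_lt(max(abs(fit$par - truth) / truth), 0.01)
  expect_equal(fit$theta_hat, 500, tolerance = 0.01)
  expect_error(fit_model(new_joint_sfs(matrix(0, 11, 11), 10, 10),
                         "split_nomig"), "empty")
})

test_that("likelihood-ratio machinery is sound", {
  fs <- structure(list(loglik = -100), class = "demographic_fit")
  fc <- structure(list(loglik = -100), class = "demographic_fit")
  l0 <- lrt(fs, fc)
  expect_equal(l0$statistic, 0)
  expect_equal(l0$p_value, 1)
  expect_false(l0$complex_supported)
  # chi-square tail: D = 10, df = 2 (independent table value)
  fc$loglik <- -95
  l1 <- lrt(fs, fc)
  expect_equal(l1$p_value, 0.006737947, tolerance = 1e-6)
  expect_true(l1$complex_supported)
  # clearly negative D flags an optimiser failure
  fc$loglik <- -101
  l2 <- lrt(fs, fc)
  expect_true(l2$optimizer_failure)
  expect_false(l2$complex_supported)
})

test_that("effective length follows the retention-fraction formula", {
  expect_equal(effective_length(1000, 100, 25), 250)
  expect_equal(effective_length(5000, 80, 80), 5000)
  expect_error(effective_length(1000, 0, 0), "positive")
  expect_error(effective_length(1000, 10, 20), "exceed")
  # synthetic pre/post-filter pair matches a manual recount
  f <- simulate_parental_panels(400, 0.3, seed = 54)
  gm <- apply_missingness(simulate_cross(f, "F2", 30, seed = 55), 0.3,
                          seed = 56)
  filt <- filter_loci(gm, maf_min = 0.1, max_locus_missing = 0.2)
  L <- effective_length(1e6, n_loci(gm), n_loci(filt))
  expect_equal(L, 1e6 * n_loci(filt) / 400)
})

test_that("real-time scaling is the stated arithmetic", {
  fit <- structure(list(par = c(nu1 = 0.4, nu2 = 0.4, T = 1),
                        theta_hat = 4),
                   class = "demographic_fit")
  sc <- scale_to_real(fit, mu = 1e-8, L = 1e8, generation_time = 3)
  expect_equal(sc$n_ref, 1)
  expect_equal(sc$t_generations, 2)
  expect_equal(sc$t_years, 6)
  # doubling mu halves N_ref and T_years
  sc2 <- scale_to_real(fit, mu = 2e-8, L = 1e8)
  expect_equal(sc2$n_ref, sc$n_ref / 2)
  expect_equal(sc2$t_years, sc$t_years / 2)
  expect_error(scale_to_real(fit, mu = 0, L = 1), "positive")
})

test_that("block bootstrap resamples whole blocks deterministically", {
  f <- simulate_parental_panels(300, 0.3, seed = 57, n_chrom = 5,
                                chrom_length = 3e6)
  gm <- simulate_cross(f, "F2", 20, seed = 58)
  pops <- rep(c("p1", "p2"), 10)
  b1 <- block_bootstrap(gm, pops, block_size = 1e6, B = 3, seed = 59)
  b2 <- block_bootstrap(gm, pops, block_size = 1e6, B = 3, seed = 59)
  expect_equal(b1[[2]]$counts, b2[[2]]$counts)
  expect_gt(attr(b1, "n_blocks"), 1)
  # replicate totals have expectation equal to the original total
  s0 <- sum(joint_sfs(gm, pops)$counts)
  reps <- block_bootstrap(gm, pops, block_size = 1e6, B = 200, seed = 60)
  tot <- vapply(reps, function(s) sum(s$counts), numeric(1))
  expect_lt(abs(mean(tot) - s0) / s0, 0.05)
  # one giant block: degenerate warning, identical replicates
  gm1 <- gm[, gm$chrom == gm$chrom[1]]
  expect_warning(r1 <- block_bootstrap(gm1, pops, block_size = 1e10, B = 2,
                                       seed = 61), "single block")
  expect_equal(r1[[1]]$counts, r1[[2]]$counts)
})

test_that("SFS text serialisation round-trips", {
  m <- expected_joint_sfs("split_nomig", list(nu1 = 0.4, nu2 = 0.4, T = 0.05),
                          6, 6, n_grid = 20)
  path <- withr::local_tempfile(fileext = ".sfs")
  write_sfs(m, path)
  back <- read_sfs(path)
  expect_equal(back$counts, m$counts, tolerance = 1e-10)
  expect_equal(back$mask, m$mask)
  expect_equal(back$folded, m$folded)
})

test_that("multinomial SFS sampling preserves totals and masks", {
  m <- expected_joint_sfs("split_nomig", list(nu1 = 0.4, nu2 = 0.4, T = 0.05),
                          6, 6, n_grid = 20)
  obs <- sample_sfs(m, 250, seed = 62)
  expect_equal(sum(obs$counts), 250)
  expect_true(all(obs$counts[obs$mask] == 0))
})
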