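test_that("Reich-Patterson estimator matches its closed forms and the loop oracle", {
  # fixed differences at every locus: h terms vanish, estimate is exactly 1
  fixed <- reich_patterson_fst(rep(10, 5), rep(10, 5), rep(0, 5), rep(10, 5))
  expect_equal(fixed$estimate, 1)
  # 5-locus toy table vs an independent loop evaluation of the formula
  a1 <- c(3, 5, 0, 7, 2); n1 <- c(10, 12, 10, 14, 10)
  a2 <- c(6, 1, 2, 7, 9); n2 <- c(12, 10, 8, 14, 12)
  est <- reich_patterson_fst(a1, n1, a2, n2)
  expect_equal(est$estimate, rp_fst_oracle(a1, n1, a2, n2))
  # single locus: ratio of sums equals the per-locus formula
  one <- reich_patterson_fst(a1[1], n1[1], a2[1], n2[1])
  expect_equal(one$estimate, rp_fst_oracle(a1[1], n1[1], a2[1], n2[1]))
  # loci with n < 2 in a population are skipped
  skip2 <- reich_patterson_fst(c(a1, 1), c(n1, 1), c(a2, 1), c(n2, 2))
  expect_equal(skip2$estimate, est$estimate)
  # all-monomorphic input is flagged undefined
  mono <- reich_patterson_fst(c(0, 0), c(8, 8), c(0, 0), c(8, 8))
  expect_true(is.nan(mono$estimate))
})

test_that("FST is invariant to population order and allele-coding flips", {
  set.seed(20)
  a1 <- rbinom(50, 20, 0.3); a2 <- rbinom(50, 20, 0.5)
  n1 <- rep(20, 50); n2 <- rep(20, 50)
  base <- reich_patterson_fst(a1, n1, a2, n2)$estimate
  expect_equal(reich_patterson_fst(a2, n2, a1, n1)$estimate, base)
  expect_equal(reich_patterson_fst(n1 - a1, n1, n2 - a2, n2)$estimate, base)
})

test_that("bootstrap FST detects divergence and validates inputs", {
  sp <- simulate_split(400, 100, 0.2, 0.2, 120, 16, 16, seed = 61)
  fst <- fst_bootstrap(sp$geno, attr(sp$geno, "pops"), B = 200, seed = 62)
  expect_true(fst$significant_nonzero)
  expect_true(fst$ci_low <= fst$estimate && fst$estimate <= fst$ci_high)
  expect_error(fst_bootstrap(sp$geno, attr(sp$geno, "pops"), B = 10), "B")
})

test_that("FST grows with divergence time", {
  est <- vapply(c(5, 40, 200), function(t_gens) {
    sp <- simulate_split(400, 100, 0.3, 0.3, t_gens, 16, 16,
                         seed = 70 + t_gens)
    cc <- attr(sp$geno, "pops")
    c1 <- allele_counts(sp$geno, cc == "pop1")
    c2 <- allele_counts(sp$geno, cc == "pop2")
    reich_patterson_fst(c1$alt, c1$n_chr, c2$alt, c2$n_chr)$estimate
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("genotype-covariance PCA separates planted clusters and normalises variance", {
  set.seed(30)
  g <- rbind(
    matrix(rbinom(10 * 100, 2, 0.2), 10, 100),
    matrix(rbinom(10 * 100, 2, 0.8), 10, 100)
  )
  gm <- gmat(g, rep("chr1", 100), seq_len(100) * 3L)
  p <- pca_genotypes(gm)
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-8)
  pc1 <- p$scores$PC1
  expect_true(max(pc1[1:10]) < min(pc1[11:20]) ||
                min(pc1[1:10]) > max(pc1[11:20]))
  # eigenvalues agree with a direct svd of the centred matrix
  x <- sanderpop:::impute_mean(gm)
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)$d^2 / (ncol(x) - 1)
  expect_equal(p$values[1:5], sv[1:5], tolerance = 1e-8)
  expect_error(pca_genotypes(gm[1:2, ]), "3 individuals")
})

test_that("diversity metrics follow their closed forms", {
  # n = 2 chromosomes: harmonic sum is 1, theta_w = S / total_sites
  g <- matrix(c(0L, 1L, 1L, 0L), 1, 4)  # one diploid, 2 segregating sites
  gm <- gmat(g, rep("chr1", 4), c(1L, 2L, 3L, 4L))
  d <- diversity_metrics(gm, "p", total_sites = 100)
  expect_equal(d$n_chr, 2)
  expect_equal(d$S, 2L)
  expect_equal(d$theta_w, 2 / 100)
  # per-site pi with n = 2: 2 * 0.5 * 0.5 * 2/1 = 1 per segregating site
  expect_equal(d$pi, 2 / 100)
  expect_equal(d$het_obs, 0.5)
  # monomorphic data: everything zero
  g0 <- gmat(matrix(0L, 4, 3), rep("chr1", 3), 1:3)
  d0 <- diversity_metrics(g0, rep("p", 4), total_sites = 10)
  expect_equal(d0$S, 0L)
  expect_equal(d0$theta_w, 0)
  expect_equal(d0$pi, 0)
  expect_equal(d0$het_obs, 0)
  expect_error(diversity_metrics(gm, "p", total_sites = 2), "total_sites")
})

test_that("theta_w and pi both recover theta on neutral-SFS draws", {
  # sites drawn from the neutral frequency spectrum (mass 1/j): by
  # construction theta_hat_W = S / (a_n * total) and E[pi] = theta
  set.seed(33)
  n_hap <- 20; S <- 4000; total <- 1e5
  j <- sample(1:(n_hap - 1), S, replace = TRUE, prob = 1 / (1:(n_hap - 1)))
  # build genotypes for 10 diploids carrying those allele counts
  g <- vapply(j, function(cnt) {
    hap <- sample(c(rep(1L, cnt), rep(0L, n_hap - cnt)))
    hap[seq(1, n_hap, 2)] + hap[seq(2, n_hap, 2)]
  }, integer(n_hap / 2))
  gm <- gmat(g, rep("chr1", S), seq_len(S))
  d <- diversity_metrics(gm, rep("p", n_hap / 2), total_sites = total)
  a_n <- sum(1 / (1:(n_hap - 1)))
  theta_true <- S / a_n / total
  expect_equal(d$theta_w, theta_true, tolerance = 1e-12)
  expect_lt(abs(d$pi - theta_true) / theta_true, 0.1)
})

test_that("river distances follow shortest paths on the network", {
  # one straight reach, sites at km 0, 5, 12
  net <- tibble::tibble(edge_id = "e1", node_from = "n1", node_to = "n2",
                        length_km = 12)
  sites <- tibble::tibble(site = c("a", "b", "c"), edge_id = "e1",
                          offset_km = c(0, 5, 12))
  d <- river_distance(net, sites)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["b", "c"], 7)
  expect_equal(d["a", "c"], 12)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  # Y-shaped network: distances hand-computed through the junction
  net_y <- tibble::tibble(
    edge_id = c("trunk", "left", "right"),
    node_from = c("mouth", "fork", "fork"),
    node_to = c("fork", "ltip", "rtip"),
    length_km = c(10, 4, 6)
  )
  sites_y <- tibble::tibble(site = c("s1", "s2", "s3"),
                            edge_id = c("trunk", "left", "right"),
                            offset_km = c(2, 3, 5))
  dy <- river_distance(net_y, sites_y)
  expect_equal(dy["s1", "s2"], 8 + 3)   # to fork, then down the left arm
  expect_equal(dy["s1", "s3"], 8 + 5)
  expect_equal(dy["s2", "s3"], 3 + 5)
  # permuting the site order permutes rows/columns consistently
  dy2 <- river_distance(net_y, sites_y[c(3, 1, 2), ])
  expect_equal(dy2[c("s1", "s2", "s3"), c("s1", "s2", "s3")], dy)
  # disconnected site errors by name
  net_d <- rbind(net_y, tibble::tibble(edge_id = "island", node_from = "i1",
                                       node_to = "i2", length_km = 3))
  sites_d <- rbind(sites_y, tibble::tibble(site = "lost", edge_id = "island",
                                           offset_km = 1))
  expect_error(river_distance(net_d, sites_d), "lost")
  expect_error(river_distance(net_y, tibble::tibble(site = "x", edge_id = "e9",
                                                    offset_km = 0)), "e9")
})

test_that("Mantel p-values match exhaustive enumeration and the perfect case", {
  set.seed(40)
  d <- as.matrix(dist(cbind(runif(4), runif(4))))
  gen <- d * 0.01 / (1 + d * 0.01)   # linearises back to a multiple of d
  # perfect correlation with random permutations: p = 1 / (n_perm + 1)
  r <- ibd_test(gen, d, n_perm = 199, seed = 41)
  expect_equal(r$mantel_r, 1, tolerance = 1e-12)
  expect_equal(r$p_value, 1 / 200)
  # exact enumeration equals a brute-force oracle over all 4! permutations
  set.seed(42)
  g2 <- as.matrix(dist(runif(4)))
  rex <- ibd_test(g2, d, exact = TRUE)
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  y <- g2 / (1 - g2)
  lt <- lower.tri(y)
  r_obs <- cor(y[lt], d[lt])
  r_all <- apply(perms, 1, function(p) {
    yp <- y[unlist(p), unlist(p)]
    cor(yp[lt], d[lt])
  })
  expect_equal(rex$p_value, mean(r_all >= r_obs - 1e-12))
  expect_equal(rex$n_perm, 24)
})

test_that("an FST of one is excluded from the IBD regression with a warning", {
  d <- as.matrix(dist(1:4))
  f <- as.matrix(dist(c(0.02, 0.09, 0.05, 0.12)))
  f[1, 2] <- f[2, 1] <- 1
  expect_warning(r <- ibd_test(f, d, n_perm = 99, seed = 43), "excluded")
  expect_equal(r$n_excluded, 1L)
  expect_true(is.finite(r$slope))
})

test_that("high migration flattens isolation by distance", {
  rv <- simulate_river(5, 20, 0.4, 150, seed = 45, n_loci = 300,
                       deme_size = 200, n_sample = 15)
  fm <- fst_matrix(rv$geno, rv$pops)
  r <- ibd_test(fm$matrix, rv$dist_km, n_perm = 99, seed = 46)
  expect_lt(abs(r$slope), 5e-4)
})
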