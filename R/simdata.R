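#' Simulate divergent parental allele-frequency panels
#'
#' Draws per-locus allele frequencies for two parental gene pools (species A,
#' e.g. sauger, and species B, e.g. walleye) around a shared ancestral
#' frequency using the Balding-Nichols model: given ancestral frequency `p`
#' and differentiation `d`, each species' frequency is an independent
#' `Beta(p(1-d)/d, (1-p)(1-d)/d)` draw. A configurable fraction of loci is
#' made diagnostic (fixed for opposite alleles) so ancestry identifiability
#' can be stress-tested.
#'
#' Loci receive synthetic 1-based coordinates spread uniformly over
#' `n_chrom` chromosomes of `chrom_length` bp, so coordinate-aware steps
#' (sex-block planting, 1-Mb block bootstrap) are exercisable downstream.
#'
#' @param n_loci number of loci (>= 1).
#' @param divergence_d Balding-Nichols differentiation parameter in `[0, 1)`.
#'   `0` means the two pools share every frequency exactly.
#' @param seed optional integer seed; fixed seed gives identical output.
#' @param diagnostic_frac fraction of loci forced diagnostic (`|pA - pB| = 1`).
#' @param n_chrom,chrom_length synthetic genome layout.
#' @return tibble of class `parental_freqs` with columns `locus`, `chrom`,
#'   `pos`, `p_a`, `p_b` (alternate-allele frequency in each species) and
#'   `diagnostic`.
#' @export
simulate_parental_panels <- function(n_loci, divergence_d, seed = NULL,
                                     diagnostic_frac = 0.05,
                                     n_chrom = 10, chrom_length = 5e6) {
  if (n_loci < 1) abort("`n_loci` must be >= 1.")
  if (divergence_d < 0 || divergence_d >= 1) {
    abort("`divergence_d` must lie in [0, 1).")
  }
  if (diagnostic_frac < 0 || diagnostic_frac > 1) {
    abort("`diagnostic_frac` must lie in [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)

  coord <- synth_coords(n_loci, n_chrom, chrom_length)
  p_anc <- runif(n_loci, 0.05, 0.95)
  if (divergence_d == 0) {
    p_a <- p_anc
    p_b <- p_anc
  } else {
    shape <- (1 - divergence_d) / divergence_d
    p_a <- rbeta(n_loci, p_anc * shape, (1 - p_anc) * shape)
    p_b <- rbeta(n_loci, p_anc * shape, (1 - p_anc) * shape)
  }
  diag_flag <- rep(FALSE, n_loci)
  n_diag <- round(diagnostic_frac * n_loci)
  if (n_diag > 0) {
    idx <- sample.int(n_loci, n_diag)
    diag_flag[idx] <- TRUE
    flip <- runif(n_diag) < 0.5
    p_a[idx] <- ifelse(flip, 1, 0)
    p_b[idx] <- ifelse(flip, 0, 1)
  }
  out <- tibble(
    locus = paste0(coord$chrom, ":", coord$pos),
    chrom = coord$chrom, pos = coord$pos,
    p_a = p_a, p_b = p_b, diagnostic = diag_flag
  )
  class(out) <- c("parental_freqs", class(out))
  out
}

# uniform random sorted coordinates over a synthetic genome
synth_coords <- function(n_loci, n_chrom, chrom_length) {
  chrom <- sort(sample.int(n_chrom, n_loci, replace = TRUE))
  pos <- integer(n_loci)
  for (c in unique(chrom)) {
    k <- sum(chrom == c)
    pos[chrom == c] <- sort(sample.int(chrom_length, k))
  }
  list(chrom = sprintf("chr%d", chrom), pos = pos)
}

#' Simulate genotypes for a hybrid-cross ancestry class
#'
#' For each individual and locus an ancestry-state pair is drawn according to
#' the cross type (`pureA`: AA everywhere; `F1`: AB everywhere; `F2`:
#' AA/AB/BB with probabilities 1/4, 1/2, 1/4; `BC_A`: AA/AB with 1/2 each;
#' `BC_B`: BB/AB with 1/2 each), then each allele is drawn from the parental
#' pool its ancestry points to. The realized admixture proportion `q`
#' (fraction of species-B ancestry copies) and interspecific ancestry `Q`
#' (fraction of loci with one copy from each species) are recorded per
#' individual and available via [sim_truth()].
#'
#' @param freqs a `parental_freqs` tibble from [simulate_parental_panels()].
#' @param class one of `"pureA"`, `"pureB"`, `"F1"`, `"F2"`, `"BC_A"`,
#'   `"BC_B"`.
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @param prefix sample-id prefix.
#' @return a [gmat] with a `truth` attribute (tibble: `sample`, `class`,
#'   `true_q`, `true_Q`).
#' @export
simulate_cross <- function(freqs, class, n, seed = NULL, prefix = class) {
  classes <- c("pureA", "pureB", "F1", "F2", "BC_A", "BC_B")
  if (!class %in% classes) {
    abort(sprintf("unknown ancestry class '%s'", class))
  }
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(freqs)
  # ancestry of the two allele copies: 0 = species A, 1 = species B
  anc <- switch(class,
    pureA = function() matrix(0L, n, 2 * L),
    pureB = function() matrix(1L, n, 2 * L),
    F1 = function() matrix(rep(c(0L, 1L), each = 1, times = n * L), n, 2 * L, byrow = TRUE),
    F2 = function() matrix(rbinom(2 * n * L, 1, 0.5), n, 2 * L),
    BC_A = function() {
      # one gamete from an F1 (coin flip), one from pure A
      m <- matrix(0L, n, 2 * L)
      m[, seq(2, 2 * L, by = 2)] <- rbinom(n * L, 1, 0.5)
      m
    },
    BC_B = function() {
      m <- matrix(1L, n, 2 * L)
      m[, seq(2, 2 * L, by = 2)] <- rbinom(n * L, 1, 0.5)
      m
    }
  )()
  a1 <- anc[, seq(1, 2 * L, by = 2), drop = FALSE]
  a2 <- anc[, seq(2, 2 * L, by = 2), drop = FALSE]
  pa <- matrix(freqs$p_a, n, L, byrow = TRUE)
  pb <- matrix(freqs$p_b, n, L, byrow = TRUE)
  p1 <- ifelse(a1 == 1L, pb, pa)
  p2 <- ifelse(a2 == 1L, pb, pa)
  g <- matrix(rbinom(n * L, 1, p1) + rbinom(n * L, 1, p2), n, L)
  rownames(g) <- sprintf("%s_%03d", prefix, seq_len(n))
  out <- gmat(g, freqs$chrom, freqs$pos)
  truth <- tibble(
    sample = rownames(g),
    class = class,
    true_q = rowSums(a1 + a2) / (2 * L),
    true_Q = rowMeans(a1 != a2)
  )
  attr(out, "truth") <- truth
  out
}

#' Ground truth attached to a simulated object
#'
#' @param x an object produced by a `simulate_*` function.
#' @return the `truth` tibble/list recorded by the simulator.
#' @export
sim_truth <- function(x) attr(x, "truth")

#' Simulate an ancestral population splitting into two drifting populations
#'
#' Coalescent simulation of the divergence model used for demographic
#' inference: an ancestral population of `n_ref` diploids at neutral
#' equilibrium splits `t_gens` generations ago into two isolated populations
#' of relative sizes `nu1` and `nu2` (so `nu1 + nu2 <= 1`, the daughters
#' cannot outnumber the ancestor). Each locus is an independent genealogy of
#' `n1 + n2` sampled haplotypes carrying a single segregating mutation placed
#' uniformly on the tree (branch-length weighted), emulating a SNP dataset.
#'
#' @param n_loci number of SNP loci.
#' @param n_ref ancestral diploid population size.
#' @param nu1,nu2 daughter sizes relative to `n_ref`; `nu1 + nu2 <= 1`.
#' @param t_gens divergence time in generations (0 = panmixia).
#' @param n1,n2 sampled haplotypes per population (must be even; haplotypes
#'   are paired into diploids).
#' @param mu per-site per-generation mutation rate, recorded in the truth
#'   record (genotypes are conditioned on one SNP per locus).
#' @param seed optional integer seed.
#' @param n_chrom,chrom_length synthetic genome layout.
#' @return list with elements `geno` (a [gmat]; population labels in the
#'   `pops` attribute), `sfs` (realized folded [joint_sfs]) and `truth`
#'   (generating parameters).
#' @export
simulate_split <- function(n_loci, n_ref, nu1, nu2, t_gens, n1, n2,
                           mu = 5.97e-9, seed = NULL,
                           n_chrom = 10, chrom_length = 5e6) {
  if (nu1 + nu2 > 1 + 1e-12) {
    abort("`nu1 + nu2` must not exceed 1: the daughter populations cannot outnumber the ancestral population.")
  }
  if (nu1 <= 0 || nu2 <= 0) abort("`nu1` and `nu2` must be positive.")
  if (n1 %% 2 != 0 || n2 %% 2 != 0) {
    abort("`n1` and `n2` must be even haplotype counts.")
  }
  if (!is.null(seed)) set.seed(seed)
  t_scaled <- t_gens / (2 * n_ref)  # coalescent time in units of 2*n_ref generations
  coord <- synth_coords(n_loci, n_chrom, chrom_length)
  hap <- matrix(0L, n1 + n2, n_loci)
  for (l in seq_len(n_loci)) {
    segs <- sim_split_genealogy(n1, n2, nu1, nu2, t_scaled)
    pick <- sample.int(length(segs$len), 1, prob = segs$len)
    hap[segs$desc[[pick]], l] <- 1L
  }
  # pair haplotypes into diploids within each population
  idx1 <- seq_len(n1)
  idx2 <- n1 + seq_len(n2)
  g <- rbind(
    hap[idx1[c(TRUE, FALSE)], , drop = FALSE] + hap[idx1[c(FALSE, TRUE)], , drop = FALSE],
    hap[idx2[c(TRUE, FALSE)], , drop = FALSE] + hap[idx2[c(FALSE, TRUE)], , drop = FALSE]
  )
  pops <- rep(c("pop1", "pop2"), c(n1 / 2, n2 / 2))
  rownames(g) <- sprintf("%s_%03d", pops, c(seq_len(n1 / 2), seq_len(n2 / 2)))
  geno <- gmat(g, coord$chrom, coord$pos)
  attr(geno, "pops") <- setNames(pops, rownames(g))
  sfs <- joint_sfs(geno, pops, fold = TRUE)
  truth <- list(
    n_ref = n_ref, nu1 = nu1, nu2 = nu2, t_gens = t_gens,
    t_scaled = t_scaled, mu = mu, n1 = n1, n2 = n2,
    theta = 4 * n_ref * mu
  )
  attr(geno, "truth") <- truth
  list(geno = geno, sfs = sfs, truth = truth)
}

# Structured coalescent for the two-population split, time in units of
# 2*n_ref generations (pairwise rate 1/nu within a daughter, 1 in the
# ancestor). Returns branch segments as descendant-id sets plus lengths.
sim_split_genealogy <- function(n1, n2, nu1, nu2, t_split) {
  desc <- vector("list", 2 * (n1 + n2))
  len <- numeric(2 * (n1 + n2))
  n_seg <- 0L
  record <- function(d, l) {
    n_seg <<- n_seg + 1L
    desc[[n_seg]] <<- d
    len[n_seg] <<- l
  }
  # evolve one population from `t0` to `t_end` (Inf allowed)
  evolve <- function(lin, birth, nu, t0, t_end) {
    t_cur <- t0
    while (length(lin) > 1) {
      rate <- choose(length(lin), 2) / nu
      t_next <- t_cur + stats::rexp(1, rate)
      if (t_next > t_end) break
      pair <- sample.int(length(lin), 2)
      record(lin[[pair[1]]], t_next - birth[pair[1]])
      record(lin[[pair[2]]], t_next - birth[pair[2]])
      lin[[pair[1]]] <- c(lin[[pair[1]]], lin[[pair[2]]])
      birth[pair[1]] <- t_next
      lin[[pair[2]]] <- NULL
      birth <- birth[-pair[2]]
      t_cur <- t_next
    }
    list(lin = lin, birth = birth)
  }
  p1 <- evolve(lapply(seq_len(n1), identity), rep(0, n1), nu1, 0, t_split)
  p2 <- evolve(lapply(n1 + seq_len(n2), identity), rep(0, n2), nu2, 0, t_split)
  anc <- evolve(c(p1$lin, p2$lin), c(p1$birth, p2$birth), 1, t_split, Inf)
  # the root lineage has no branch above it
  stopifnot(length(anc$lin) == 1)
  list(desc = desc[seq_len(n_seg)], len = len[seq_len(n_seg)])
}

#' Mask genotypes as missing, GBS-style
#'
#' Sets genotype calls to missing independently, with a per-locus target
#' rate, emulating the uneven locus coverage of reduced-representation
#' sequencing (the emulated datasets have ~20% median missingness per locus).
#'
#' @param gm a [gmat].
#' @param locus_rates scalar or per-locus vector of missingness rates in
#'   `[0, 1)`.
#' @param seed optional integer seed; the same seed yields the same mask.
#' @return a [gmat] with additional missing genotypes.
#' @export
apply_missingness <- function(gm, locus_rates, seed = NULL) {
  if (any(locus_rates < 0) || any(locus_rates >= 1)) {
    abort("missingness rates must lie in [0, 1).")
  }
  rates <- rep_len(locus_rates, n_loci(gm))
  if (!is.null(seed)) set.seed(seed)
  g <- gm$geno
  mask <- matrix(runif(length(g)) < rep(rates, each = nrow(g)), nrow(g))
  g[mask] <- NA_integer_
  out <- gmat(g, gm$chrom, gm$pos)
  attributes_keep(out, gm)
}

# carry simulator attributes across genotype-preserving transforms
attributes_keep <- function(new, old) {
  for (a in c("truth", "pops", "sex", "sex_loci")) {
    if (!is.null(attr(old, a))) attr(new, a) <- attr(old, a)
  }
  new
}

#' Plant a sex-differentiated locus block
#'
#' Assigns sexes 50/50 and rewrites the genotypes of `n_sexloci` randomly
#' chosen loci on one chromosome so that the allele frequency differs
#' between the sexes by `effect` (male frequency `0.5 + effect/2`, female
#' `0.5 - effect/2`). All other loci are untouched. This mimics a
#' differentiated sex-linked region concentrated on a single chromosome.
#'
#' @param gm a [gmat].
#' @param chromosome chromosome id carrying the block.
#' @param n_sexloci number of loci to plant (must not exceed the loci
#'   available on `chromosome`).
#' @param effect male-female allele frequency difference in `[0, 1]`.
#' @param seed optional integer seed.
#' @return list with `geno` (modified [gmat]), `sex` (named character vector
#'   `"M"`/`"F"`) and `sex_loci` (planted locus ids).
#' @export
simulate_sex_block <- function(gm, chromosome, n_sexloci, effect, seed = NULL) {
  on_chr <- which(gm$chrom == chromosome)
  if (!length(on_chr)) abort(sprintf("chromosome '%s' not present", chromosome))
  if (n_sexloci > length(on_chr)) {
    abort(sprintf(
      "requested %d sex loci but chromosome '%s' has only %d loci",
      n_sexloci, chromosome, length(on_chr)
    ))
  }
  if (effect < 0 || effect > 1) abort("`effect` must lie in [0, 1].")
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples(gm)
  sex <- sample(rep(c("M", "F"), length.out = n))
  names(sex) <- sample_ids(gm)
  planted <- sort(sample(on_chr, n_sexloci))
  p_m <- 0.5 + effect / 2
  p_f <- 0.5 - effect / 2
  g <- gm$geno
  p <- ifelse(sex == "M", p_m, p_f)
  for (j in planted) {
    keep_na <- is.na(g[, j])
    g[, j] <- rbinom(n, 2, p)
    g[keep_na, j] <- NA_integer_
  }
  out <- gmat(g, gm$chrom, gm$pos)
  attr(out, "sex") <- sex
  attr(out, "sex_loci") <- colnames(gm$geno)[planted]
  list(geno = out, sex = sex, sex_loci = colnames(gm$geno)[planted])
}

#' Simulate stepping-stone populations along a linear river
#'
#' Forward Wright-Fisher simulation of `n_pops` demes on a line, each of
#' `deme_size` diploids, exchanging migrants at rate `migration_rate` with
#' adjacent demes, starting from a shared ancestral frequency per locus.
#' Returns sampled genotypes and the along-river distance matrix implied by
#' even spacing.
#'
#' @param n_pops number of demes (>= 3).
#' @param spacing_km distance between adjacent demes.
#' @param migration_rate per-generation fraction of migrants exchanged with
#'   neighbours.
#' @param generations number of generations of drift.
#' @param seed optional integer seed.
#' @param n_loci,deme_size,n_sample simulation sizes.
#' @return list with `geno` (a [gmat]; deme labels in the `pops` attribute),
#'   `pops` (per-sample deme label) and `dist_km` (symmetric distance
#'   matrix).
#' @export
simulate_river <- function(n_pops, spacing_km, migration_rate, generations,
                           seed = NULL, n_loci = 500, deme_size = 100,
                           n_sample = 20) {
  if (n_pops < 3) abort("`n_pops` must be >= 3 for a stepping-stone river.")
  if (migration_rate < 0 || migration_rate > 1) {
    abort("`migration_rate` must lie in [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(runif(n_loci, 0.1, 0.9), n_loci, n_pops)
  m <- migration_rate
  for (g in seq_len(generations)) {
    left <- cbind(p[, 1], p[, -n_pops, drop = FALSE])
    right <- cbind(p[, -1, drop = FALSE], p[, n_pops])
    p_mig <- (1 - m) * p + (m / 2) * (left + right)
    p <- matrix(
      rbinom(n_loci * n_pops, 2 * deme_size, p_mig) / (2 * deme_size),
      n_loci, n_pops
    )
  }
  coord <- synth_coords(n_loci, 10, 5e6)
  geno <- matrix(NA_integer_, n_pops * n_sample, n_loci)
  pops <- rep(sprintf("site%02d", seq_len(n_pops)), each = n_sample)
  for (k in seq_len(n_pops)) {
    rows <- (k - 1) * n_sample + seq_len(n_sample)
    geno[rows, ] <- matrix(
      rbinom(n_sample * n_loci, 2, rep(p[, k], each = n_sample)),
      n_sample, n_loci
    )
  }
  rownames(geno) <- sprintf("%s_%02d", pops, rep(seq_len(n_sample), n_pops))
  gm <- gmat(geno, coord$chrom, coord$pos)
  attr(gm, "pops") <- setNames(pops, rownames(geno))
  d <- spacing_km * abs(outer(seq_len(n_pops), seq_len(n_pops), "-"))
  dimnames(d) <- list(sprintf("site%02d", seq_len(n_pops)), sprintf("site%02d", seq_len(n_pops)))
  list(geno = gm, pops = pops, dist_km = d)
}
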