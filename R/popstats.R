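#' Reich-Patterson FST from allele counts
#'
#' The unbiased allele-count estimator of Reich et al. combined across loci
#' as a ratio of sums. Per locus, with alternate counts `a` out of `n`
#' called chromosomes and `h = a(n - a) / (n(n - 1))`:
#' `N = (a1/n1 - a2/n2)^2 - h1/n1 - h2/n2` and `D = N + h1 + h2`; the
#' estimate is `sum(N) / sum(D)`. Loci with fewer than two called
#' chromosomes in either population are skipped.
#'
#' @param a1,n1 per-locus alternate-allele count and called chromosomes in
#'   population 1.
#' @param a2,n2 likewise for population 2.
#' @return an `fst_result`: list with `estimate`, `n_loci`, `ci_low`,
#'   `ci_high`, `significant_nonzero` (the latter three `NA` until
#'   bootstrapped) and the per-locus `num`/`den` terms.
#' @export
reich_patterson_fst <- function(a1, n1, a2, n2) {
  stopifnot(length(a1) == length(n1), length(a2) == length(n2),
            length(a1) == length(a2))
  use <- n1 >= 2 & n2 >= 2
  a1 <- a1[use]; n1 <- n1[use]; a2 <- a2[use]; n2 <- n2[use]
  h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
  h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
  num <- (a1 / n1 - a2 / n2)^2 - h1 / n1 - h2 / n2
  den <- num + h1 + h2
  est <- if (sum(den) == 0) NaN else sum(num) / sum(den)
  structure(
    list(
      estimate = est, n_loci = length(num),
      ci_low = NA_real_, ci_high = NA_real_,
      significant_nonzero = NA, num = num, den = den
    ),
    class = "fst_result"
  )
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> FST = %.5f over %d loci", x$estimate, x$n_loci))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" [95%% CI %.5f, %.5f]%s", x$ci_low, x$ci_high,
                if (isTRUE(x$significant_nonzero)) " *" else ""))
  }
  cat("\n")
  invisible(x)
}

#' FST between two populations with a locus bootstrap
#'
#' Computes the Reich-Patterson estimate between two groups of individuals
#' and resamples loci with replacement to obtain a percentile confidence
#' interval; the difference from zero is called significant when the
#' interval excludes zero.
#'
#' @param gm a [gmat].
#' @param pops per-sample population labels (exactly two distinct values
#'   among the samples used).
#' @param B bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return an `fst_result` with the CI fields filled in.
#' @export
fst_bootstrap <- function(gm, pops, B = 1000, level = 0.95, seed = NULL) {
  if (B < 100) abort("`B` must be >= 100.")
  pops <- as.character(pops)
  lv <- unique(pops[!is.na(pops)])
  if (length(lv) != 2) abort("`pops` must contain exactly two populations.")
  if (!is.null(seed)) set.seed(seed)
  c1 <- allele_counts(gm, !is.na(pops) & pops == lv[1])
  c2 <- allele_counts(gm, !is.na(pops) & pops == lv[2])
  res <- reich_patterson_fst(c1$alt, c1$n_chr, c2$alt, c2$n_chr)
  L <- res$n_loci
  if (L == 0) return(res)
  boot <- vapply(seq_len(B), function(b) {
    idx <- sample.int(L, L, replace = TRUE)
    s <- sum(res$den[idx])
    if (s == 0) NA_real_ else sum(res$num[idx]) / s
  }, numeric(1))
  a <- (1 - level) / 2
  ci <- quantile(boot, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  res$ci_low <- ci[1]
  res$ci_high <- ci[2]
  res$significant_nonzero <- ci[1] > 0 || ci[2] < 0
  res$boot <- boot
  res
}

#' Pairwise FST matrix over populations
#'
#' @param gm a [gmat].
#' @param pops per-sample population labels.
#' @param bootstrap if `TRUE`, attach a bootstrap CI per pair.
#' @param B,level,seed bootstrap settings (see [fst_bootstrap()]).
#' @return list with `matrix` (symmetric, zero diagonal) and `pairs`
#'   (tibble: `pop1`, `pop2`, `fst`, optional CI columns).
#' @export
fst_matrix <- function(gm, pops, bootstrap = FALSE, B = 1000, level = 0.95,
                       seed = NULL) {
  pops <- as.character(pops)
  lv <- sort(unique(pops[!is.na(pops)]))
  if (length(lv) < 2) abort("need at least two populations.")
  if (!is.null(seed)) set.seed(seed)
  counts <- lapply(lv, function(p) allele_counts(gm, !is.na(pops) & pops == p))
  names(counts) <- lv
  m <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  pairs <- list()
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j <= i) next
      if (bootstrap) {
        r <- fst_bootstrap(gm, ifelse(pops %in% lv[c(i, j)], pops, NA), B = B,
                           level = level)
        row <- tibble(pop1 = lv[i], pop2 = lv[j], fst = r$estimate,
                      ci_low = r$ci_low, ci_high = r$ci_high,
                      significant_nonzero = r$significant_nonzero)
      } else {
        r <- reich_patterson_fst(counts[[i]]$alt, counts[[i]]$n_chr,
                                 counts[[j]]$alt, counts[[j]]$n_chr)
        row <- tibble(pop1 = lv[i], pop2 = lv[j], fst = r$estimate)
      }
      m[i, j] <- m[j, i] <- r$estimate
      pairs[[length(pairs) + 1]] <- row
    }
  }
  list(matrix = m, pairs = bind_rows(pairs))
}

#' PCA of the genotype covariance matrix
#'
#' Missing genotypes are mean-imputed per locus, loci are centred, and the
#' individual-by-individual genotype covariance matrix is
#' eigendecomposed. Principal components are ordered by variance explained.
#'
#' @param gm a [gmat] with at least 3 individuals.
#' @param n_pcs number of PCs returned in the score table.
#' @return a `pca_geno`: list with `scores` (tibble: `sample`, `PC1`, ...),
#'   `var_explained` (all eigenvalue fractions), `values` (eigenvalues) and
#'   `constant` (flag: no genotypic variance at all).
#' @export
pca_genotypes <- function(gm, n_pcs = 4) {
  if (n_samples(gm) < 3) abort("PCA needs at least 3 individuals.")
  x <- impute_mean(gm)
  x <- sweep(x, 2, colMeans(x))
  cv <- tcrossprod(x) / max(1, ncol(x) - 1)
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  constant <- sum(vals) <= 0
  vf <- if (constant) rep(0, length(vals)) else vals / sum(vals)
  n_pcs <- min(n_pcs, length(vals))
  sc <- e$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(n_pcs)]), n_pcs)
  colnames(sc) <- paste0("PC", seq_len(n_pcs))
  structure(
    list(
      scores = as_tibble(cbind(tibble(sample = sample_ids(gm)), as_tibble(sc))),
      var_explained = vf, values = vals, constant = constant
    ),
    class = "pca_geno"
  )
}

#' @export
print.pca_geno <- function(x, ...) {
  cat(sprintf(
    "<pca_geno> %d individuals; PC1-PC4 variance: %s\n",
    nrow(x$scores),
    paste(sprintf("%.1f%%", 100 * head(x$var_explained, 4)), collapse = ", ")
  ))
  invisible(x)
}

#' Per-population diversity metrics
#'
#' Watterson's theta and nucleotide diversity (pi) per site, plus observed
#' and expected heterozygosity. Because the variant loci come from a
#' SNP-only matrix, a total site count (variant plus invariant) must be
#' supplied as the per-site denominator. With `S` segregating sites and `n`
#' the rounded mean number of called chromosomes:
#' `theta_w = S / sum(1/i, i = 1..n-1) / total_sites`;
#' `pi = sum(2 p (1 - p) n_l / (n_l - 1)) / total_sites` over sites with
#' per-site frequency `p` and call count `n_l`; observed heterozygosity is
#' the mean over individuals of (het calls / called sites); expected
#' heterozygosity is the mean of `2p(1-p)` over variant loci.
#'
#' @param gm a [gmat].
#' @param pops per-sample population labels.
#' @param total_sites total number of sites (variant + invariant) the loci
#'   were ascertained from; must be at least the number of variant loci.
#' @return a `diversity_report` tibble: `pop`, `n_chr`, `S`, `theta_w`,
#'   `pi`, `het_obs`, `het_exp`.
#' @export
diversity_metrics <- function(gm, pops, total_sites) {
  pops <- as.character(pops)
  if (total_sites < n_loci(gm)) {
    abort("`total_sites` must be at least the number of variant loci.")
  }
  res <- map_dfr(sort(unique(pops[!is.na(pops)])), function(p) {
    rows <- !is.na(pops) & pops == p
    cc <- allele_counts(gm, rows)
    called <- cc$n_chr >= 2
    a <- cc$alt[called]
    nl <- cc$n_chr[called]
    poly <- a > 0 & a < nl
    S <- sum(poly)
    n <- round(mean(nl))
    if (is.na(n) || n < 2) {
      return(tibble(pop = p, n_chr = n, S = S, theta_w = NA_real_,
                    pi = NA_real_, het_obs = NA_real_, het_exp = NA_real_))
    }
    harm <- sum(1 / seq_len(n - 1))
    theta_w <- S / harm / total_sites
    pfreq <- a / nl
    pi <- sum(2 * pfreq * (1 - pfreq) * nl / (nl - 1)) / total_sites
    g <- gm$geno[rows, , drop = FALSE]
    het_i <- rowSums(g == 1L, na.rm = TRUE) / rowSums(!is.na(g))
    het_obs <- mean(het_i, na.rm = TRUE)
    het_exp <- if (any(poly)) mean(2 * pfreq[poly] * (1 - pfreq[poly])) else 0
    tibble(pop = p, n_chr = n, S = S, theta_w = theta_w, pi = pi,
           het_obs = het_obs, het_exp = het_exp)
  })
  class(res) <- c("diversity_report", class(res))
  res
}

#' Along-network river distances between sites
#'
#' Shortest-path distances along a river network given as an edge list with
#' lengths. Sites are located on edges by an offset from the edge's
#' `node_from`; each site becomes a vertex splitting its edge, and distances
#' are shortest paths on the resulting weighted graph.
#'
#' @param network tibble/data frame with columns `edge_id`, `node_from`,
#'   `node_to`, `length_km`.
#' @param sites tibble/data frame with columns `site`, `edge_id`,
#'   `offset_km` (0 <= offset <= edge length).
#' @return symmetric site-by-site distance matrix (km) with zero diagonal.
#' @export
river_distance <- function(network, sites) {
  network <- as_tibble(network)
  sites <- as_tibble(sites)
  need_n <- c("edge_id", "node_from", "node_to", "length_km")
  need_s <- c("site", "edge_id", "offset_km")
  if (!all(need_n %in% names(network))) {
    abort(sprintf("network needs columns: %s", paste(need_n, collapse = ", ")))
  }
  if (!all(need_s %in% names(sites))) {
    abort(sprintf("sites needs columns: %s", paste(need_s, collapse = ", ")))
  }
  bad_edge <- setdiff(sites$edge_id, network$edge_id)
  if (length(bad_edge)) {
    abort(sprintf("site edge id(s) not in network: %s",
                  paste(bad_edge, collapse = ", ")))
  }
  edges <- list()
  for (k in seq_len(nrow(network))) {
    e <- network[k, ]
    on_e <- sites[sites$edge_id == e$edge_id, ]
    if (any(on_e$offset_km < 0 | on_e$offset_km > e$length_km)) {
      abort(sprintf("site offset outside edge '%s'", e$edge_id))
    }
    ord <- order(on_e$offset_km)
    chain_v <- c(e$node_from, paste0("site::", on_e$site[ord]), e$node_to)
    chain_d <- diff(c(0, on_e$offset_km[ord], e$length_km))
    for (s in seq_along(chain_d)) {
      edges[[length(edges) + 1]] <- tibble(
        from = chain_v[s], to = chain_v[s + 1], weight = chain_d[s]
      )
    }
  }
  ed <- bind_rows(edges)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  vsite <- paste0("site::", sites$site)
  d <- igraph::distances(g, v = vsite, to = vsite,
                         weights = igraph::E(g)$weight)
  dimnames(d) <- list(sites$site, sites$site)
  if (any(!is.finite(d))) {
    bad <- sites$site[apply(!is.finite(d), 1, any)]
    abort(sprintf("site(s) disconnected from the network: %s",
                  paste(bad, collapse = ", ")))
  }
  d
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

mantel_r <- function(m1, m2) {
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  v2 <- m2[lt]
  ok <- is.finite(v1) & is.finite(v2)
  if (sd(v1[ok]) == 0 || sd(v2[ok]) == 0) return(NA_real_)
  cor(v1[ok], v2[ok])
}

#' Isolation by distance with a Mantel test
#'
#' Linearises genetic divergence as `FST / (1 - FST)`, regresses it on
#' pairwise river distance, and tests the association with a one-sided
#' (positive) Mantel permutation test: rows and columns of the genetic
#' matrix are permuted jointly, and
#' `p = (count of permuted r >= observed + 1) / (n_perm + 1)`. With
#' `exact = TRUE` all `n!` permutations are enumerated instead and
#' `p = count(r_perm >= r_obs) / n!` (the identity included). Pairs with
#' `FST = 1` have infinite linearised divergence and are excluded with a
#' warning.
#'
#' @param fst_mat symmetric pairwise FST matrix.
#' @param dist_mat symmetric pairwise distance matrix, same order.
#' @param n_perm number of random permutations (identity excluded from the
#'   random draws; the observed configuration is the `+ 1`).
#' @param exact enumerate all permutations (population count <= 8).
#' @param seed optional integer seed.
#' @return an `ibd_result`: list with `slope`, `intercept`, `mantel_r`,
#'   `p_value`, `n_perm`, `n_excluded` and the pairwise table `pairs`.
#' @export
ibd_test <- function(fst_mat, dist_mat, n_perm = 999, exact = FALSE,
                     seed = NULL) {
  stopifnot(nrow(fst_mat) == ncol(fst_mat), all(dim(fst_mat) == dim(dist_mat)))
  n <- nrow(fst_mat)
  if (n < 3) abort("need at least 3 populations.")
  y <- fst_mat / (1 - fst_mat)
  n_inf <- sum(!is.finite(y[lower.tri(y)]))
  if (n_inf > 0) {
    warn(sprintf("ibd_test: %d pair(s) with FST = 1 excluded (infinite linearised divergence)", n_inf))
    y[!is.finite(y)] <- NA
  }
  if (!is.null(seed)) set.seed(seed)
  r_obs <- mantel_r(y, dist_mat)
  if (exact) {
    if (n > 8) abort("exact enumeration limited to 8 populations.")
    perms <- all_perms(n)
    r_perm <- vapply(perms, function(p) mantel_r(y[p, p], dist_mat), numeric(1))
    p_value <- mean(r_perm >= r_obs - 1e-12, na.rm = TRUE)
    n_perm_used <- length(perms)
  } else {
    r_perm <- vapply(seq_len(n_perm), function(b) {
      repeat {
        p <- sample.int(n)
        if (any(p != seq_len(n))) break
      }
      mantel_r(y[p, p], dist_mat)
    }, numeric(1))
    p_value <- (sum(r_perm >= r_obs - 1e-12, na.rm = TRUE) + 1) / (n_perm + 1)
    n_perm_used <- n_perm
  }
  lt <- lower.tri(y)
  fit_ok <- is.finite(y[lt])
  fit <- lm(y[lt][fit_ok] ~ dist_mat[lt][fit_ok])
  pairs <- tibble(
    pop1 = rownames(fst_mat)[row(fst_mat)[lt]],
    pop2 = colnames(fst_mat)[col(fst_mat)[lt]],
    fst = fst_mat[lt],
    linearised = y[lt],
    dist = dist_mat[lt]
  )
  structure(
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      mantel_r = r_obs, p_value = p_value, n_perm = n_perm_used,
      n_excluded = n_inf, pairs = pairs
    ),
    class = "ibd_result"
  )
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf(
    "<ibd_result> Mantel r = %.3f, p = %.4g (%d permutations); slope = %.3g per km\n",
    x$mantel_r, x$p_value, x$n_perm, x$slope
  ))
  invisible(x)
}
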