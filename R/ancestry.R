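#' Estimate parental allele frequencies from reference panels
#'
#' Per-locus alternate-allele frequencies for each parental species, with
#' additive smoothing: `p = (alt + pseudocount) / (n_chr + 2 * pseudocount)`.
#' The default pseudocount of 0.5 per allele keeps frequencies strictly
#' inside (0, 1), which stabilises the downstream likelihoods; set
#' `pseudocount = 0` for plain counts (required for truly diagnostic loci).
#'
#' @param gm a [gmat] containing the reference individuals.
#' @param panel per-sample panel labels: `"refA"` (species A, e.g. sauger),
#'   `"refB"` (species B, e.g. walleye); other values are ignored.
#' @param pseudocount additive smoothing per allele (>= 0).
#' @return a `parental_freqs` tibble: `locus`, `chrom`, `pos`, `p_a`, `p_b`,
#'   `n_chr_a`, `n_chr_b`, `zero_call_a`, `zero_call_b` (loci whose
#'   frequency rests on the pseudocount alone are flagged).
#' @export
estimate_parental_freqs <- function(gm, panel, pseudocount = 0.5) {
  panel <- as.character(panel)
  if (length(panel) != n_samples(gm)) {
    abort("`panel` must have one entry per individual.")
  }
  if (!any(panel == "refA") || !any(panel == "refB")) {
    abort("both reference panels (refA, refB) must be non-empty.")
  }
  ca <- allele_counts(gm, panel == "refA")
  cb <- allele_counts(gm, panel == "refB")
  pc <- pseudocount
  out <- tibble(
    locus = ca$locus, chrom = ca$chrom, pos = ca$pos,
    p_a = (ca$alt + pc) / (ca$n_chr + 2 * pc),
    p_b = (cb$alt + pc) / (cb$n_chr + 2 * pc),
    n_chr_a = ca$n_chr, n_chr_b = cb$n_chr,
    zero_call_a = ca$n_chr == 0L, zero_call_b = cb$n_chr == 0L
  )
  if (pc == 0) {
    out$p_a[out$zero_call_a] <- NA_real_
    out$p_b[out$zero_call_b] <- NA_real_
  }
  class(out) <- c("parental_freqs", class(out))
  out
}

# per-locus genotype likelihoods under the three ancestry states,
# rows = loci, cols = AA, AB, BB; g is the genotype vector (0/1/2)
qq_likelihoods <- function(g, p_a, p_b) {
  l_aa <- dbinom(g, 2, p_a)
  l_bb <- dbinom(g, 2, p_b)
  l_ab <- ifelse(g == 0L, (1 - p_a) * (1 - p_b),
          ifelse(g == 1L, p_a * (1 - p_b) + (1 - p_a) * p_b,
                 p_a * p_b))
  cbind(AA = l_aa, AB = l_ab, BB = l_bb)
}

# EM over genome-wide ancestry-state proportions for one individual.
# lik: loci x 3 matrix of genotype likelihoods. Returns pi, loglik, iters.
qq_em <- function(lik, max_iter = 500, tol = 1e-8) {
  pi_z <- c(1, 1, 1) / 3
  ll_old <- -Inf
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    w <- sweep(lik, 2, pi_z, "*")
    tot <- rowSums(w)
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    r <- w / tot
    pi_z <- colMeans(r)
    if (ll - ll_old < tol && it > 1) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(pi = pi_z, loglik = ll_old, converged = converged,
       iters = length(trace), trace = trace)
}

#' Estimate admixture proportion q and interspecific ancestry Q
#'
#' For each individual, each locus has a latent ancestry state
#' (AA: both allele copies from species A; AB: one from each; BB: both from
#' species B). Genotype likelihoods under each state follow Hardy-Weinberg
#' draws from the parental frequencies (the AB state draws one allele from
#' each pool). An EM algorithm maximises the likelihood over the
#' genome-wide state proportions `(pi_AA, pi_AB, pi_BB)`; then
#' `q = pi_BB + pi_AB / 2` (proportion of species-B ancestry) and
#' `Q = pi_AB` (proportion of loci with ancestry from both species).
#' Parental frequencies stay fixed during the EM, so hybrid queries cannot
#' drift the panels. Missing genotypes and loci with no usable frequency
#' are skipped.
#'
#' Note this is a fixed-panel maximum-likelihood estimator of the same
#' (q, Q) estimands a hierarchical Bayesian admixture model would target;
#' it conditions on called genotypes and the panel frequencies, so its
#' variance behaves differently from an MCMC posterior.
#'
#' @param gm a [gmat] with the individuals to estimate.
#' @param freqs a `parental_freqs` tibble ([estimate_parental_freqs()] or
#'   [simulate_parental_panels()]); matched to `gm` by locus id.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   drops below `tol` or after `max_iter` iterations.
#' @return an `ancestry_est` tibble: `sample`, `q`, `Q`, `loglik`,
#'   `n_informative`, `converged`, `valid`.
#' @export
estimate_qQ <- function(gm, freqs, max_iter = 500, tol = 1e-8) {
  m <- match(locus_ids(gm), freqs$locus)
  if (all(is.na(m))) abort("no loci shared between `gm` and `freqs`.")
  p_a <- freqs$p_a[m]
  p_b <- freqs$p_b[m]
  usable_locus <- !is.na(p_a) & !is.na(p_b)
  res <- map_dfr(seq_len(n_samples(gm)), function(i) {
    g <- gm$geno[i, ]
    use <- usable_locus & !is.na(g)
    if (!any(use)) {
      return(tibble(
        sample = sample_ids(gm)[i], q = NA_real_, Q = NA_real_,
        loglik = NA_real_, n_informative = 0L, converged = NA, valid = FALSE
      ))
    }
    lik <- qq_likelihoods(g[use], p_a[use], p_b[use])
    ok <- rowSums(lik) > 0  # drop loci impossible under every state
    lik <- lik[ok, , drop = FALSE]
    if (!nrow(lik)) {
      return(tibble(
        sample = sample_ids(gm)[i], q = NA_real_, Q = NA_real_,
        loglik = NA_real_, n_informative = 0L, converged = NA, valid = FALSE
      ))
    }
    em <- qq_em(lik, max_iter = max_iter, tol = tol)
    tibble(
      sample = sample_ids(gm)[i],
      q = em$pi[["BB"]] + em$pi[["AB"]] / 2,
      Q = em$pi[["AB"]],
      loglik = em$loglik,
      n_informative = nrow(lik),
      converged = em$converged,
      valid = TRUE
    )
  })
  class(res) <- c("ancestry_est", class(res))
  res
}

#' Classify an individual from its (q, Q) ancestry estimates
#'
#' Threshold rules on the admixture proportion `q` (species-B, i.e. walleye,
#' ancestry) and interspecific ancestry `Q`:
#' `q < 0.1` is pure sauger and `q > 0.9` pure walleye; everything else is a
#' hybrid, sub-typed in fixed order: F1 if `0.4 <= q <= 0.6` and `Q > 0.8`;
#' F2 if `0.4 <= q <= 0.6` and `0.4 <= Q <= 0.6`; backcross to sauger if
#' `-0.1 <= Q - 2q <= 0.1`; backcross to walleye if
#' `1.9 <= Q + 2q <= 2.1`; otherwise `hybrid_unassigned`. Interval bounds
#' are closed; the F1 -> F2 -> BC order resolves the rare border overlaps.
#'
#' @param q,Q numeric vectors in `[0, 1]`.
#' @return factor with levels `sauger`, `walleye`, `F1`, `F2`, `BC_sauger`,
#'   `BC_walleye`, `hybrid_unassigned`.
#' @export
classify_hybrid <- function(q, Q) {
  if (length(q) != length(Q)) abort("`q` and `Q` must have equal length.")
  ok <- !is.na(q) & !is.na(Q)
  if (any(q[ok] < 0 | q[ok] > 1 | Q[ok] < 0 | Q[ok] > 1)) {
    abort("`q` and `Q` must lie in [0, 1].")
  }
  lv <- c("sauger", "walleye", "F1", "F2", "BC_sauger", "BC_walleye",
          "hybrid_unassigned")
  out <- rep(NA_character_, length(q))
  out[ok & q < 0.1] <- "sauger"
  out[ok & q > 0.9] <- "walleye"
  hyb <- ok & is.na(out)
  f1 <- hyb & q >= 0.4 & q <= 0.6 & Q > 0.8
  out[f1] <- "F1"
  f2 <- hyb & is.na(out) & q >= 0.4 & q <= 0.6 & Q >= 0.4 & Q <= 0.6
  out[f2] <- "F2"
  bcs <- hyb & is.na(out) & (Q - 2 * q) >= -0.1 & (Q - 2 * q) <= 0.1
  out[bcs] <- "BC_sauger"
  bcw <- hyb & is.na(out) & (Q + 2 * q) >= 1.9 & (Q + 2 * q) <= 2.1
  out[bcw] <- "BC_walleye"
  out[hyb & is.na(out)] <- "hybrid_unassigned"
  factor(out, levels = lv)
}

#' Add hybrid classes to an ancestry-estimate table
#'
#' @param est an `ancestry_est` tibble (or any tibble with `q` and `Q`).
#' @return the input with a `class` factor column appended.
#' @export
classify_ancestry <- function(est) {
  est$class <- classify_hybrid(est$q, est$Q)
  est
}

#' Bootstrap confidence intervals for one individual's (q, Q)
#'
#' Resamples loci with replacement `B` times, re-running the EM on each
#' replicate, and returns percentile intervals.
#'
#' @param gm a [gmat].
#' @param freqs a `parental_freqs` tibble.
#' @param sample sample id or row index of the individual.
#' @param B bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return list with `ci_q` and `ci_Q` (length-2 numeric vectors) and the
#'   replicate draws in `boot` (tibble).
#' @export
bootstrap_qQ <- function(gm, freqs, sample, B = 200, level = 0.95,
                         seed = NULL) {
  if (B < 100) abort("`B` must be >= 100 for a percentile interval.")
  if (is.character(sample)) sample <- match(sample, sample_ids(gm))
  if (is.na(sample)) abort("sample not found.")
  if (!is.null(seed)) set.seed(seed)
  m <- match(locus_ids(gm), freqs$locus)
  p_a <- freqs$p_a[m]
  p_b <- freqs$p_b[m]
  g <- gm$geno[sample, ]
  use <- !is.na(p_a) & !is.na(p_b) & !is.na(g)
  lik <- qq_likelihoods(g[use], p_a[use], p_b[use])
  lik <- lik[rowSums(lik) > 0, , drop = FALSE]
  if (!nrow(lik)) abort("no informative loci for this individual.")
  draws <- map_dfr(seq_len(B), function(b) {
    em <- qq_em(lik[sample.int(nrow(lik), nrow(lik), replace = TRUE), ,
                    drop = FALSE])
    tibble(q = em$pi[["BB"]] + em$pi[["AB"]] / 2, Q = em$pi[["AB"]])
  })
  a <- (1 - level) / 2
  list(
    ci_q = unname(quantile(draws$q, c(a, 1 - a))),
    ci_Q = unname(quantile(draws$Q, c(a, 1 - a))),
    boot = draws
  )
}
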