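#' Discriminant analysis of principal components
#'
#' PCA of the mean-imputed, centred genotype matrix followed by a linear
#' discriminant on the retained PC scores, with per-locus contributions
#' obtained by back-projecting the discriminant axis into locus space and
#' squaring (normalised to sum to 1). With sex as the grouping variable the
#' locus loadings localise sex-differentiated regions of the genome.
#'
#' The number of retained PCs defaults to the smallest count explaining at
#' least 90% of the genotypic variance, capped at one third of the sample
#' size; a requested `n_pcs` above the matrix rank is clipped with a
#' warning.
#'
#' @param gm a [gmat].
#' @param labels group labels (e.g. sex), one per individual; at least two
#'   groups with two or more individuals each.
#' @param n_pcs number of principal components to retain (default:
#'   automatic, see above).
#' @return a `dapc_result`: list with `scores` (tibble: `sample`, `label`,
#'   `ld1`), `loadings` (tibble: `locus`, `chrom`, `pos`, `loading`),
#'   `n_pcs`, `groups`, `var_explained`.
#' @export
dapc <- function(gm, labels, n_pcs = NULL) {
  labels <- as.character(labels)
  if (length(labels) != n_samples(gm)) {
    abort("`labels` must have one entry per individual.")
  }
  tab <- table(labels)
  if (length(tab) < 2) abort("DAPC needs at least two groups.")
  if (any(tab < 2)) abort("every group needs at least two individuals.")
  dec <- dapc_decompose(gm)
  n_pcs <- choose_n_pcs(dec, n_samples(gm), n_pcs)
  res <- dapc_core(dec, labels, n_pcs)
  structure(
    list(
      scores = tibble(sample = sample_ids(gm), label = labels, ld1 = res$ld1),
      loadings = tibble(
        locus = locus_ids(gm), chrom = gm$chrom, pos = gm$pos,
        loading = res$loading
      ),
      n_pcs = n_pcs,
      groups = names(tab),
      var_explained = dec$var_explained
    ),
    class = "dapc_result"
  )
}

# label-free part of DAPC, reusable across label permutations
dapc_decompose <- function(gm) {
  x <- impute_mean(gm)
  x <- sweep(x, 2, colMeans(x))
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  list(
    scores = p$x, rotation = p$rotation,
    var_explained = ev / sum(ev),
    rank = sum(p$sdev > max(p$sdev) * 1e-8)
  )
}

choose_n_pcs <- function(dec, n, n_pcs) {
  if (is.null(n_pcs)) {
    cum <- cumsum(dec$var_explained)
    n_pcs <- which(cum >= 0.9)[1]
    if (is.na(n_pcs)) n_pcs <- dec$rank
    n_pcs <- min(n_pcs, max(1L, floor(n / 3)))
  }
  if (n_pcs > dec$rank) {
    warn(sprintf("n_pcs clipped from %d to matrix rank %d", n_pcs, dec$rank))
    n_pcs <- dec$rank
  }
  max(1L, as.integer(n_pcs))
}

dapc_core <- function(dec, labels, n_pcs) {
  s <- dec$scores[, seq_len(n_pcs), drop = FALSE]
  # PC scores are orthogonal; lda's collinearity warning only flags
  # directions with negligible within-group variance, which are harmless here
  fit <- suppressWarnings(MASS::lda(s, grouping = labels))
  ld1 <- unname(drop(s %*% fit$scaling[, 1]))
  w <- drop(dec$rotation[, seq_len(n_pcs), drop = FALSE] %*% fit$scaling[, 1])
  loading <- unname(w^2 / sum(w^2))
  list(ld1 = ld1, loading = loading)
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf(
    "<dapc_result> %d individuals, %d loci, %d PCs retained, groups: %s\n",
    nrow(x$scores), nrow(x$loadings), x$n_pcs, paste(x$groups, collapse = "/")
  ))
  invisible(x)
}

#' Flag loci by loading quantile
#'
#' Returns loci whose DAPC loading is at or above the stated quantile of the
#' loading distribution; loadings tied with the quantile are all included.
#'
#' @param result a `dapc_result` from [dapc()].
#' @param quantile quantile in `(0, 1]`; the conventional screen uses 0.99.
#' @return character vector of flagged locus ids.
#' @export
flag_sex_loci <- function(result, quantile = 0.99) {
  if (quantile <= 0 || quantile > 1) abort("`quantile` must lie in (0, 1].")
  thr <- stats::quantile(result$loadings$loading, quantile, names = FALSE)
  result$loadings$locus[result$loadings$loading >= thr]
}

#' Randomization threshold for DAPC loadings
#'
#' Permutes the group labels `B` times, rerunning the discriminant step on
#' the fixed PCA each time, and returns the 95th percentile of the
#' per-replicate maximum locus loading. An observed loading above this
#' threshold is unlikely under the no-association null.
#'
#' @param gm a [gmat].
#' @param labels group labels, as in [dapc()].
#' @param B number of permutations (>= 20).
#' @param prob percentile of the null maxima used as the threshold.
#' @param n_pcs PCs retained (default as in [dapc()]).
#' @param seed optional integer seed.
#' @return the loading threshold (scalar), with the per-replicate maxima in
#'   the `null_max` attribute.
#' @export
randomization_threshold <- function(gm, labels, B = 100, prob = 0.95,
                                    n_pcs = NULL, seed = NULL) {
  if (B < 20) abort("`B` must be >= 20 for a stable threshold.")
  labels <- as.character(labels)
  if (!is.null(seed)) set.seed(seed)
  dec <- dapc_decompose(gm)
  n_pcs <- choose_n_pcs(dec, n_samples(gm), n_pcs)
  null_max <- vapply(seq_len(B), function(b) {
    max(dapc_core(dec, sample(labels), n_pcs)$loading)
  }, numeric(1))
  thr <- stats::quantile(null_max, prob, names = FALSE)
  attr(thr, "null_max") <- null_max
  thr
}
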