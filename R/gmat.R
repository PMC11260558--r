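#' Genotype matrix container
#'
#' `gmat()` wraps an individuals-by-loci matrix of biallelic genotypes coded
#' as the number of copies of the alternate allele (0, 1, 2) with `NA` for
#' missing calls, together with 1-based locus coordinates. Loci are stored
#' sorted by chromosome then position; positions must be unique within a
#' chromosome.
#'
#' @param geno integer matrix, individuals in rows, loci in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param chrom character vector of chromosome ids, one per locus.
#' @param pos integer vector of 1-based positions, one per locus.
#' @param samples sample ids; defaults to rownames of `geno` or `ind_<i>`.
#' @return an object of class `gmat`.
#' @export
gmat <- function(geno, chrom, pos, samples = NULL) {
  geno <- as.matrix(geno)
  if (length(chrom) != ncol(geno) || length(pos) != ncol(geno)) {
    abort("`chrom` and `pos` must have one entry per locus (column).")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("genotypes must be 0, 1, 2 or NA.")
  }
  if (is.null(samples)) {
    samples <- rownames(geno)
    if (is.null(samples)) samples <- paste0("ind_", seq_len(nrow(geno)))
  }
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ord <- order(chrom, pos)
  geno <- geno[, ord, drop = FALSE]
  chrom <- chrom[ord]
  pos <- pos[ord]
  if (anyDuplicated(paste(chrom, pos))) {
    abort("locus coordinates must be unique within a chromosome.")
  }
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(samples, if (ncol(geno)) paste0(chrom, ":", pos))
  structure(
    list(geno = geno, chrom = chrom, pos = pos),
    class = "gmat"
  )
}

#' @export
dim.gmat <- function(x) dim(x$geno)

#' Number of samples / loci in a genotype matrix
#' @param x a [gmat] object.
#' @return an integer count.
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname n_samples
#' @export
n_loci <- function(x) ncol(x$geno)

#' @rdname n_samples
#' @export
sample_ids <- function(x) rownames(x$geno)

#' @rdname n_samples
#' @export
locus_ids <- function(x) colnames(x$geno)

#' Subset a genotype matrix
#'
#' Rows index individuals, columns index loci; locus coordinates are carried
#' along. Attributes attached by the simulators (ground truth, sex labels)
#' are dropped, matching base matrix semantics.
#'
#' @param x a [gmat].
#' @param i,j sample and locus indices (any base subscript form).
#' @param ... ignored.
#' @export
`[.gmat` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  if (is.character(j)) j <- match(j, colnames(x$geno))
  if (is.logical(j)) j <- which(j)
  g <- x$geno[i, j, drop = FALSE]
  gmat(g, x$chrom[j], x$pos[j], samples = rownames(g))
}

#' @export
print.gmat <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf(
    "<gmat> %d individuals x %d loci (%d chromosome%s), %.1f%% missing\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$chrom)),
    if (length(unique(x$chrom)) == 1) "" else "s", 100 * miss
  ))
  invisible(x)
}

#' Locus table of a genotype matrix
#'
#' @param x a [gmat].
#' @return a tibble with columns `locus`, `chrom`, `pos`.
#' @export
loci_table <- function(x) {
  tibble(locus = colnames(x$geno), chrom = x$chrom, pos = x$pos)
}

#' Per-locus allele counts for a set of individuals
#'
#' Counts alternate alleles and called chromosomes per locus, the summaries
#' consumed by the Reich-Patterson estimator and the joint SFS.
#'
#' @param x a [gmat].
#' @param which optional sample index/logical/ids restricting the tally.
#' @return tibble with columns `locus`, `chrom`, `pos`, `alt` (alternate
#'   allele count) and `n_chr` (called chromosomes).
#' @export
allele_counts <- function(x, which = NULL) {
  g <- x$geno
  if (!is.null(which)) g <- g[which, , drop = FALSE]
  alt <- colSums(g, na.rm = TRUE)
  n_chr <- 2L * colSums(!is.na(g))
  tibble(
    locus = colnames(g), chrom = x$chrom, pos = x$pos,
    alt = as.integer(alt), n_chr = as.integer(n_chr)
  )
}

# per-locus missingness fraction
locus_missingness <- function(x) colMeans(is.na(x$geno))

# per-individual missingness fraction
indiv_missingness <- function(x) rowMeans(is.na(x$geno))

# per-locus alternate allele frequency from non-missing calls (NaN if none)
locus_freq <- function(x) {
  called <- 2 * colSums(!is.na(x$geno))
  colSums(x$geno, na.rm = TRUE) / called
}

# mean-impute missing genotypes and return a plain numeric matrix
impute_mean <- function(x) {
  g <- x$geno
  storage.mode(g) <- "double"
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2]]
  g
}

#' Convert a genotype matrix to a long tibble
#'
#' @param x a [gmat].
#' @param ... unused.
#' @return tibble with columns `sample`, `locus`, `chrom`, `pos`, `genotype`.
#' @export
as_tibble.gmat <- function(x, ...) {
  tibble(
    sample = rep(rownames(x$geno), times = ncol(x$geno)),
    locus = rep(colnames(x$geno), each = nrow(x$geno)),
    chrom = rep(x$chrom, each = nrow(x$geno)),
    pos = rep(x$pos, each = nrow(x$geno)),
    genotype = as.integer(x$geno)
  )
}
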