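#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (v4.x) with `vcfR` and keeps only biallelic SNP records;
#' multiallelic or non-SNP records are skipped with a message reporting the
#' count. Genotypes are coded as alternate-allele copy counts; uncalled
#' genotypes (`./.`) become missing.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @return a [gmat]; the number of skipped records is attached as the
#'   `skipped` attribute.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0) {
    inform(sprintf("read_vcf: skipped %d multiallelic/non-SNP record(s)", n_skip))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  chrom <- fix[snp, "CHROM"]
  pos <- as.integer(fix[snp, "POS"])
  # count ALT alleles in GT strings like 0/1, 1|1
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  g <- (a1 == "1") + (a2 == "1")
  g[a1 == "." | a2 == "." | is.na(gt)] <- NA_integer_
  g <- t(matrix(as.integer(g), nrow(gt), ncol(gt), dimnames = dimnames(gt)))
  out <- gmat(g, chrom, pos, samples = colnames(gt))
  attr(out, "skipped") <- n_skip
  out
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF v4.2 with GT as the only FORMAT field, `A`/`T` as placeholder
#' REF/ALT alleles, suitable for round-tripping through [read_vcf()] and for
#' consumption by standard tools.
#'
#' @param gm a [gmat].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sanderpop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  g <- gm$geno
  body <- vapply(seq_len(ncol(g)), function(j) {
    calls <- ifelse(is.na(g[, j]), "./.", gt_code[g[, j] + 1L])
    paste(c(gm$chrom[j], gm$pos[j], colnames(g)[j], "A", "T", ".", "PASS",
            ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Filter loci on minor allele frequency and missingness
#'
#' Both criteria are evaluated on the input matrix, then failing loci are
#' dropped in one pass (so the criteria do not interact). MAF is computed
#' from non-missing genotypes only.
#'
#' @param gm a [gmat].
#' @param maf_min minimum minor allele frequency retained (default 0.03, the
#'   standard SNP-panel filter for this kind of study).
#' @param max_locus_missing maximum fraction of individuals missing at a
#'   retained locus.
#' @return a filtered [gmat]; a one-row report tibble (`n_before`, `n_after`,
#'   `n_fail_maf`, `n_fail_missing`) is attached as the `report` attribute.
#' @export
filter_loci <- function(gm, maf_min = 0.03, max_locus_missing = 0.5) {
  stopifnot(maf_min >= 0, maf_min <= 1, max_locus_missing >= 0, max_locus_missing <= 1)
  f <- locus_freq(gm)
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  miss <- locus_missingness(gm)
  fail_maf <- maf < maf_min
  fail_miss <- miss > max_locus_missing
  keep <- !(fail_maf | fail_miss)
  if (!any(keep)) warn("filter_loci: no loci survive the filter.")
  out <- gm[, keep]
  out <- attributes_keep(out, gm)
  attr(out, "report") <- tibble(
    n_before = n_loci(gm), n_after = sum(keep),
    n_fail_maf = sum(fail_maf), n_fail_missing = sum(fail_miss)
  )
  out
}

#' Filter individuals on missingness
#'
#' Individuals missing data for `max_indiv_missing` or more of the loci are
#' removed (the threshold itself is removed, matching "80% or more").
#'
#' @param gm a [gmat].
#' @param max_indiv_missing removal threshold in `[0, 1]`; `1` removes
#'   nobody.
#' @return a filtered [gmat] with the removed ids in the `removed` attribute.
#' @export
filter_individuals <- function(gm, max_indiv_missing = 0.8) {
  stopifnot(max_indiv_missing >= 0, max_indiv_missing <= 1)
  miss <- indiv_missingness(gm)
  drop <- miss >= max_indiv_missing & max_indiv_missing < 1
  if (any(drop)) {
    inform(sprintf(
      "filter_individuals: removed %d individual(s): %s",
      sum(drop), paste(head(sample_ids(gm)[drop], 10), collapse = ", ")
    ))
  }
  out <- gm[!drop, ]
  out <- attributes_keep(out, gm)
  attr(out, "removed") <- sample_ids(gm)[drop]
  out
}

#' Shipped filtering presets
#'
#' Four presets mirror the filtering regimes of a typical GBS hybridization
#' study: `hybrid` (MAF >= 0.03, locus missingness <= 0.5) for ancestry
#' estimation; `pca` (additionally locus missingness <= 0.25) for principal
#' components; `sauger` (locus missingness <= 0.25, applied after hybrids
#' and walleye are removed) for within-species structure; `demography` (no
#' MAF filter, sex-linked loci retained, locus missingness <= 0.7) for SFS
#' construction, where rare variants carry the signal.
#'
#' @return a tibble with one row per preset: `name`, `maf_min`,
#'   `max_locus_missing`, `max_indiv_missing`, `drop_sex_loci`.
#' @export
filter_presets <- function() {
  tibble(
    name = c("hybrid", "pca", "sauger", "demography"),
    maf_min = c(0.03, 0.03, 0.03, 0),
    max_locus_missing = c(0.5, 0.25, 0.25, 0.7),
    max_indiv_missing = c(0.8, 0.8, 0.8, 0.8),
    drop_sex_loci = c(TRUE, TRUE, TRUE, FALSE)
  )
}

#' Apply a named filtering preset
#'
#' @param gm a [gmat].
#' @param preset preset name (see [filter_presets()]).
#' @param sex_loci locus ids to drop when the preset removes sex-linked loci
#'   (ignored otherwise).
#' @param max_indiv_missing override of the individual-missingness removal
#'   threshold (the shipped default is 0.8).
#' @return a filtered [gmat] with a `report` attribute.
#' @export
apply_filter_preset <- function(gm, preset = "hybrid", sex_loci = NULL,
                                max_indiv_missing = NULL) {
  p <- filter_presets()
  p <- p[p$name == preset, ]
  if (nrow(p) != 1) abort(sprintf("unknown preset '%s'", preset))
  if (is.null(max_indiv_missing)) max_indiv_missing <- p$max_indiv_missing
  out <- gm
  if (p$drop_sex_loci && length(sex_loci)) {
    out <- out[, setdiff(locus_ids(out), sex_loci)]
    out <- attributes_keep(out, gm)
  }
  out <- filter_loci(out, maf_min = p$maf_min, max_locus_missing = p$max_locus_missing)
  rep_loci <- attr(out, "report")
  out2 <- filter_individuals(out, max_indiv_missing)
  attr(out2, "report") <- rep_loci
  out2
}

#' Read / write the sample-metadata table
#'
#' Tab-separated with columns `sample_id`, `location`, `date` (ISO-8601),
#' `sex` (`M`/`F`/`unknown`), `phenotype` (`sauger`/`walleye`/`hybrid`/
#' `unknown`) and `panel` (`refA`/`refB`/`query`).
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_sample_table <- function(path) {
  x <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, colClasses = "character"))
  need <- c("sample_id", "location", "date", "sex", "phenotype", "panel")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(sprintf("sample table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(x$panel), c("refA", "refB", "query"))
  if (length(bad)) abort(sprintf("unknown panel value(s): %s", paste(bad, collapse = ", ")))
  x
}

#' @rdname read_sample_table
#' @param x a sample-metadata tibble.
#' @export
write_sample_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
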