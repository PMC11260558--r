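# small handcrafted genotype matrix: 4 individuals x 5 loci on 2 chromosomes
toy_gmat <- function() {
  g <- rbind(
    s1 = c(0L, 1L, 2L, NA, 0L),
    s2 = c(0L, 1L, 1L, 2L, 0L),
    s3 = c(1L, NA, 0L, 2L, 0L),
    s4 = c(2L, 0L, 0L, 1L, 0L)
  )
  gmat(g, chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
       pos = c(100L, 200L, 300L, 50L, 90L))
}

# write a tiny VCF: 3 samples x 2 biallelic SNPs (+ optional triallelic row)
write_toy_vcf <- function(path, with_triallelic = FALSE) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", "b", "c", sep = "\t")
  )
  body <- c(
    paste("chr1", "10", ".", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "20", ".", "C", "T", ".", "PASS", ".", "GT",
          "./.", "0/0", "0/1", sep = "\t")
  )
  if (with_triallelic) {
    body <- c(body,
              paste("chr2", "5", ".", "A", "G,T", ".", "PASS", ".", "GT",
                    "0/1", "0/2", "0/0", sep = "\t"))
  }
  writeLines(c(hdr, body), path)
  path
}

# independent (loop-based) Reich-Patterson evaluation used as an oracle
rp_fst_oracle <- function(a1, n1, a2, n2) {
  num <- den <- 0
  for (l in seq_along(a1)) {
    if (n1[l] < 2 || n2[l] < 2) next
    h1 <- a1[l] * (n1[l] - a1[l]) / (n1[l] * (n1[l] - 1))
    h2 <- a2[l] * (n2[l] - a2[l]) / (n2[l] * (n2[l] - 1))
    nl <- (a1[l] / n1[l] - a2[l] / n2[l])^2 - h1 / n1[l] - h2 / n2[l]
    num <- num + nl
    den <- den + nl + h1 + h2
  }
  num / den
}

# class centroids in (q, Q) space for the simulated crosses
class_centroids <- list(
  pureA = c(0, 0), pureB = c(1, 0), F1 = c(0.5, 1), F2 = c(0.5, 0.5),
  BC_A = c(0.25, 0.5), BC_B = c(0.75, 0.5)
)

expected_class_label <- c(
  pureA = "sauger", pureB = "walleye", F1 = "F1", F2 = "F2",
  BC_A = "BC_sauger", BC_B = "BC_walleye"
)
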