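#' Reported hybrid ancestry estimates from the Wind-Bighorn survey
#'
#' The eight sauger x walleye individuals genotypically identified as
#' hybrids in a genomic survey of Wyoming's Wind River and Bighorn River
#' systems, with their published admixture proportion `q` (walleye
#' ancestry) and interspecific ancestry `Q`, sampling location, field
#' phenotype call and collection metadata. Useful as a worked example for
#' [classify_hybrid()]: the classifier reproduces the survey's hybrid-class
#' assignments, including the single F1 (from Boysen Reservoir, the
#' impounded section where hybridization concentrated).
#'
#' @return a tibble with columns `sample_id`, `location`, `temporal_event`,
#'   `phenotype`, `date`, `sex`, `maturity`, `q`, `Q`.
#' @export
sander_hybrids <- function() {
  path <- system.file("extdata", "hybrid_examples.tsv", package = "sanderpop")
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE,
                       colClasses = c(q = "numeric", Q = "numeric",
                                      sample_id = "character")))
}
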