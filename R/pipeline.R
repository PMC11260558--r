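#' Default pipeline configuration
#'
#' A named list of every knob the pipeline reads, pre-filled with the
#' package defaults. With no `vcf`/`samples` input paths the pipeline runs
#' in demo mode: it simulates a complete synthetic study (reference panels,
#' a mixed query set with hybrids, a planted sex block, GBS missingness, a
#' stepping-stone river and a dam-split population pair) and analyses it
#' end to end.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-stage seeds are derived from it, so a rerun
#'   with the same configuration is byte-identical.
#' @param ... overrides of any default entry.
#' @return a named list.
#' @export
pipeline_config <- function(out_dir = "sanderpop_run", seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed,
    vcf = NULL, samples = NULL,
    # filtering
    preset = "hybrid", max_indiv_missing = 0.8,
    # sex scan
    do_sexscan = TRUE, sex_quantile = 0.99, sex_rand_B = 50,
    # ancestry
    pseudocount = 0.5,
    # popstats
    fst_B = 200, ibd_n_perm = 999,
    # demography
    do_demography = TRUE, demog_n_grid = 50, demog_restarts = 4,
    demog_maxeval = 300, mu = 5.97e-9, generation_time = 3,
    # demo-mode simulation sizes
    demo_n_loci = 3000, demo_divergence = 0.3, demo_missing = 0.15,
    demo_sex_chrom = "chr1", demo_sex_loci = 30, demo_sex_effect = 0.8,
    demo_split_loci = 1200, demo_split_nref = 200, demo_split_t = 40,
    demo_split_n = 16, demo_river_pops = 6, demo_river_m = 0.02
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Read a plain-text pipeline configuration
#'
#' `key = value` lines (comments with `#`); values are parsed as numbers or
#' logicals where possible. Keys mirror [pipeline_config()].
#'
#' @param path file path.
#' @return a config list.
#' @export
read_run_config <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*", "", ln)
  ln <- trimws(ln[nzchar(trimws(ln))])
  kv <- strsplit(ln, "\\s*=\\s*")
  args <- list()
  for (p in kv) {
    if (length(p) != 2) abort(sprintf("cannot parse config line: %s", paste(p, collapse = "=")))
    v <- p[2]
    v2 <- suppressWarnings(as.numeric(v))
    if (!is.na(v2)) v <- v2
    else if (v %in% c("TRUE", "FALSE", "true", "false")) v <- toupper(v) == "TRUE"
    args[[p[1]]] <- v
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Stages run in order: input (read or simulate) -> locus/individual
#' filtering -> sex-linked-locus screen and removal -> parental frequencies,
#' (q, Q) estimation and hybrid classification -> population statistics
#' (pairwise FST, diversity, isolation by distance) -> demographic model fit
#' with real-time scaling. Each stage writes a TSV under `out_dir`, and a
#' manifest records the package version, seeds and parameters. A stage
#' failure aborts with the stage name.
#'
#' @param config a list from [pipeline_config()] or [read_run_config()].
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest tibble.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  for (p in c(cfg$vcf, cfg$samples)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("config error: input path does not exist: %s", p))
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  results <- list()
  manifest <- list(tibble(key = "sanderpop_version",
                          value = as.character(utils::packageVersion("sanderpop"))),
                   tibble(key = "seed", value = as.character(cfg$seed)))

  # -- input ----------------------------------------------------------------
  demo_mode <- is.null(cfg$vcf)
  inp <- stage("input", {
    if (demo_mode) demo_inputs(cfg) else {
      gm <- read_vcf(cfg$vcf)
      meta <- read_sample_table(cfg$samples)
      meta <- meta[match(sample_ids(gm), meta$sample_id), ]
      list(gm = gm, panel = meta$panel, sex = meta$sex, meta = meta)
    }
  })
  results$input <- inp

  # -- filter ---------------------------------------------------------------
  filt <- stage("filter", {
    apply_filter_preset(inp$gm, cfg$preset,
                        max_indiv_missing = cfg$max_indiv_missing)
  })
  keep <- match(sample_ids(filt), sample_ids(inp$gm))
  panel <- inp$panel[keep]
  sex <- inp$sex[keep]
  write.table(attr(filt, "report"), file.path(cfg$out_dir, "filter_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  results$filtered <- filt

  # -- sexscan --------------------------------------------------------------
  if (isTRUE(cfg$do_sexscan) && length(unique(na.omit(sex))) == 2) {
    sx <- stage("sexscan", {
      known <- !is.na(sex) & sex %in% c("M", "F")
      d <- dapc(filt[known, ], sex[known])
      flagged <- flag_sex_loci(d, cfg$sex_quantile)
      thr <- randomization_threshold(filt[known, ], sex[known],
                                     B = cfg$sex_rand_B,
                                     seed = cfg$seed + 101L)
      list(dapc = d, flagged = flagged, threshold = as.numeric(thr))
    })
    write.table(
      dplyr::filter(sx$dapc$loadings, .data$locus %in% sx$flagged),
      file.path(cfg$out_dir, "sex_loci.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    filt <- filt[, setdiff(locus_ids(filt), sx$flagged)]
    results$sexscan <- sx
  }

  # -- ancestry -------------------------------------------------------------
  anc <- stage("ancestry", {
    freqs <- estimate_parental_freqs(filt, panel, pseudocount = cfg$pseudocount)
    est <- estimate_qQ(filt[panel == "query", ], freqs)
    classify_ancestry(est)
  })
  write.table(anc, file.path(cfg$out_dir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  results$ancestry <- anc

  # -- popstats -------------------------------------------------------------
  pop <- stage("popstats", {
    out <- list()
    if (demo_mode) {
      riv <- inp$river
      fm <- fst_matrix(riv$geno, riv$pops)
      out$fst_pairs <- fm$pairs
      out$ibd <- ibd_test(fm$matrix, riv$dist_km, n_perm = cfg$ibd_n_perm,
                          seed = cfg$seed + 202L)
      sp <- inp$split
      out$diversity <- diversity_metrics(sp$geno, attr(sp$geno, "pops"),
                                         total_sites = 10 * n_loci(sp$geno))
      out$fst_split <- fst_bootstrap(sp$geno, attr(sp$geno, "pops"),
                                     B = cfg$fst_B, seed = cfg$seed + 203L)
    }
    out
  })
  if (!is.null(pop$fst_pairs)) {
    write.table(pop$fst_pairs, file.path(cfg$out_dir, "fst_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(tidy(pop$ibd), file.path(cfg$out_dir, "ibd.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(pop$diversity, file.path(cfg$out_dir, "diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  results$popstats <- pop

  # -- demography -----------------------------------------------------------
  if (isTRUE(cfg$do_demography) && demo_mode) {
    dm <- stage("demography", {
      sp <- inp$split
      fit <- fit_model(sp$sfs, "split_nomig", n_restarts = cfg$demog_restarts,
                       seed = cfg$seed + 303L, n_grid = cfg$demog_n_grid,
                       maxeval = cfg$demog_maxeval)
      scaling <- scale_to_real(fit, mu = cfg$mu,
                               L = n_loci(sp$geno) * 100,
                               generation_time = cfg$generation_time)
      list(fit = fit, scaling = scaling)
    })
    write.table(
      cbind(glance(dm$fit), tidyr::pivot_wider(tidy(dm$fit),
                                               names_from = "term",
                                               values_from = "estimate")),
      file.path(cfg$out_dir, "demographic_fit.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write.table(dm$scaling, file.path(cfg$out_dir, "real_time_scaling.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$demography <- dm
  }

  manifest <- bind_rows(
    manifest,
    tibble(key = names(cfg)[!vapply(cfg, is.null, logical(1))],
           value = vapply(cfg[!vapply(cfg, is.null, logical(1))],
                          function(v) paste(format(v), collapse = ","),
                          character(1)))
  )
  write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  results$manifest <- manifest
  invisible(results)
}

# synthetic end-to-end demo inputs with known ground truth
demo_inputs <- function(cfg) {
  seed <- cfg$seed
  freqs <- simulate_parental_panels(cfg$demo_n_loci, cfg$demo_divergence,
                                    seed = seed)
  sets <- list(
    refA = simulate_cross(freqs, "pureA", 20, seed = seed + 1L, prefix = "refA"),
    refB = simulate_cross(freqs, "pureB", 20, seed = seed + 2L, prefix = "refB"),
    qA = simulate_cross(freqs, "pureA", 40, seed = seed + 3L, prefix = "qsauger"),
    qB = simulate_cross(freqs, "pureB", 10, seed = seed + 4L, prefix = "qwalleye"),
    f1 = simulate_cross(freqs, "F1", 3, seed = seed + 5L),
    f2 = simulate_cross(freqs, "F2", 3, seed = seed + 6L),
    bca = simulate_cross(freqs, "BC_A", 3, seed = seed + 7L),
    bcb = simulate_cross(freqs, "BC_B", 3, seed = seed + 8L)
  )
  geno <- do.call(rbind, lapply(sets, function(s) s$geno))
  gm <- gmat(geno, freqs$chrom, freqs$pos)
  panel <- rep(c("refA", "refB", "query"),
               c(20, 20, nrow(geno) - 40))
  sb <- simulate_sex_block(gm, cfg$demo_sex_chrom, cfg$demo_sex_loci,
                           cfg$demo_sex_effect, seed = seed + 9L)
  gm <- apply_missingness(sb$geno, cfg$demo_missing, seed = seed + 10L)
  truth <- bind_rows(lapply(sets, sim_truth))
  split <- simulate_split(cfg$demo_split_loci, cfg$demo_split_nref, 0.4, 0.4,
                          cfg$demo_split_t, cfg$demo_split_n,
                          cfg$demo_split_n, seed = seed + 11L)
  river <- simulate_river(cfg$demo_river_pops, 25, cfg$demo_river_m, 200,
                          seed = seed + 12L)
  list(gm = gm, panel = panel, sex = sb$sex, truth = truth,
       sex_loci = sb$sex_loci, split = split, river = river)
}
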