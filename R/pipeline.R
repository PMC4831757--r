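# End-to-end orchestration over the module functions: simulate ground-truth
# data, quantify, test divergence and TE, profile RRT, scan ORF variants, and
# summarise. Every stage is idempotent for a fixed config and writes plain
# TSV/FASTA/GFF3.

#' Pipeline configuration
#'
#' Collects the study thresholds (with their standard defaults) and the
#' simulation settings for a full run.
#'
#' @param sim A [sim_config()].
#' @param n_resamples Resamples for divergence/TE nulls (10,000).
#' @param fdr FDR threshold (0.05).
#' @param min_cds_reads CDS read filter (50).
#' @param rrt_n_perm RRT permutations (10,000).
#' @param rrt_thresh,rrt_p_thresh,rrt_min_windows Stalling filter
#'   (1.2, 1e-4, 300).
#' @param orf_span ORF-variant search space in nt (180).
#' @param orf_min_reads,orf_min_cov ORF-variant evidence thresholds (10, 0.8).
#' @param refine_new_reads,refine_new_len,refine_ext_reads Refinement
#'   thresholds (50, 150, 20).
#' @param seed Root seed.
#' @return An `rp_config` list.
#' @export
rp_config <- function(sim = sim_config(),
                      n_resamples = 10000L, fdr = 0.05, min_cds_reads = 50L,
                      rrt_n_perm = 10000L, rrt_thresh = 1.2,
                      rrt_p_thresh = 1e-4, rrt_min_windows = 300L,
                      orf_span = 180L, orf_min_reads = 10L, orf_min_cov = 0.8,
                      refine_new_reads = 50L, refine_new_len = 150L,
                      refine_ext_reads = 20L, seed = 1L) {
  structure(as.list(environment()), class = "rp_config")
}

drop_list_cols <- function(tbl) {
  tbl[, !vapply(tbl, is.list, logical(1)), drop = FALSE]
}

#' Run the pipeline on simulated data
#'
#' Stages: `simulate` (strain pair + coverage + footprints), `divergence`
#' (mRNA and RFP tests), `te` (TE test + regulatory categories), `rrt`
#' (per-strain RRT tables, stalling calls, between-strain ratio test), `orf`
#' (candidate scan on both strains). Results are returned and, when
#' `out_dir` is given, written as TSV/FASTA/GFF3.
#'
#' @param config An [rp_config()].
#' @param out_dir Optional output directory.
#' @param stages Which stages to run (simulate is always implied).
#' @param n_footprints Footprints per strain for the RRT stage.
#' @return Named list of stage results, invisibly a `summary` tibble as well.
#' @export
run_pipeline <- function(config = rp_config(), out_dir = NULL,
                         stages = c("divergence", "te", "rrt", "orf"),
                         n_footprints = 100000L) {
  cfg <- config
  res <- list(config = cfg)
  sim <- simulate_strain_pair(cfg$sim)
  coverage <- simulate_coverage(sim, cfg$sim)
  res$sim <- sim
  res$coverage <- coverage
  oc <- ortholog_counts(sim$orthologs, sim$cds, coverage)

  if ("divergence" %in% stages) {
    res$div_mrna <- divergence_test(oc, "mRNA",
      n_resamples = cfg$n_resamples,
      fdr = cfg$fdr, min_cds_reads = cfg$min_cds_reads, seed = cfg$seed
    )
    res$div_rfp <- divergence_test(oc, "RFP",
      n_resamples = cfg$n_resamples,
      fdr = cfg$fdr, min_cds_reads = cfg$min_cds_reads, seed = cfg$seed
    )
  }
  if ("te" %in% stages) {
    res$te <- te_test(oc,
      n_resamples = cfg$n_resamples, fdr = cfg$fdr,
      min_cds_reads = cfg$min_cds_reads, seed = cfg$seed
    )
    if (!is.null(res$div_mrna)) {
      res$categories <- regulation_categories(res$div_mrna, res$te)
    }
  }
  if ("rrt" %in% stages) {
    cds_b <- sim$cds %>% filter(endsWith(.data$gene_id, "_B"))
    cds_y <- sim$cds %>% filter(endsWith(.data$gene_id, "_Y"))
    fp_b <- simulate_footprints(cds_b, cfg$sim$dwell_spec,
      n_reads = n_footprints,
      seed = substream_seed(cfg$seed, "fp", "B")
    )
    fp_y <- simulate_footprints(cds_y, cfg$sim$dwell_spec,
      n_reads = n_footprints,
      seed = substream_seed(cfg$seed, "fp", "Y")
    )
    res$rrt_b <- rrt_table(cds_b, fp_b, n_perm = cfg$rrt_n_perm, seed = cfg$seed)
    res$rrt_y <- rrt_table(cds_y, fp_y, n_perm = cfg$rrt_n_perm, seed = cfg$seed)
    res$stalling_b <- significant_stalling(
      res$rrt_b, cfg$rrt_thresh, cfg$rrt_p_thresh, cfg$rrt_min_windows
    )
    res$rrt_ratio <- strain_rrt_ratio_test(
      cds_b, fp_b, cds_y, fp_y,
      n_perm = cfg$rrt_n_perm,
      seed = cfg$seed, rrt_thresh = cfg$rrt_thresh,
      p_thresh = cfg$rrt_p_thresh, min_windows = cfg$rrt_min_windows
    )
  }
  if ("orf" %in% stages) {
    empty_aln <- tibble(
      seqid = character(), pos = integer(),
      strand = character(), length = integer()
    )
    res$orf_b <- call_orf_variants(
      sim$models %>% filter(endsWith(.data$gene_id, "_B")), sim$genome_b,
      empty_aln, empty_aln,
      span = cfg$orf_span,
      min_reads = cfg$orf_min_reads, min_cov_frac = cfg$orf_min_cov
    )
  }

  res$summary <- pipeline_summary(res)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

pipeline_summary <- function(res) {
  rows <- list(tibble(stage = "simulate", n = nrow(res$sim$orthologs)))
  if (!is.null(res$div_mrna)) {
    rows[[length(rows) + 1]] <- tibble(
      stage = "divergence_mRNA", n = sum(res$div_mrna$results$significant)
    )
    rows[[length(rows) + 1]] <- tibble(
      stage = "divergence_RFP", n = sum(res$div_rfp$results$significant)
    )
  }
  if (!is.null(res$te)) {
    rows[[length(rows) + 1]] <- tibble(stage = "te", n = sum(res$te$results$significant))
  }
  if (!is.null(res$stalling_b)) {
    rows[[length(rows) + 1]] <- tibble(stage = "stalling_B", n = nrow(res$stalling_b))
  }
  if (!is.null(res$orf_b)) {
    rows[[length(rows) + 1]] <- tibble(stage = "orf_candidates_B", n = nrow(res$orf_b))
  }
  bind_rows(rows)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(file.path(out_dir, "genome_B.fasta"), res$sim$genome_b)
  write_fasta(file.path(out_dir, "genome_Y.fasta"), res$sim$genome_y)
  write_gene_gff(file.path(out_dir, "models.gff3"), res$sim$models)
  write_ortholog_table(file.path(out_dir, "orthologs.tsv"), res$sim$orthologs)
  if (!is.null(res$div_mrna)) {
    readr::write_tsv(drop_list_cols(tidy(res$div_mrna)), file.path(out_dir, "divergence_mRNA.tsv"))
    readr::write_tsv(drop_list_cols(tidy(res$div_rfp)), file.path(out_dir, "divergence_RFP.tsv"))
  }
  if (!is.null(res$te)) {
    readr::write_tsv(drop_list_cols(tidy(res$te)), file.path(out_dir, "te.tsv"))
  }
  if (!is.null(res$categories)) {
    readr::write_tsv(res$categories, file.path(out_dir, "categories.tsv"))
  }
  if (!is.null(res$rrt_b)) {
    readr::write_tsv(tidy(res$rrt_b), file.path(out_dir, "rrt_B.tsv"))
    readr::write_tsv(tidy(res$rrt_y), file.path(out_dir, "rrt_Y.tsv"))
    readr::write_tsv(res$rrt_ratio, file.path(out_dir, "rrt_ratio.tsv"))
  }
  if (!is.null(res$orf_b)) {
    readr::write_tsv(res$orf_b, file.path(out_dir, "orf_candidates_B.tsv"))
  }
  readr::write_tsv(res$summary, file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}
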