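# Evidence-based refinement of gene models against de-novo predictions.
# Predictions come in as GFF-derived models (the predictor itself is external);
# mRNA and footprint alignments supply the evidence.

# count alignments whose 5'-most nucleotide falls inside [start, end) on
# seqid (consistent with the 5'-end feature-assignment rule); strand-blind
# unless `strand` is given
region_read_count <- function(alignments, seqid, start, end, strand = NULL) {
  hit <- alignments$seqid == seqid & alignments$pos >= start & alignments$pos < end
  if (!is.null(strand)) hit <- hit & alignments$strand == strand
  sum(hit)
}

# fraction of region bases covered by at least one aligned span; a read
# occupies its full aligned length, not just its 5' end
region_span_coverage <- function(alignments, seqid, start, end, strand = NULL) {
  al <- alignments %>% filter(.data$seqid == !!seqid)
  if (!is.null(strand)) al <- al %>% filter(.data$strand == !!strand)
  if (nrow(al) == 0) {
    return(0)
  }
  left <- if_else(al$strand == "-", al$pos - al$length + 1L, al$pos)
  ir <- IRanges::IRanges(start = left + 1L, width = al$length)
  region <- IRanges::IRanges(start = start + 1L, end = end)
  covered <- sum(IRanges::width(IRanges::intersect(
    IRanges::reduce(ir), region
  )))
  covered / (end - start)
}

gene_span <- function(models, gene) {
  rows <- models %>% filter(.data$gene_id == gene)
  if (nrow(rows) == 0) abort(paste0("unknown gene ", gene))
  list(
    seqid = rows$seqid[1], strand = rows$strand[1],
    start = min(rows$start), end = max(rows$end),
    ivs = IRanges::IRanges(start = sort(rows$start) + 1L, end = sort(rows$end))
  )
}

#' Classify a predicted gene model against an existing annotation
#'
#' @param prediction Gene-model tibble rows for one predicted gene.
#' @param existing Gene-model tibble of the current annotation.
#' @return List with `kind` (`"new"`, `"extended"`, `"trimmed"`,
#'   `"unchanged"`, or `"ambiguous"` when it overlaps two existing genes or
#'   shifts without a length change) and `match` (the existing gene id, or NA).
#' @export
classify_prediction <- function(prediction, existing) {
  stopifnot(length(unique(prediction$gene_id)) == 1)
  p <- gene_span(prediction, prediction$gene_id[1])
  if (nrow(existing) == 0) {
    return(list(kind = "new", match = NA_character_))
  }
  spans <- existing %>%
    group_by(.data$gene_id) %>%
    summarise(
      seqid = first(.data$seqid), start = min(.data$start),
      end = max(.data$end), .groups = "drop"
    )
  ov <- spans %>%
    filter(.data$seqid == p$seqid, .data$start < p$end, .data$end > p$start)
  if (nrow(ov) == 0) {
    return(list(kind = "new", match = NA_character_))
  }
  if (nrow(ov) >= 2) {
    return(list(kind = "ambiguous", match = NA_character_))
  }
  ex <- existing %>% filter(.data$gene_id == ov$gene_id[1])
  same <- nrow(ex) == nrow(prediction) &&
    all(sort(ex$start) == sort(prediction$start)) &&
    all(sort(ex$end) == sort(prediction$end)) &&
    ex$strand[1] == prediction$strand[1]
  if (same) {
    return(list(kind = "unchanged", match = ov$gene_id[1]))
  }
  len_p <- sum(prediction$end - prediction$start)
  len_e <- sum(ex$end - ex$start)
  kind <- if (len_p > len_e) "extended" else if (len_p < len_e) "trimmed" else "ambiguous"
  list(kind = kind, match = ov$gene_id[1])
}

# genomic interval difference a \ b as a tibble of (start, end)
interval_diff <- function(ivs_a, ivs_b) {
  d <- IRanges::setdiff(ivs_a, ivs_b)
  tibble(start = IRanges::start(d) - 1L, end = IRanges::end(d))
}

has_valid_codons <- function(prediction, genome) {
  seq <- extract_cds(prediction, genome)$seq[1]
  nchar(seq) %% 3 == 0 &&
    startsWith(seq, "ATG") &&
    substr(seq, nchar(seq) - 2, nchar(seq)) %in% STOP_CODONS
}

#' Confirm or reject one refinement
#'
#' Acceptance rules by kind: a *new* gene needs >= `new_min_reads` mRNA and
#' footprint reads on its CDS and length >= `new_min_len` nt; an *extension*
#' needs >= `ext_min_reads` of each on the added region; a *trim* is accepted
#' only with zero reads of either assay on the removed region. Accepted
#' models of any kind must begin with ATG and end with an in-frame stop.
#'
#' @param prediction Gene-model rows of the predicted gene.
#' @param existing Current annotation (all genes).
#' @param genome Genome tibble for this strain.
#' @param mrna_aln,rfp_aln Alignment tibbles (`seqid`, `pos`, `strand`,
#'   `length`) for the two assays, pooled over replicates.
#' @param new_min_reads,new_min_len,ext_min_reads Thresholds (50, 150, 20).
#' @return One-row decision tibble.
#' @export
confirm_refinement <- function(prediction, existing, genome, mrna_aln, rfp_aln,
                               new_min_reads = 50L, new_min_len = 150L,
                               ext_min_reads = 20L) {
  cls <- classify_prediction(prediction, existing)
  p <- gene_span(prediction, prediction$gene_id[1])
  if (p$end > nchar(genome$seq[genome$name == p$seqid])) {
    abort("prediction extends past the end of its sequence")
  }
  decision <- tibble(
    gene_id = prediction$gene_id[1], kind = cls$kind, match = cls$match,
    mrna_reads = NA_integer_, rfp_reads = NA_integer_,
    cds_length = sum(prediction$end - prediction$start),
    valid_codons = has_valid_codons(prediction, genome),
    accepted = FALSE
  )
  count_on <- function(ivs_tbl) {
    if (nrow(ivs_tbl) == 0) {
      return(c(0L, 0L))
    }
    m <- sum(map_int(seq_len(nrow(ivs_tbl)), function(k) {
      region_read_count(mrna_aln, p$seqid, ivs_tbl$start[k], ivs_tbl$end[k])
    }))
    r <- sum(map_int(seq_len(nrow(ivs_tbl)), function(k) {
      region_read_count(rfp_aln, p$seqid, ivs_tbl$start[k], ivs_tbl$end[k])
    }))
    c(m, r)
  }
  if (cls$kind == "new") {
    cnt <- count_on(tibble(start = prediction$start, end = prediction$end))
    decision$mrna_reads <- cnt[1]
    decision$rfp_reads <- cnt[2]
    decision$accepted <- cnt[1] >= new_min_reads && cnt[2] >= new_min_reads &&
      decision$cds_length >= new_min_len && decision$valid_codons
  } else if (cls$kind == "extended") {
    ex <- gene_span(existing, cls$match)
    added <- interval_diff(p$ivs, ex$ivs)
    cnt <- count_on(added)
    decision$mrna_reads <- cnt[1]
    decision$rfp_reads <- cnt[2]
    decision$accepted <- cnt[1] >= ext_min_reads && cnt[2] >= ext_min_reads &&
      decision$valid_codons
  } else if (cls$kind == "trimmed") {
    ex <- gene_span(existing, cls$match)
    removed <- interval_diff(ex$ivs, p$ivs)
    cnt <- count_on(removed)
    decision$mrna_reads <- cnt[1]
    decision$rfp_reads <- cnt[2]
    decision$accepted <- cnt[1] == 0 && cnt[2] == 0 && decision$valid_codons
  }
  # "unchanged" and "ambiguous" are never refinements
  decision
}

#' Refine an annotation with a set of predictions
#'
#' Runs [confirm_refinement()] for every predicted gene and applies the
#' accepted changes: accepted new genes are added, accepted extensions and
#' trims replace their matched models.
#'
#' @param predicted Gene-model tibble of de-novo predictions.
#' @inheritParams confirm_refinement
#' @return List with `decisions` (one row per prediction) and `models` (the
#'   refined annotation).
#' @export
refine_annotation <- function(existing, predicted, genome, mrna_aln, rfp_aln,
                              new_min_reads = 50L, new_min_len = 150L,
                              ext_min_reads = 20L) {
  decisions <- purrr::map_dfr(unique(predicted$gene_id), function(g) {
    confirm_refinement(
      predicted %>% filter(.data$gene_id == g), existing, genome,
      mrna_aln, rfp_aln, new_min_reads, new_min_len, ext_min_reads
    )
  })
  models <- existing
  for (i in seq_len(nrow(decisions))) {
    if (!decisions$accepted[i]) next
    pred <- predicted %>% filter(.data$gene_id == decisions$gene_id[i])
    if (decisions$kind[i] == "new") {
      models <- bind_rows(models, pred)
    } else {
      models <- models %>% filter(.data$gene_id != decisions$match[i])
      models <- bind_rows(models, mutate(pred, gene_id = decisions$match[i]))
    }
  }
  list(decisions = decisions, models = arrange(models, .data$seqid, .data$start))
}
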