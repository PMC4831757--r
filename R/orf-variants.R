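# Translated ORF variants: N-terminal extensions from upstream in-frame ATGs
# and C-terminal read-through past the annotated stop. Candidate discovery is
# purely sequence-determined; mRNA + footprint evidence decides acceptance.

# sequence immediately up/downstream of a gene, in transcript orientation;
# NULL when the contig ends too close
flank_seq <- function(gene, models, genome, span, side = c("up", "down")) {
  side <- match.arg(side)
  g <- gene_span(models, gene)
  chrom <- genome$seq[genome$name == g$seqid]
  if (length(chrom) == 0) abort(paste0("no sequence named ", g$seqid))
  take_left <- (g$strand == "+") == (side == "up")
  if (take_left) {
    if (g$start - span < 0) {
      return(NULL)
    }
    s <- substr(chrom, g$start - span + 1, g$start)
  } else {
    if (g$end + span > nchar(chrom)) {
      return(NULL)
    }
    s <- substr(chrom, g$end + 1, g$end + span)
  }
  if (g$strand == "-") revcomp(s) else s
}

# genomic interval of the `len` bases adjacent to the gene on `side`
# (transcript orientation), as 0-based half-open coordinates
flank_region <- function(gene, models, len, side = c("up", "down")) {
  side <- match.arg(side)
  g <- gene_span(models, gene)
  take_left <- (g$strand == "+") == (side == "up")
  if (take_left) {
    list(seqid = g$seqid, start = g$start - len, end = g$start, strand = g$strand)
  } else {
    list(seqid = g$seqid, start = g$end, end = g$end + len, strand = g$strand)
  }
}

#' Find a 5'-extension candidate
#'
#' Scans the `span` bases upstream of the annotated start codon for in-frame
#' ATGs with no in-frame stop codon between them and the annotated start, and
#' reports the 5'-most qualifying one (the maximal extension).
#'
#' @param gene Gene id.
#' @param models Gene-model tibble.
#' @param genome Genome tibble for the gene's strain.
#' @param span Upstream search space in nt (180 = 60 codons).
#' @return One-row tibble (`gene_id`, `ext_codons`, `seqid`, `start`, `end`,
#'   `strand`) describing the extension region (planted ATG up to, exclusive,
#'   the annotated start), or NULL when no candidate exists (including genes
#'   too close to the contig edge).
#' @export
find_extension_candidate <- function(gene, models, genome, span = 180L) {
  stopifnot(span %% 3 == 0)
  up <- flank_seq(gene, models, genome, span, "up")
  if (is.null(up)) {
    inform(paste0(gene, ": too close to the sequence edge for a ", span, " nt scan"))
    return(NULL)
  }
  cod <- codon_split(up) # cod[n] is adjacent to the annotated ATG
  n <- length(cod)
  stops <- which(cod %in% STOP_CODONS)
  atgs <- which(cod == "ATG")
  ok <- atgs[vapply(atgs, function(j) !any(stops > j), logical(1))]
  if (length(ok) == 0) {
    return(NULL)
  }
  j <- min(ok)
  ext <- n - j + 1L
  reg <- flank_region(gene, models, 3L * ext, "up")
  tibble(
    gene_id = gene, ext_codons = ext, seqid = reg$seqid,
    start = reg$start, end = reg$end, strand = reg$strand
  )
}

#' Find a 3'-read-through candidate
#'
#' Looks for the first in-frame stop codon (TAG, TAA, TGA) within `span` bases
#' downstream of the annotated stop. The read-through region runs from the
#' annotated stop (exclusive) to the new stop (inclusive); an immediately
#' adjacent stop (zero translated codons) is not a candidate.
#'
#' @inheritParams find_extension_candidate
#' @return One-row tibble (`gene_id`, `rt_codons`, `seqid`, `start`, `end`,
#'   `strand`) or NULL.
#' @export
find_readthrough_candidate <- function(gene, models, genome, span = 180L) {
  stopifnot(span %% 3 == 0)
  dn <- flank_seq(gene, models, genome, span, "down")
  if (is.null(dn)) {
    inform(paste0(gene, ": too close to the sequence edge for a ", span, " nt scan"))
    return(NULL)
  }
  cod <- codon_split(dn)
  stops <- which(cod %in% STOP_CODONS)
  if (length(stops) == 0 || min(stops) == 1) {
    return(NULL)
  }
  k <- min(stops)
  reg <- flank_region(gene, models, 3L * k, "down")
  tibble(
    gene_id = gene, rt_codons = k - 1L, seqid = reg$seqid,
    start = reg$start, end = reg$end, strand = reg$strand
  )
}

#' Confirm expression evidence over a candidate region
#'
#' Accepted when both assays contribute at least `min_reads` reads whose
#' 5'-most nucleotide falls in the region, and the full aligned spans of the
#' region's reads cover at least `min_cov_frac` of its bases in both assays.
#'
#' @param region List or one-row tibble with `seqid`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param mrna_aln,rfp_aln Alignment tibbles (`seqid`, `pos`, `strand`,
#'   `length`).
#' @param min_reads Minimum reads per assay (10).
#' @param min_cov_frac Minimum covered fraction per assay (0.8).
#' @return One-row tibble (`mrna_reads`, `rfp_reads`, `mrna_cov`, `rfp_cov`,
#'   `accepted`).
#' @export
confirm_expression <- function(region, mrna_aln, rfp_aln, min_reads = 10L,
                               min_cov_frac = 0.8) {
  if (region$end <= region$start) abort("empty candidate region")
  m <- region_read_count(mrna_aln, region$seqid, region$start, region$end, region$strand)
  r <- region_read_count(rfp_aln, region$seqid, region$start, region$end, region$strand)
  mc <- region_span_coverage(mrna_aln, region$seqid, region$start, region$end, region$strand)
  rc <- region_span_coverage(rfp_aln, region$seqid, region$start, region$end, region$strand)
  tibble(
    mrna_reads = m, rfp_reads = r, mrna_cov = mc, rfp_cov = rc,
    accepted = m >= min_reads && r >= min_reads &&
      mc >= min_cov_frac && rc >= min_cov_frac
  )
}

#' Call ORF variants across an annotation
#'
#' Runs the candidate scans for every gene and confirms each candidate
#' against the alignment evidence.
#'
#' @inheritParams find_extension_candidate
#' @inheritParams confirm_expression
#' @param span Search space in nt on either side (180).
#' @return Tibble with one row per candidate: `gene_id`, `kind`, `length`
#'   (codons), region coordinates (0-based half-open plus 1-based closed GFF
#'   columns), evidence and `accepted`.
#' @export
call_orf_variants <- function(models, genome, mrna_aln, rfp_aln, span = 180L,
                              min_reads = 10L, min_cov_frac = 0.8) {
  genes <- unique(models$gene_id)
  rows <- list()
  for (g in genes) {
    ext <- suppressMessages(find_extension_candidate(g, models, genome, span))
    if (!is.null(ext)) {
      ev <- confirm_expression(ext, mrna_aln, rfp_aln, min_reads, min_cov_frac)
      rows[[length(rows) + 1]] <- bind_cols(
        tibble(
          gene_id = g, kind = "extension-5p", length = ext$ext_codons,
          seqid = ext$seqid, start = ext$start, end = ext$end,
          strand = ext$strand
        ), ev
      )
    }
    rt <- suppressMessages(find_readthrough_candidate(g, models, genome, span))
    if (!is.null(rt)) {
      ev <- confirm_expression(rt, mrna_aln, rfp_aln, min_reads, min_cov_frac)
      rows[[length(rows) + 1]] <- bind_cols(
        tibble(
          gene_id = g, kind = "readthrough-3p", length = rt$rt_codons,
          seqid = rt$seqid, start = rt$start, end = rt$end,
          strand = rt$strand
        ), ev
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      gene_id = character(), kind = character(), length = integer(),
      seqid = character(), start = integer(), end = integer(),
      strand = character(), mrna_reads = integer(), rfp_reads = integer(),
      mrna_cov = numeric(), rfp_cov = numeric(), accepted = logical()
    ))
  }
  bind_rows(rows) %>%
    mutate(gff_start = .data$start + 1L, gff_end = .data$end)
}
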