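# Read alignment (toy iterative 3'-trimming aligner), 5'-end feature
# assignment, and per-gene quantification.
#
# The aligner is a naive exact scan with mismatches, meant for toy genomes up
# to ~1 Mb; real libraries would come in as externally produced alignments, to
# which only the assignment and counting layers apply.

#' Feature-assignment offsets
#'
#' The windows that classify an aligned read by its 5'-most nucleotide, in
#' transcript-oriented coordinates anchored at the CDS. With the defaults a 5'
#' end 16 nt upstream of the start codon still belongs to the CDS (initiating
#' ribosomes protect upstream bases), 17 nt upstream is 5'-UTR; the CDS window
#' ends 14 nt short of the last CDS base, where the 3'-UTR window begins.
#'
#' @param cds_upstream CDS window reaches this many bases upstream of the
#'   first CDS base (16).
#' @param cds_last CDS window stops this many bases upstream of the last CDS
#'   base (14).
#' @param utr5_last 5'-UTR window stops this many bases upstream of the first
#'   CDS base (17).
#' @param utr3_first 3'-UTR window starts this many bases upstream of the last
#'   CDS base (13).
#' @param utr3_last 3'-UTR window stops this many bases upstream of the last
#'   transcript base (28).
#' @param intron_last Intron window stops this many bases upstream of the last
#'   intron base (8).
#' @return Validated list of offsets.
#' @export
assignment_offsets <- function(cds_upstream = 16L, cds_last = 14L,
                               utr5_last = 17L, utr3_first = 13L,
                               utr3_last = 28L, intron_last = 8L) {
  off <- list(
    cds_upstream = cds_upstream, cds_last = cds_last, utr5_last = utr5_last,
    utr3_first = utr3_first, utr3_last = utr3_last, intron_last = intron_last
  )
  # windows are half-open after conversion; adjacent windows must tile without
  # overlap: 5'UTR ends where the CDS window starts, 3'UTR starts where it ends
  if (utr5_last - 1 < cds_upstream) {
    abort("5'UTR and CDS windows overlap (utr5_last must exceed cds_upstream)")
  }
  if (utr3_first > cds_last - 1) {
    abort("CDS and 3'UTR windows overlap (utr3_first must be < cds_last)")
  }
  off
}

# per-chromosome hit scan at <= max_mismatch, both strands; returns tibble of
# candidate alignments with mismatch counts
scan_hits <- function(pattern, genome, max_mismatch) {
  pat <- Biostrings::DNAString(pattern)
  rcpat <- Biostrings::reverseComplement(pat)
  out <- list()
  for (i in seq_len(nrow(genome))) {
    subject <- Biostrings::DNAString(genome$seq[i])
    for (str in c("+", "-")) {
      p <- if (str == "+") pat else rcpat
      m <- Biostrings::matchPattern(p, subject,
        max.mismatch = max_mismatch, with.indels = FALSE
      )
      if (length(m) == 0) next
      mm <- Biostrings::neditStartingAt(p, subject, starting.at = IRanges::start(m))
      # 5'-most nucleotide of the *read*: left end on +, right end on -
      pos5 <- if (str == "+") IRanges::start(m) - 1L else IRanges::end(m) - 1L
      out[[length(out) + 1]] <- tibble(
        seqid = genome$name[i], pos = as.integer(pos5), strand = str,
        mismatches = as.integer(mm)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      seqid = character(), pos = integer(), strand = character(),
      mismatches = integer()
    ))
  }
  bind_rows(out)
}

#' Iteratively trim and align one read
#'
#' Ribosome-footprint reads carry spurious 3' adenines, so the read is aligned
#' repeatedly, removing one 3' base per round, until a hit survives. The first
#' round (fewest trims) with any alignment decides the outcome: a unique
#' best-mismatch position is reported; ties (multi-mappers) make the read
#' unmapped. Alignments shorter than `min_len` are never attempted.
#'
#' @param read_seq Read sequence (A/C/G/T string).
#' @param genome Genome tibble (`name`, `seq`).
#' @param min_len Minimum surviving alignment length (23).
#' @param max_mismatch Maximum mismatches (2).
#' @return One-row tibble (`seqid`, `pos`, `strand`, `length`, `mismatches`,
#'   `trimmed`) or NULL when unmapped. `pos` is the 0-based genomic position
#'   of the read's 5'-most nucleotide.
#' @export
iterative_trim_align <- function(read_seq, genome, min_len = 23L,
                                 max_mismatch = 2L) {
  read_seq <- toupper(read_seq)
  if (nchar(read_seq) < min_len) {
    abort(paste0("read shorter than min_len (", min_len, ")"))
  }
  for (trim in 0:(nchar(read_seq) - min_len)) {
    cand <- substr(read_seq, 1, nchar(read_seq) - trim)
    hits <- scan_hits(cand, genome, max_mismatch)
    if (nrow(hits) == 0) next
    best <- hits %>% filter(.data$mismatches == min(.data$mismatches))
    if (nrow(best) > 1) {
      return(NULL) # non-unique best alignment
    }
    return(best %>% mutate(length = nchar(cand), trimmed = as.integer(trim)))
  }
  NULL
}

#' Align a table of reads
#'
#' @param reads Tibble (`read_id`, `seq`).
#' @inheritParams iterative_trim_align
#' @return Alignment tibble, one row per uniquely aligned read.
#' @export
align_reads <- function(reads, genome, min_len = 23L, max_mismatch = 2L) {
  rows <- purrr::map2(reads$read_id, reads$seq, function(id, s) {
    a <- iterative_trim_align(s, genome, min_len, max_mismatch)
    if (is.null(a)) NULL else mutate(a, read_id = id)
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    return(tibble(
      read_id = character(), seqid = character(), pos = integer(),
      strand = character(), length = integer(), mismatches = integer(),
      trimmed = integer()
    ))
  }
  bind_rows(rows) %>%
    select("read_id", "seqid", "pos", "strand", "length", "mismatches", "trimmed")
}

# CDS-anchored transcript coordinate of a genomic position for one gene.
# ivs: interval matrix (start, end), genomically sorted. Returns either
# kind "cds_axis" with coordinate c (0 = first CDS base in transcript
# orientation, negative = upstream of the start codon, L - 1 + d = d bases
# past the last CDS base) or kind "intron" with the transcript-oriented
# offset within the intron.
anchor_position <- function(pos, ivs, strand) {
  L <- sum(ivs[, 2] - ivs[, 1])
  n <- nrow(ivs)
  cum <- cumsum(c(0, ivs[, 2] - ivs[, 1]))
  if (pos < ivs[1, 1]) {
    d <- ivs[1, 1] - pos # bases left of the leftmost genomic CDS base
    cc <- if (strand == "+") -d else L + d - 1
    return(list(kind = "cds_axis", c = cc))
  }
  if (pos >= ivs[n, 2]) {
    d <- pos - ivs[n, 2] + 1
    cc <- if (strand == "+") L + d - 1 else -d
    return(list(kind = "cds_axis", c = cc))
  }
  for (k in seq_len(n)) {
    if (pos >= ivs[k, 1] && pos < ivs[k, 2]) {
      gidx <- cum[k] + (pos - ivs[k, 1])
      cc <- if (strand == "+") gidx else L - 1 - gidx
      return(list(kind = "cds_axis", c = cc))
    }
    if (k < n && pos >= ivs[k, 2] && pos < ivs[k + 1, 1]) {
      ilen <- ivs[k + 1, 1] - ivs[k, 2]
      d <- if (strand == "+") pos - ivs[k, 2] else ivs[k + 1, 1] - 1 - pos
      return(list(kind = "intron", d = d, len = ilen))
    }
  }
  stop("unreachable")
}

#' Assign alignments to genomic features by 5'-end position
#'
#' Labels every alignment `CDS`, `5UTR`, `intron`, `3UTR` or `unassigned`
#' using the strand-aware offset windows of [assignment_offsets()]. Transcript
#' extent is the CDS extended by `tx_flank` bases on each side (no UTR
#' annotation is assumed). Reads claimed by more than one gene are unassigned.
#'
#' @param alignments Alignment tibble (needs `seqid`, `pos`, `strand`).
#' @param models Gene-model tibble.
#' @param offsets [assignment_offsets()].
#' @param tx_flank Length-2 vector: assumed 5' and 3' UTR extents in nt.
#' @return `alignments` with added `gene_id`, `feature`, `cds_pos` (0-based
#'   position within the concatenated CDS, NA unless the 5' end lies inside
#'   the CDS proper).
#' @export
assign_to_feature <- function(alignments, models,
                              offsets = assignment_offsets(),
                              tx_flank = c(60L, 60L)) {
  check_gene_models(models)
  genes <- models %>%
    group_by(.data$gene_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(
      seqid = first(.data$seqid), strand = first(.data$strand),
      ivs = list(cbind(.data$start, .data$end)),
      gmin = min(.data$start), gmax = max(.data$end), .groups = "drop"
    )
  pad <- max(tx_flank) + 1L
  n_al <- nrow(alignments)
  feature <- rep("unassigned", n_al)
  gene_out <- rep(NA_character_, n_al)
  cds_pos <- rep(NA_integer_, n_al)
  if (n_al == 0) {
    return(mutate(alignments,
      gene_id = gene_out, feature = feature, cds_pos = cds_pos
    ))
  }
  al_gr <- GenomicRanges::GRanges(alignments$seqid,
    IRanges::IRanges(alignments$pos + 1L, width = 1L),
    strand = alignments$strand
  )
  g_gr <- GenomicRanges::GRanges(genes$seqid,
    IRanges::IRanges(genes$gmin + 1L - pad, genes$gmax + pad),
    strand = genes$strand
  )
  hits <- GenomicRanges::findOverlaps(al_gr, g_gr, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in unique(qh)) {
    cand <- sh[qh == i]
    labels <- character(0)
    cpos <- integer(0)
    gid <- character(0)
    for (g in cand) {
      ivs <- genes$ivs[[g]]
      strand <- genes$strand[g]
      L <- sum(ivs[, 2] - ivs[, 1])
      a <- anchor_position(alignments$pos[i], ivs, strand)
      lab <- "unassigned"
      cp <- NA_integer_
      if (a$kind == "intron") {
        if (a$d >= 0 && a$d < a$len - offsets$intron_last) lab <- "intron"
      } else {
        cc <- a$c
        if (cc >= -offsets$cds_upstream && cc < L - offsets$cds_last) {
          lab <- "CDS"
          if (cc >= 0 && cc < L) cp <- as.integer(cc)
        } else if (cc >= -tx_flank[1] && cc < -(offsets$utr5_last - 1)) {
          lab <- "5UTR"
        } else if (cc >= L - 1 - offsets$utr3_first &&
          cc < L - 1 + tx_flank[2] - offsets$utr3_last + 1) {
          lab <- "3UTR"
        }
      }
      if (lab != "unassigned") {
        labels <- c(labels, lab)
        cpos <- c(cpos, cp)
        gid <- c(gid, genes$gene_id[g])
      }
    }
    if (length(labels) == 1) {
      feature[i] <- labels
      gene_out[i] <- gid
      cds_pos[i] <- cpos
    }
  }
  mutate(alignments, gene_id = gene_out, feature = feature, cds_pos = cds_pos)
}

#' Per-gene CDS counts and base coverage
#'
#' Counts reads whose 5'-most nucleotide lands inside the CDS proper and
#' builds the per-base 5'-end coverage vector (transcript orientation), so
#' `sum(counts) == n_cds` holds for every gene. Genes below `min_reads` are
#' flagged rather than dropped.
#'
#' @param assigned Output of [assign_to_feature()].
#' @param models Gene-model tibble.
#' @param min_reads CDS read count needed to retain a gene (50).
#' @return Tibble (`gene_id`, `n_cds`, `retained`, `counts`), `counts` a
#'   list-column of integer vectors of CDS length.
#' @export
base_coverage <- function(assigned, models, min_reads = 50L) {
  lens <- cds_lengths(models)
  in_cds <- assigned %>% filter(.data$feature == "CDS", !is.na(.data$cds_pos))
  lens %>%
    mutate(
      counts = map2(.data$gene_id, .data$cds_length, function(g, L) {
        p <- in_cds$cds_pos[in_cds$gene_id == g]
        as.integer(tabulate(p + 1L, nbins = L))
      }),
      n_cds = map_int(.data$counts, sum),
      retained = .data$n_cds >= min_reads
    ) %>%
    select("gene_id", "n_cds", "retained", "counts")
}

#' @rdname base_coverage
#' @param gene_id Single gene id.
#' @return `cds_read_count()`: the integer CDS read count for one gene.
#' @export
cds_read_count <- function(assigned, models, gene_id) {
  cov <- base_coverage(assigned, models, min_reads = 0L)
  row <- cov[cov$gene_id == gene_id, ]
  if (nrow(row) == 0) abort(paste0("unknown gene ", gene_id))
  row$n_cds[[1]]
}
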