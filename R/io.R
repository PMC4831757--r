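# Sequence and annotation I/O plus ortholog bookkeeping.
#
# Conventions: genomes are tibbles with columns `name`, `seq` (uppercase
# A/C/G/T/N); gene models are tibbles with one row per CDS interval, 0-based
# half-open coordinates (`start`, `end`), columns `gene_id`, `seqid`, `strand`,
# `start`, `end`, `source`. GFF3 on disk is 1-based closed; reading and writing
# are the only places that conversion happens.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `name`, `seq`; sequences uppercased and
#'   restricted to A/C/G/T/N.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA record name: ", nm[duplicated(nm)][1]))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("illegal characters in FASTA record '", nm[bad][1], "'"))
  }
  tibble(name = unname(nm), seq = unname(seqs))
}

#' Write a FASTA file
#'
#' @param path Output path.
#' @param genome Tibble with columns `name`, `seq`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(path, genome) {
  stopifnot(all(c("name", "seq") %in% names(genome)))
  set <- Biostrings::DNAStringSet(setNames(genome$seq, genome$name))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# line-level GFF3 validation so parse errors can point at a line number
validate_gff_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      abort(paste0("GFF parse error at line ", i, ": expected 9 tab-separated fields"))
    }
    s <- suppressWarnings(as.numeric(f[4]))
    e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e)) {
      abort(paste0("GFF parse error at line ", i, ": non-numeric coordinates"))
    }
    if (e < s) {
      abort(paste0("GFF parse error at line ", i, ": end < start"))
    }
  }
  invisible(TRUE)
}

#' Read CDS gene models from GFF3
#'
#' CDS features are grouped by their `Parent` attribute (falling back to `ID`).
#' GFF 1-based closed coordinates become 0-based half-open internally.
#'
#' @param path Path to a GFF3 file.
#' @return Gene-model tibble (`gene_id`, `seqid`, `strand`, `start`, `end`,
#'   `source`), intervals sorted in genomic order within gene.
#' @export
read_gene_gff <- function(path) {
  validate_gff_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) {
    return(tibble(
      gene_id = character(), seqid = character(), strand = character(),
      start = integer(), end = integer(), source = character()
    ))
  }
  parent <- as.character(S4Vectors::mcols(gr)$Parent %||% NA_character_)
  if (!is.null(S4Vectors::mcols(gr)$Parent)) {
    pl <- S4Vectors::mcols(gr)$Parent
    parent <- vapply(as.list(pl), function(x) {
      if (length(x) == 0) NA_character_ else as.character(x[1])
    }, character(1))
  }
  id <- as.character(S4Vectors::mcols(gr)$ID %||% rep(NA_character_, length(gr)))
  gene <- ifelse(is.na(parent), id, parent)
  if (anyNA(gene)) abort("CDS feature without Parent or ID attribute")
  src <- as.character(S4Vectors::mcols(gr)$source %||% rep(".", length(gr)))
  tibble(
    gene_id = sub("^gene:", "", gene),
    seqid = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    source = src
  ) %>%
    arrange(.data$gene_id, .data$start)
}

#' Write gene models to GFF3
#'
#' @param path Output path.
#' @param models Gene-model tibble.
#' @return `path`, invisibly.
#' @export
write_gene_gff <- function(path, models) {
  check_gene_models(models)
  gr <- GenomicRanges::GRanges(
    seqnames = models$seqid,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    strand = models$strand
  )
  S4Vectors::mcols(gr)$source <- models$source %||% "ribodiverge"
  S4Vectors::mcols(gr)$type <- "CDS"
  # phase: bases to skip before the first complete codon, in transcript order
  phase <- models %>%
    mutate(.row = row_number()) %>%
    group_by(.data$gene_id) %>%
    arrange(if_else(.data$strand == "-", -.data$start, .data$start),
      .by_group = TRUE
    ) %>%
    mutate(.phase = (3L - cumsum(dplyr::lag(.data$end - .data$start, default = 0L)) %% 3L) %% 3L) %>%
    ungroup() %>%
    arrange(.data$.row) %>%
    pull(".phase")
  S4Vectors::mcols(gr)$phase <- phase
  S4Vectors::mcols(gr)$ID <- paste0(models$gene_id, ".cds", seq_len(nrow(models)))
  S4Vectors::mcols(gr)$Parent <- models$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

check_gene_models <- function(models) {
  need <- c("gene_id", "seqid", "strand", "start", "end")
  if (!all(need %in% names(models))) {
    abort(paste0("gene models need columns: ", paste(need, collapse = ", ")))
  }
  if (any(models$end < models$start)) abort("gene model interval with end < start")
  if (!all(models$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  bad <- models %>%
    group_by(.data$gene_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(ok = all(diff(.data$start) >= 0) &&
      (n() < 2 || all(head(.data$end, -1) <= tail(.data$start, -1))))
  if (!all(bad$ok)) {
    abort(paste0("overlapping CDS intervals within gene ", bad$gene_id[!bad$ok][1]))
  }
  invisible(TRUE)
}

# total CDS length per gene
cds_lengths <- function(models) {
  models %>%
    group_by(.data$gene_id) %>%
    summarise(cds_length = as.integer(sum(.data$end - .data$start)), .groups = "drop")
}

#' Extract CDS sequences in transcript orientation
#'
#' Intervals are concatenated in genomic order; minus-strand genes are
#' reverse-complemented so the result reads 5' to 3' in the mRNA.
#'
#' @param models Gene-model tibble.
#' @param genome Genome tibble (`name`, `seq`).
#' @return Tibble `gene_id`, `seq`.
#' @export
extract_cds <- function(models, genome) {
  check_gene_models(models)
  seqs <- setNames(genome$seq, genome$name)
  out <- models %>%
    group_by(.data$gene_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(
      seqid = first(.data$seqid), strand = first(.data$strand),
      seq = paste(substring(seqs[first(.data$seqid)], .data$start + 1, .data$end),
        collapse = ""
      ),
      .groups = "drop"
    )
  minus <- out$strand == "-"
  out$seq[minus] <- vapply(out$seq[minus], revcomp, character(1))
  out %>% select("gene_id", "seq")
}

#' Marginal nucleotide frequencies
#'
#' @param seq A/C/G/T/N string; Ns are excluded from the denominator.
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
nucleotide_freq <- function(seq) {
  stopifnot(length(seq) == 1L, nchar(seq) > 0)
  counts <- vapply(DNA_BASES, function(b) {
    lengths(regmatches(seq, gregexpr(b, seq, fixed = TRUE)))
  }, integer(1))
  tot <- sum(counts)
  if (tot == 0) abort("sequence contains no A/C/G/T bases")
  counts / tot
}

#' Read / write an ortholog table
#'
#' Plain TSV with header columns `gene_b`, `gene_y`.
#'
#' @param path Path to the table.
#' @return Tibble with columns `gene_b`, `gene_y`.
#' @export
read_ortholog_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_b", "gene_y") %in% names(tab))) {
    abort("ortholog table needs columns gene_b, gene_y")
  }
  as_tibble(tab)
}

#' @rdname read_ortholog_table
#' @param pairs Tibble with columns `gene_b`, `gene_y`.
#' @export
write_ortholog_table <- function(path, pairs) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' Drop ortholog pairs with positionally ambiguous genes
#'
#' Retains only pairs whose members occupy a genomic location shared with no
#' other gene (strand-blind interval intersection of whole-gene footprints,
#' i.e. one ORF per chromosome location). Idempotent.
#'
#' @param pairs Ortholog tibble (`gene_b`, `gene_y`).
#' @param models Gene models for both strains (seqids distinguish genomes).
#' @return Filtered ortholog tibble.
#' @export
dedup_orthologs <- function(pairs, models) {
  check_gene_models(models)
  missing <- setdiff(c(pairs$gene_b, pairs$gene_y), models$gene_id)
  if (length(missing) > 0) {
    abort(paste0("ortholog pair references missing gene: ", missing[1]))
  }
  span <- models %>%
    group_by(.data$gene_id) %>%
    summarise(
      seqid = first(.data$seqid), start = min(.data$start),
      end = max(.data$end), .groups = "drop"
    )
  gr <- GenomicRanges::GRanges(
    seqnames = span$seqid,
    ranges = IRanges::IRanges(start = span$start + 1L, end = span$end),
    strand = "*"
  )
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  clashing <- span$gene_id[unique(S4Vectors::queryHits(hits))]
  pairs %>% filter(!(.data$gene_b %in% clashing) & !(.data$gene_y %in% clashing))
}

#' Attach mappable lengths and nucleotide composition to ortholog pairs
#'
#' `L` is total CDS length; `pi` the marginal nucleotide frequency of the CDS.
#'
#' @param pairs Ortholog tibble (`gene_b`, `gene_y`).
#' @param cds_seqs Tibble (`gene_id`, `seq`) covering both strains' genes.
#' @return `pairs` with added `L_b`, `L_y` and list-columns `pi_b`, `pi_y`.
#' @export
ortholog_profile <- function(pairs, cds_seqs) {
  seqs <- setNames(cds_seqs$seq, cds_seqs$gene_id)
  missing <- setdiff(c(pairs$gene_b, pairs$gene_y), names(seqs))
  if (length(missing) > 0) abort(paste0("no CDS sequence for gene ", missing[1]))
  pairs %>%
    mutate(
      L_b = nchar(seqs[.data$gene_b]),
      L_y = nchar(seqs[.data$gene_y]),
      pi_b = map(seqs[.data$gene_b], nucleotide_freq),
      pi_y = map(seqs[.data$gene_y], nucleotide_freq)
    )
}
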