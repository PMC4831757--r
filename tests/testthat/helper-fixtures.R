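# shared fixture builders; everything is generated in code under fixed seeds

random_cds <- function(n_codons, seed = NULL) {
  build <- function() {
    paste0(
      "ATG",
      paste(sense_codons()[sample.int(61, n_codons - 2, replace = TRUE)], collapse = ""),
      "TAA"
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# single-gene plus-strand toy locus: left flank + CDS + right flank
toy_locus <- function(cds, left = 300, right = 300, chrom = "chr1", seed = 99) {
  withr::with_seed(seed, {
    genome <- tibble::tibble(
      name = chrom,
      seq = paste0(
        paste(sample(c("A", "C", "G", "T"), left, TRUE), collapse = ""),
        cds,
        paste(sample(c("A", "C", "G", "T"), right, TRUE), collapse = "")
      )
    )
  })
  models <- tibble::tibble(
    gene_id = "gA", seqid = chrom, strand = "+",
    start = as.integer(left), end = as.integer(left + nchar(cds)),
    source = "test"
  )
  list(genome = genome, models = models)
}

# ortholog_counts object with directly supplied per-gene coverage vectors:
# cov_list[[gene]] = list of counts vectors indexed [[strain]][[assay]][[rep]]
make_oc <- function(seqs_b, seqs_y, cov_b, cov_y, lib_sizes = NULL) {
  n <- length(seqs_b)
  ids_b <- sprintf("t%02d_B", seq_len(n))
  ids_y <- sprintf("t%02d_Y", seq_len(n))
  cds <- tibble::tibble(gene_id = c(ids_b, ids_y), seq = c(seqs_b, seqs_y))
  pairs <- tibble::tibble(gene_b = ids_b, gene_y = ids_y)
  rows <- list()
  add <- function(ids, cov, strain) {
    for (i in seq_len(n)) {
      for (assay in names(cov[[i]])) {
        for (r in seq_along(cov[[i]][[assay]])) {
          rows[[length(rows) + 1]] <<- tibble::tibble(
            gene_id = ids[i], strain = strain, assay = assay,
            replicate = r, counts = list(as.integer(cov[[i]][[assay]][[r]]))
          )
        }
      }
    }
  }
  add(ids_b, cov_b, "B")
  add(ids_y, cov_y, "Y")
  ortholog_counts(pairs, cds, dplyr::bind_rows(rows), lib_sizes)
}

# both replicates and assays share one vector per strain (convenience)
make_oc_simple <- function(seq_b, seq_y, counts_b, counts_y, assays = "mRNA",
                           lib_sizes = NULL) {
  cov <- function(counts) {
    list(setNames(
      lapply(assays, function(a) list(counts, counts)),
      assays
    ))
  }
  make_oc(seq_b, seq_y, cov(counts_b), cov(counts_y), lib_sizes)
}

# role-swapped view of the same data: gene ids keep their identity, but the
# Y genes become the B side (and strain labels flip in the coverage table)
swap_roles <- function(oc) {
  pairs <- tibble::tibble(
    gene_b = oc$pairs$gene_y, gene_y = oc$pairs$gene_b,
    L_b = oc$pairs$L_y, L_y = oc$pairs$L_b,
    pi_b = oc$pairs$pi_y, pi_y = oc$pairs$pi_b
  )
  coverage <- oc$coverage
  coverage$strain <- ifelse(coverage$strain == "B", "Y", "B")
  cds <- tibble::tibble(gene_id = names(oc$seqs), seq = unname(oc$seqs))
  ortholog_counts(pairs, cds, coverage)
}
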