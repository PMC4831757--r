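# hand-built upstream contexts around an annotated gene
ctx_locus <- function(upstream, cds = random_cds(30, seed = 71),
                      downstream = NULL, left = 210, right = 210, seed = 72) {
  withr::with_seed(seed, {
    pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    lpad <- pad(left - nchar(upstream))
    rpad <- pad(right - nchar(downstream %||% ""))
  })
  genome <- tibble::tibble(
    name = "chr1",
    seq = paste0(lpad, upstream, cds, downstream %||% "", rpad)
  )
  start <- nchar(lpad) + nchar(upstream)
  models <- tibble::tibble(
    gene_id = "gA", seqid = "chr1", strand = "+",
    start = as.integer(start), end = as.integer(start + nchar(cds)),
    source = "t"
  )
  list(genome = genome, models = models)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("extension scan returns the 5'-most in-frame ATG with a clear run", {
  # ... ATG GCT GCT [annotated ATG]: a 3-codon extension candidate (the
  # blocking TAA keeps further-upstream ATGs out of play)
  fx <- ctx_locus("TAAATGGCTGCT")
  cand <- find_extension_candidate("gA", fx$models, fx$genome)
  expect_equal(cand$ext_codons, 3L)
  expect_equal(cand$end - cand$start, 9L)
  expect_equal(cand$end, fx$models$start)
})

test_that("an intervening in-frame stop disqualifies the upstream ATG", {
  fx <- ctx_locus("ATGTAAGCTGCT") # ATG then TAA before the annotated start
  expect_null(find_extension_candidate("gA", fx$models, fx$genome))
})

test_that("a stop immediately before the only ATG blocks nothing (ATG still scans)", {
  # stop upstream of the ATG does not disqualify it; only stops *between*
  # ATG and the annotated start do
  fx <- ctx_locus("TAGATGGCT")
  cand <- find_extension_candidate("gA", fx$models, fx$genome)
  expect_equal(cand$ext_codons, 2L)
})

test_that("genes too close to the contig edge are skipped with a message", {
  cds <- random_cds(30, seed = 73)
  genome <- tibble::tibble(name = "chr1", seq = paste0(strrep("G", 60), cds, strrep("C", 300)))
  models <- tibble::tibble(
    gene_id = "gA", seqid = "chr1", strand = "+",
    start = 60L, end = 60L + nchar(cds), source = "t"
  )
  expect_message(
    out <- find_extension_candidate("gA", models, genome),
    "edge"
  )
  expect_null(out)
})

test_that("read-through region runs to the first downstream in-frame stop", {
  fx <- ctx_locus("TAA", downstream = "GCTGCTTAAGCG")
  cand <- find_readthrough_candidate("gA", fx$models, fx$genome)
  expect_equal(cand$rt_codons, 2L)
  expect_equal(cand$start, fx$models$end)
  expect_equal(cand$end - cand$start, 9L) # old stop exclusive -> new stop inclusive
  # an immediately adjacent stop is a zero-length read-through: no candidate
  fx0 <- ctx_locus("TAA", downstream = "TGAGCTGCT")
  expect_null(find_readthrough_candidate("gA", fx0$models, fx0$genome))
  # no stop in 60 downstream codons: no candidate
  fx_none <- ctx_locus("TAA", downstream = paste(rep("GCT", 70), collapse = ""))
  expect_null(find_readthrough_candidate("gA", fx_none$models, fx_none$genome))
})

test_that("expression confirmation enforces both printed thresholds exactly", {
  region <- list(seqid = "chr1", start = 100L, end = 280L, strand = "+")
  # non-overlapping reads spaced 15 nt apart; 12 reads of 12 nt cover exactly
  # 144/180 bases = 0.8
  mk <- function(n, lens = 12L) {
    tibble::tibble(
      seqid = "chr1", pos = as.integer(100 + (seq_len(n) - 1) * 15),
      strand = "+", length = as.integer(rep_len(lens, n))
    )
  }
  ev12 <- mk(12)
  r <- confirm_expression(region, ev12, ev12)
  expect_equal(r$mrna_reads, 12L)
  expect_equal(r$mrna_cov, 0.8)
  expect_true(r$accepted)
  # 9 reads in one assay: rejected
  expect_false(confirm_expression(region, ev12, mk(9))$accepted)
  # coverage fraction just under 0.8 (143/180 = 0.794): rejected
  ev_thin <- mk(12, lens = c(rep(12L, 11), 11L))
  r_thin <- confirm_expression(region, ev_thin, ev12)
  expect_equal(r_thin$mrna_reads, 12L)
  expect_lt(r_thin$mrna_cov, 0.8)
  expect_false(r_thin$accepted)
  expect_error(
    confirm_expression(list(seqid = "c", start = 5L, end = 5L, strand = "+"),
      ev12, ev12
    ),
    "empty"
  )
})

test_that("candidates are sequence-determined; acceptance needs evidence", {
  fx <- ctx_locus("TAAATGGCTGCT", downstream = "GCTGCTTAAGCG")
  empty <- tibble::tibble(
    seqid = character(), pos = integer(), strand = character(), length = integer()
  )
  calls <- call_orf_variants(fx$models, fx$genome, empty, empty)
  expect_equal(nrow(calls), 2)
  expect_false(any(calls$accepted))
  # saturating evidence accepts both
  tile <- function(s, e) {
    # two reads per base: the 9 nt candidate regions still clear the 10-read bar
    tibble::tibble(
      seqid = "chr1", pos = as.integer(rep(seq(s, e - 1), 2)), strand = "+",
      length = 27L
    )
  }
  full <- dplyr::bind_rows(
    tile(calls$start[1], calls$end[1]), tile(calls$start[2], calls$end[2])
  )
  calls2 <- call_orf_variants(fx$models, fx$genome, full, full)
  expect_true(all(calls2$accepted))
  # candidate fields are identical with and without coverage
  expect_equal(
    calls[, c("gene_id", "kind", "length", "start", "end")],
    calls2[, c("gene_id", "kind", "length", "start", "end")]
  )
})

test_that("planted simulator variants are recovered exactly, on both strands", {
  ov <- tibble::tibble(
    gene = c(2L, 5L), kind = c("extension-5p", "readthrough-3p"),
    length = c(6L, 4L)
  )
  cfg <- sim_config(n_genes = 6, orf_variant_spec = ov, frac_minus = 0.5, seed = 74)
  sim <- simulate_strain_pair(cfg)
  models_b <- dplyr::filter(sim$models, endsWith(gene_id, "_B"))
  ext <- find_extension_candidate("g002_B", models_b, sim$genome_b)
  expect_equal(ext$ext_codons, 6L)
  rt <- find_readthrough_candidate("g005_B", models_b, sim$genome_b)
  expect_equal(rt$rt_codons, 4L)
  # minus-strand planting works identically in the Y genome
  models_y <- dplyr::filter(sim$models, endsWith(gene_id, "_Y"))
  ext_y <- find_extension_candidate("g002_Y", models_y, sim$genome_y)
  expect_equal(ext_y$ext_codons, 6L)
})

test_that("reverse-complementing the genome leaves calls invariant", {
  fx <- ctx_locus("TAAATGGCTGCT", downstream = "GCTGCTTAAGCG")
  G <- nchar(fx$genome$seq)
  rc_genome <- tibble::tibble(
    name = "chr1",
    seq = as.character(Biostrings::reverseComplement(Biostrings::DNAString(fx$genome$seq)))
  )
  rc_models <- dplyr::mutate(fx$models,
    strand = "-",
    start = G - fx$models$end, end = G - fx$models$start
  )
  a <- find_extension_candidate("gA", fx$models, fx$genome)
  b <- find_extension_candidate("gA", rc_models, rc_genome)
  expect_equal(b$ext_codons, a$ext_codons)
  expect_equal(b$start, G - a$end)
  expect_equal(b$end, G - a$start)
  ra <- find_readthrough_candidate("gA", fx$models, fx$genome)
  rb <- find_readthrough_candidate("gA", rc_models, rc_genome)
  expect_equal(rb$rt_codons, ra$rt_codons)
})
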