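# Resampling divergence tests. The null for an ortholog pair is built by
# bootstrap-resampling base-level 5'-end counts from one gene, stratified so
# the drawn positions match the *other* context's length and nucleotide
# composition (L, pi). This absorbs gene-length and sequence-composition bias
# that parametric count models ignore.

# partition L_target draws across the four base classes by pi_target
# (largest-remainder rounding), reallocating quota away from base classes the
# source gene lacks
stratified_quotas <- function(L_target, pi_target, class_sizes) {
  w <- as.numeric(pi_target)
  stopifnot(length(w) == 4, all(w >= 0))
  w[class_sizes == 0] <- 0
  if (sum(w) == 0) abort("no source positions in any base class with positive target frequency")
  largest_remainder(L_target, w)
}

split_by_base <- function(counts, seq) {
  if (length(counts) == 0) abort("empty coverage vector")
  if (nchar(seq) != length(counts)) abort("coverage length does not match sequence")
  bases <- strsplit(seq, "")[[1]]
  lapply(DNA_BASES, function(b) as.numeric(counts[bases == b]))
}

#' Stratified composition-matched bootstrap totals
#'
#' Draws, with replacement, `L_target` positions from the source gene's
#' base-level counts — `n_b` positions from those carrying base `b`, where the
#' `n_b` partition `L_target` proportionally to `pi_target` — and returns the
#' summed counts. Base classes absent from the source have their quota
#' reallocated proportionally across the remaining classes.
#'
#' @param counts Per-base 5'-end counts of the source gene.
#' @param seq Source gene CDS sequence (same length as `counts`).
#' @param L_target Mappable length of the target context.
#' @param pi_target Length-4 nucleotide frequency vector (A, C, G, T).
#' @param n_rep Number of bootstrap totals to return.
#' @param seed Optional seed.
#' @return Numeric vector of `n_rep` pseudo-count totals.
#' @export
stratified_resample_total <- function(counts, seq, L_target, pi_target,
                                      n_rep = 1L, seed = NULL) {
  cls <- split_by_base(counts, seq)
  quota <- stratified_quotas(L_target, pi_target, lengths(cls))
  draw <- function() resample_totals_cpp(cls, quota, as.integer(n_rep))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Bundle ortholog pairs with coverage and library sizes
#'
#' @param pairs Ortholog tibble, typically from [ortholog_profile()] (columns
#'   `gene_b`, `gene_y`, `L_b`, `L_y`, `pi_b`, `pi_y`; the profile is computed
#'   from `cds_seqs` if absent).
#' @param cds_seqs Tibble (`gene_id`, `seq`) for both strains.
#' @param coverage Tibble (`gene_id`, `strain`, `assay`, `replicate`,
#'   `counts`) as produced by [simulate_coverage()] or built from
#'   [base_coverage()].
#' @param lib_sizes Optional tibble (`strain`, `assay`, `replicate`,
#'   `lib_size`); defaults to total counts summed over genes, i.e. total
#'   CDS-assigned reads per library.
#' @return An `ortholog_counts` object.
#' @export
ortholog_counts <- function(pairs, cds_seqs, coverage, lib_sizes = NULL) {
  if (!all(c("L_b", "L_y") %in% names(pairs))) {
    pairs <- ortholog_profile(pairs, cds_seqs)
  }
  if (is.null(lib_sizes)) {
    lib_sizes <- coverage %>%
      group_by(.data$strain, .data$assay, .data$replicate) %>%
      summarise(lib_size = sum(map_dbl(.data$counts, sum)), .groups = "drop")
  }
  structure(
    list(
      pairs = pairs,
      seqs = setNames(cds_seqs$seq, cds_seqs$gene_id),
      coverage = coverage,
      lib = lib_sizes
    ),
    class = "ortholog_counts"
  )
}

oc_counts <- function(oc, gene, assay, rep) {
  row <- oc$coverage %>%
    filter(.data$gene_id == gene, .data$assay == !!assay, .data$replicate == rep)
  if (nrow(row) == 0) {
    abort(paste0("missing replicate ", rep, " (", assay, ") for gene ", gene))
  }
  row$counts[[1]]
}

oc_lib <- function(oc, strain, assay, rep) {
  v <- oc$lib %>%
    filter(.data$strain == !!strain, .data$assay == !!assay, .data$replicate == rep) %>%
    pull("lib_size")
  if (length(v) != 1) abort(paste0("missing library size for ", strain, "/", assay, "/", rep))
  v
}

# N null log2 ratios for one (pair row, assay, replicate, source gene).
# pseudo counts for both strains are resampled from the same source gene's
# coverage, each matched to its own strain's (L, pi) and scaled by that
# library's size. Draw order and stream keys are canonical in the unordered
# gene pair so that swapping strain labels negates the null exactly.
null_log2_pair <- function(oc, pr, assay, rep, source_gene, n, seed) {
  src_counts <- oc_counts(oc, source_gene, assay, rep)
  cls <- split_by_base(src_counts, oc$seqs[[source_gene]])
  canon <- paste(sort(c(pr$gene_b, pr$gene_y)), collapse = "|")
  side <- function(target_gene, L, pi) {
    quota <- stratified_quotas(L, pi, lengths(cls))
    with_seed(
      substream_seed(seed, "divnull", canon, assay, rep, source_gene, target_gene),
      resample_totals_cpp(cls, quota, as.integer(n))
    )
  }
  ord <- order(c(pr$gene_b, pr$gene_y))
  sides <- list(
    b = function() side(pr$gene_b, pr$L_b, pr$pi_b[[1]]),
    y = function() side(pr$gene_y, pr$L_y, pr$pi_y[[1]])
  )[ord]
  drawn <- lapply(sides, function(f) f())
  names(drawn) <- c("b", "y")[ord]
  lib_b <- oc_lib(oc, "B", assay, rep)
  lib_y <- oc_lib(oc, "Y", assay, rep)
  log2(((drawn$y + 0.5) / lib_y) / ((drawn$b + 0.5) / lib_b))
}

#' Null distribution of the between-strain log2 ratio
#'
#' @param oc An [ortholog_counts()] object.
#' @param gene_b,gene_y The ortholog pair.
#' @param assay `"mRNA"` or `"RFP"`.
#' @param replicate Replicate id.
#' @param source `"B"` or `"Y"`: which ortholog's coverage seeds the null.
#' @param n Number of resamples (>= 100).
#' @param seed Seed.
#' @return Numeric vector of `n` null log2(Y/B) values (library-size scaled).
#' @export
null_log2_distribution <- function(oc, gene_b, gene_y, assay, replicate,
                                   source = c("B", "Y"), n = 10000L, seed = 1L) {
  source <- match.arg(source)
  if (n < 100) abort("n must be >= 100")
  pr <- oc$pairs %>% filter(.data$gene_b == !!gene_b, .data$gene_y == !!gene_y)
  if (nrow(pr) != 1) abort("pair not found in ortholog table")
  src_gene <- if (source == "B") gene_b else gene_y
  null_log2_pair(oc, pr[1, ], assay, replicate, src_gene, n, seed)
}

obs_log2 <- function(oc, pr, assay, rep, direction = c("YB", "BY")) {
  direction <- match.arg(direction)
  t_b <- sum(oc_counts(oc, pr$gene_b, assay, rep))
  t_y <- sum(oc_counts(oc, pr$gene_y, assay, rep))
  r_b <- (t_b + 0.5) / oc_lib(oc, "B", assay, rep)
  r_y <- (t_y + 0.5) / oc_lib(oc, "Y", assay, rep)
  if (direction == "YB") log2(r_y / r_b) else log2(r_b / r_y)
}

pair_totals <- function(oc, gene, assay) {
  rows <- oc$coverage %>% filter(.data$gene_id == gene, .data$assay == !!assay)
  sum(map_dbl(rows$counts, sum))
}

#' Per-ortholog divergence test
#'
#' For each ortholog pair and each (source strain x replicate) combination the
#' observed library-size-normalised log2(Y/B) is compared against the
#' composition-matched resampling null, giving four two-sided empirical P
#' values per pair; the maximum is retained and BH-adjusted across genes.
#' Genes with fewer than `min_cds_reads` pooled CDS reads in either strain are
#' reported with a skip reason instead of a test.
#'
#' @param oc An [ortholog_counts()] object.
#' @param assay `"mRNA"` or `"RFP"`.
#' @param n_resamples Resamples per null distribution (10,000).
#' @param fdr FDR threshold for the significance call (0.05).
#' @param min_cds_reads Minimum pooled CDS reads per strain (50).
#' @param replicates Replicate ids used (default 1:2).
#' @param seed Seed; all resampling substreams derive from it.
#' @return An `rp_divergence` object; `tidy()` it for the per-gene table.
#' @export
divergence_test <- function(oc, assay = "mRNA", n_resamples = 10000L,
                            fdr = 0.05, min_cds_reads = 50L,
                            replicates = 1:2, seed = 1L) {
  pairs <- oc$pairs
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    tot_b <- pair_totals(oc, pr$gene_b, assay)
    tot_y <- pair_totals(oc, pr$gene_y, assay)
    if (tot_b < min_cds_reads || tot_y < min_cds_reads) {
      rows[[i]] <- tibble(
        gene_b = pr$gene_b, gene_y = pr$gene_y, assay = assay,
        log2_obs = list(rep(NA_real_, length(replicates))),
        log2_mean = NA_real_, p_comp = list(NULL), p_max = NA_real_,
        skip_reason = sprintf("below %d CDS reads", min_cds_reads)
      )
      next
    }
    obs <- vapply(replicates, function(r) obs_log2(oc, pr, assay, r, "YB"), numeric(1))
    p <- c()
    for (r in seq_along(replicates)) {
      for (src in c("B", "Y")) {
        src_gene <- if (src == "B") pr$gene_b else pr$gene_y
        null <- null_log2_pair(oc, pr, assay, replicates[r], src_gene, n_resamples, seed)
        p[paste0(src, replicates[r])] <- empirical_p_two_sided(obs[r], null)
      }
    }
    rows[[i]] <- tibble(
      gene_b = pr$gene_b, gene_y = pr$gene_y, assay = assay,
      log2_obs = list(obs), log2_mean = mean(obs),
      p_comp = list(p), p_max = max(p), skip_reason = NA_character_
    )
  }
  res <- bind_rows(rows)
  res$q <- NA_real_
  ok <- !is.na(res$p_max)
  res$q[ok] <- bh_adjust(res$p_max[ok])
  res$significant <- !is.na(res$q) & res$q <= fdr
  structure(
    list(
      results = res, assay = assay, n_resamples = n_resamples, fdr = fdr,
      min_cds_reads = min_cds_reads, seed = seed
    ),
    class = "rp_divergence"
  )
}

# one reciprocal TE null: the null of log2[assay_null (B/Y)] where each
# strain's pseudo counts come from its *own* coverage in that assay
te_null <- function(oc, pr, assay_null, rep, n, seed) {
  canon <- paste(sort(c(pr$gene_b, pr$gene_y)), collapse = "|")
  side <- function(gene, L, pi) {
    cls <- split_by_base(oc_counts(oc, gene, assay_null, rep), oc$seqs[[gene]])
    quota <- stratified_quotas(L, pi, lengths(cls))
    with_seed(
      substream_seed(seed, "tenull", canon, assay_null, rep, gene),
      resample_totals_cpp(cls, quota, as.integer(n))
    )
  }
  ord <- order(c(pr$gene_b, pr$gene_y))
  sides <- list(
    b = function() side(pr$gene_b, pr$L_b, pr$pi_b[[1]]),
    y = function() side(pr$gene_y, pr$L_y, pr$pi_y[[1]])
  )[ord]
  drawn <- lapply(sides, function(f) f())
  names(drawn) <- c("b", "y")[ord]
  lib_b <- oc_lib(oc, "B", assay_null, rep)
  lib_y <- oc_lib(oc, "Y", assay_null, rep)
  log2(((drawn$b + 0.5) / lib_b) / ((drawn$y + 0.5) / lib_y))
}

#' Translation-efficiency divergence test
#'
#' Tests whether log2[RFP(B/Y)] differs from log2[mRNA(B/Y)] per ortholog
#' pair. Reciprocal comparisons: the observed mRNA ratio is compared to the
#' resampled null of the RFP ratio (each strain resampled from its own RFP
#' coverage, matched to its own L and pi), and vice versa, in every replicate
#' — four component P values. The max P is retained only when the TE shift
#' direction agrees across replicates; otherwise the gene is non-significant.
#'
#' @inheritParams divergence_test
#' @return An `rp_te` object; `tidy()` it for the per-gene table.
#' @export
te_test <- function(oc, n_resamples = 10000L, fdr = 0.05, min_cds_reads = 50L,
                    replicates = 1:2, seed = 1L) {
  pairs <- oc$pairs
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    tots <- c(
      pair_totals(oc, pr$gene_b, "mRNA"), pair_totals(oc, pr$gene_y, "mRNA"),
      pair_totals(oc, pr$gene_b, "RFP"), pair_totals(oc, pr$gene_y, "RFP")
    )
    if (any(tots < min_cds_reads)) {
      rows[[i]] <- tibble(
        gene_b = pr$gene_b, gene_y = pr$gene_y,
        log2_rfp = list(rep(NA_real_, length(replicates))),
        log2_mrna = list(rep(NA_real_, length(replicates))),
        te_log2 = NA_real_, agree = NA, p_comp = list(NULL), p_max = NA_real_,
        skip_reason = sprintf("below %d CDS reads", min_cds_reads)
      )
      next
    }
    obs_rfp <- vapply(replicates, function(r) obs_log2(oc, pr, "RFP", r, "BY"), numeric(1))
    obs_mrna <- vapply(replicates, function(r) obs_log2(oc, pr, "mRNA", r, "BY"), numeric(1))
    te_r <- obs_rfp - obs_mrna
    agree <- length(unique(sign(te_r))) == 1 && all(sign(te_r) != 0)
    p <- c()
    for (r in seq_along(replicates)) {
      null_rfp <- te_null(oc, pr, "RFP", replicates[r], n_resamples, seed)
      null_mrna <- te_null(oc, pr, "mRNA", replicates[r], n_resamples, seed)
      p[paste0("mRNAvsRFPnull", replicates[r])] <-
        empirical_p_two_sided(obs_mrna[r], null_rfp)
      p[paste0("RFPvsmRNAnull", replicates[r])] <-
        empirical_p_two_sided(obs_rfp[r], null_mrna)
    }
    p_max <- if (agree) max(p) else 1
    rows[[i]] <- tibble(
      gene_b = pr$gene_b, gene_y = pr$gene_y,
      log2_rfp = list(obs_rfp), log2_mrna = list(obs_mrna),
      te_log2 = mean(te_r), agree = agree,
      p_comp = list(p), p_max = p_max, skip_reason = NA_character_
    )
  }
  res <- bind_rows(rows)
  res$q <- NA_real_
  ok <- !is.na(res$p_max)
  res$q[ok] <- bh_adjust(res$p_max[ok])
  res$significant <- !is.na(res$q) & res$q <= fdr
  structure(
    list(
      results = res, n_resamples = n_resamples, fdr = fdr,
      min_cds_reads = min_cds_reads, seed = seed
    ),
    class = "rp_te"
  )
}

#' Regulatory category from mRNA and TE significance
#'
#' @param mrna_significant,te_significant Logical vectors (FDR-thresholded
#'   significance calls).
#' @return Character vector: `"mRNA-only"`, `"TE-only"`, `"both"`, `"neither"`.
#' @export
classify_regulation <- function(mrna_significant, te_significant) {
  stopifnot(length(mrna_significant) == length(te_significant))
  case_when(
    mrna_significant & te_significant ~ "both",
    mrna_significant & !te_significant ~ "mRNA-only",
    !mrna_significant & te_significant ~ "TE-only",
    TRUE ~ "neither"
  )
}

#' Join mRNA divergence and TE results into regulatory categories
#'
#' @param div An `rp_divergence` object for the mRNA assay.
#' @param te An `rp_te` object.
#' @return Tibble (`gene_b`, `gene_y`, `mrna_significant`, `te_significant`,
#'   `category`).
#' @export
regulation_categories <- function(div, te) {
  stopifnot(inherits(div, "rp_divergence"), inherits(te, "rp_te"))
  dm <- div$results %>%
    select("gene_b", "gene_y", mrna_significant = "significant")
  tm <- te$results %>%
    select("gene_b", "gene_y", te_significant = "significant")
  inner_join(dm, tm, by = c("gene_b", "gene_y")) %>%
    mutate(category = classify_regulation(.data$mrna_significant, .data$te_significant))
}
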