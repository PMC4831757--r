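# Synthetic two-strain generator. Everything downstream is validated against
# the ground truth planted here: gene-level log2 fold changes per assay,
# codon dwell multipliers, and ORF-variant coordinates.

#' Simulation configuration
#'
#' Holds every knob of the two-strain generator. Defaults describe a small but
#' realistic budding-yeast-like study: intronless genes of 300-600 nt at ~0.40
#' GC, ~0.6% coding sequence divergence between strains, negative-binomial
#' counts (variance = mu + mu^2/dispersion) with mild log-normal positional
#' bias, two replicates.
#'
#' @param n_genes Number of ortholog gene pairs.
#' @param gene_length_range Min/max CDS length in nt; multiples of 3, >= 51.
#' @param gc_content Length-2 vector, GC fraction per strain (B, Y).
#' @param mean_depth Expected CDS-assigned reads per gene per library.
#' @param dispersion NB size parameter; `Inf` gives Poisson counts.
#' @param pos_sigma SD (log scale) of per-position log-normal rate multipliers.
#' @param substitution_rate Per-base substitution probability between ortholog
#'   CDSs (start/stop codons preserved; no premature stops introduced).
#' @param fold_change_spec Tibble (`gene`, `assay`, `log2fc`): planted
#'   log2(Y/B) changes; `gene` is the pair index, `assay` "mRNA" or "RFP".
#' @param dwell_spec Tibble (`codon`, `position`, `multiplier`): codon dwell
#'   multipliers at window positions 1..9 for footprint placement.
#' @param orf_variant_spec Tibble (`gene`, `kind`, `length`): planted ORF
#'   variants; `kind` is "extension-5p" or "readthrough-3p", `length` in codons.
#' @param n_replicates Replicates per strain x assay (>= 2).
#' @param frac_minus Fraction of genes placed on the minus strand.
#' @param intergenic_range Min/max intergenic spacer length in nt.
#' @param seed Root seed; all randomness flows from it via named substreams.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 50,
                       gene_length_range = c(300L, 600L),
                       gc_content = c(0.40, 0.40),
                       mean_depth = 500,
                       dispersion = 10,
                       pos_sigma = 0.3,
                       substitution_rate = 0.006,
                       fold_change_spec = NULL,
                       dwell_spec = NULL,
                       orf_variant_spec = NULL,
                       n_replicates = 2L,
                       frac_minus = 0.3,
                       intergenic_range = c(200L, 400L),
                       seed = 1L) {
  fc <- fold_change_spec %||%
    tibble(gene = integer(), assay = character(), log2fc = numeric())
  dw <- dwell_spec %||%
    tibble(codon = character(), position = integer(), multiplier = numeric())
  ov <- orf_variant_spec %||%
    tibble(gene = integer(), kind = character(), length = integer())
  cfg <- list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    gc_content = gc_content,
    mean_depth = mean_depth,
    dispersion = dispersion,
    pos_sigma = pos_sigma,
    substitution_rate = substitution_rate,
    fold_change_spec = as_tibble(fc),
    dwell_spec = as_tibble(dw),
    orf_variant_spec = as_tibble(ov),
    n_replicates = as.integer(n_replicates),
    frac_minus = frac_minus,
    intergenic_range = as.integer(intergenic_range),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) abort("n_genes must be positive")
  r <- cfg$gene_length_range
  if (length(r) != 2 || r[1] > r[2]) abort("bad gene_length_range")
  if (any(r %% 3 != 0) || r[1] < 51) {
    abort("gene lengths must be multiples of 3 and >= 51 nt (17 codons)")
  }
  if (any(cfg$gc_content < 0 | cfg$gc_content > 1)) abort("gc_content must be in [0,1]")
  if (cfg$frac_minus < 0 || cfg$frac_minus > 1) abort("frac_minus must be in [0,1]")
  if (cfg$mean_depth <= 0) abort("mean_depth must be positive")
  if (cfg$dispersion <= 0) abort("dispersion must be positive")
  if (cfg$n_replicates < 2) abort("n_replicates must be >= 2")
  dw <- cfg$dwell_spec
  if (nrow(dw) > 0) {
    if (!all(is_sense_codon(dw$codon))) abort("dwell_spec codon is not a sense codon")
    if (!all(dw$position %in% 1:9)) abort("dwell_spec positions must be in 1..9")
    if (any(dw$multiplier <= 0)) abort("dwell multipliers must be > 0")
  }
  fc <- cfg$fold_change_spec
  if (nrow(fc) > 0) {
    if (!all(fc$gene %in% seq_len(cfg$n_genes))) {
      abort("fold_change_spec references a gene outside 1..n_genes")
    }
    if (!all(fc$assay %in% c("mRNA", "RFP"))) abort("assay must be mRNA or RFP")
  }
  ov <- cfg$orf_variant_spec
  if (nrow(ov) > 0) {
    if (!all(ov$gene %in% seq_len(cfg$n_genes))) {
      abort("orf_variant_spec references a gene outside 1..n_genes")
    }
    if (!all(ov$kind %in% c("extension-5p", "readthrough-3p"))) {
      abort("variant kind must be extension-5p or readthrough-3p")
    }
    if (any(ov$length < 1 | ov$length > 60)) {
      abort("variant length must be 1..60 codons (180 bp search space)")
    }
    if (anyDuplicated(ov[, c("gene", "kind")])) {
      abort("duplicate variant spec for a gene")
    }
  }
  invisible(TRUE)
}

# mutate a CDS string at `rate` per base, preserving the start and stop codon
# and never creating an in-frame stop
mutate_cds <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  eligible <- setdiff(seq_len(n), c(1:3, (n - 2):n))
  hit <- eligible[runif(length(eligible)) < rate]
  for (i in hit) {
    alt <- sample(setdiff(DNA_BASES, bases[i]), 1)
    old <- bases[i]
    bases[i] <- alt
    cod0 <- (i - 1) %/% 3
    codon <- paste(bases[(cod0 * 3 + 1):(cod0 * 3 + 3)], collapse = "")
    if (codon %in% STOP_CODONS) bases[i] <- old
  }
  paste(bases, collapse = "")
}

#' Simulate a two-strain ortholog genome pair
#'
#' Builds one chromosome per strain carrying `n_genes` intronless ortholog
#' CDSs (both strands) separated by random intergenic spacers, applies
#' between-strain substitutions, and plants the configured ORF variants:
#' an upstream in-frame ATG preceded by a blocking stop ("extension-5p") or a
#' run of sense codons ending at a shifted stop ("readthrough-3p"), planted
#' identically in both strains.
#'
#' @param config A [sim_config()].
#' @return List with `genome_b`, `genome_y` (FASTA-ready tibbles), `models`
#'   (gene models for both strains), `orthologs` (`gene_b`, `gene_y`), `cds`
#'   (CDS sequences, transcript orientation) and `truth` (planted fold
#'   changes, dwell multipliers and variant coordinates).
#' @export
simulate_strain_pair <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_seed(substream_seed(cfg$seed, "genome"), {
    n <- cfg$n_genes
    len_choices <- seq(cfg$gene_length_range[1] / 3, cfg$gene_length_range[2] / 3)
    lens <- 3L * len_choices[sample.int(length(len_choices), n, replace = TRUE)]
    strands <- ifelse(runif(n) < cfg$frac_minus, "-", "+")

    ov <- cfg$orf_variant_spec
    ext_len <- setNames(rep(NA_integer_, n), seq_len(n))
    rt_len <- setNames(rep(NA_integer_, n), seq_len(n))
    if (nrow(ov) > 0) {
      for (k in seq_len(nrow(ov))) {
        if (ov$kind[k] == "extension-5p") ext_len[ov$gene[k]] <- ov$length[k]
        if (ov$kind[k] == "readthrough-3p") rt_len[ov$gene[k]] <- ov$length[k]
      }
    }

    cds_b <- character(n)
    cds_y <- character(n)
    up_ctx <- character(n) # transcript-orientation context immediately 5' of ATG
    dn_ctx <- character(n) # immediately 3' of the stop codon
    for (i in seq_len(n)) {
      ncod <- lens[i] / 3 - 2
      body <- paste(random_sense_codons(ncod, cfg$gc_content[1]), collapse = "")
      cds_b[i] <- paste0("ATG", body, sample(STOP_CODONS, 1))
      cds_y[i] <- mutate_cds(cds_b[i], cfg$substitution_rate)
      up_ctx[i] <- ""
      dn_ctx[i] <- ""
      if (!is.na(ext_len[i])) {
        k <- ext_len[i]
        ext_codons <- if (k > 1) {
          paste(random_sense_codons(k - 1, cfg$gc_content[1]), collapse = "")
        } else {
          ""
        }
        # blocking stop, then the upstream in-frame ATG, then k-1 sense codons
        up_ctx[i] <- paste0(sample(STOP_CODONS, 1), "ATG", ext_codons)
      }
      if (!is.na(rt_len[i])) {
        k <- rt_len[i]
        # k sense codons then the shifted stop: a k-codon read-through
        # (region runs from the old stop, exclusive, to the new stop, inclusive)
        dn_ctx[i] <- paste0(
          paste(random_sense_codons(k, cfg$gc_content[1]), collapse = ""),
          sample(STOP_CODONS, 1)
        )
      }
    }

    build_strain <- function(cds, tag, gc) {
      chrom <- paste0("chr", tag)
      pieces <- character(0)
      pos <- 0L
      rows <- list()
      var_rows <- list()
      for (i in seq_len(n)) {
        gap_choices <- seq(cfg$intergenic_range[1], cfg$intergenic_range[2])
        gap <- gap_choices[sample.int(length(gap_choices), 1)]
        spacer <- random_dna(gap, gc)
        locus <- paste0(up_ctx[i], cds[i], dn_ctx[i])
        cds_off <- nchar(up_ctx[i]) # offset of CDS within locus (transcript sense)
        pieces <- c(pieces, spacer)
        pos <- pos + gap
        gid <- sprintf("g%03d_%s", i, tag)
        if (strands[i] == "+") {
          gstart <- pos + cds_off
          gend <- gstart + nchar(cds[i])
          pieces <- c(pieces, locus)
          pos <- pos + nchar(locus)
        } else {
          # locus inserted reverse-complemented; CDS genomic interval flips
          gend <- pos + nchar(locus) - cds_off
          gstart <- gend - nchar(cds[i])
          pieces <- c(pieces, revcomp(locus))
          pos <- pos + nchar(locus)
        }
        rows[[i]] <- tibble(
          gene_id = gid, seqid = chrom, strand = strands[i],
          start = gstart, end = gend, source = "sim"
        )
        if (!is.na(ext_len[i])) {
          var_rows[[length(var_rows) + 1]] <- tibble(
            gene_id = gid, kind = "extension-5p", length = unname(ext_len[i])
          )
        }
        if (!is.na(rt_len[i])) {
          var_rows[[length(var_rows) + 1]] <- tibble(
            gene_id = gid, kind = "readthrough-3p", length = unname(rt_len[i])
          )
        }
      }
      gap_choices <- seq(cfg$intergenic_range[1], cfg$intergenic_range[2])
      pieces <- c(pieces, random_dna(gap_choices[sample.int(length(gap_choices), 1)], gc))
      list(
        genome = tibble(name = chrom, seq = paste(pieces, collapse = "")),
        models = bind_rows(rows),
        variants = if (length(var_rows)) bind_rows(var_rows) else
          tibble(gene_id = character(), kind = character(), length = integer())
      )
    }

    b <- build_strain(cds_b, "B", cfg$gc_content[1])
    y <- build_strain(cds_y, "Y", cfg$gc_content[2])

    orthologs <- tibble(
      gene_b = sprintf("g%03d_B", seq_len(n)),
      gene_y = sprintf("g%03d_Y", seq_len(n))
    )
    truth_fc <- cfg$fold_change_spec %>%
      mutate(
        gene_b = sprintf("g%03d_B", .data$gene),
        gene_y = sprintf("g%03d_Y", .data$gene)
      )
    list(
      genome_b = b$genome,
      genome_y = y$genome,
      models = bind_rows(b$models, y$models),
      orthologs = orthologs,
      cds = tibble(
        gene_id = c(orthologs$gene_b, orthologs$gene_y),
        seq = c(cds_b, cds_y)
      ),
      truth = list(
        fold_changes = truth_fc,
        dwell = cfg$dwell_spec,
        variants = bind_rows(b$variants, y$variants)
      )
    )
  })
}

#' Simulate a per-base 5'-end count vector for one gene
#'
#' Negative-binomial counts with per-base mean `mean_depth / length` (times the
#' optional positional multipliers); `dispersion = Inf` gives the Poisson
#' limit.
#'
#' @param length Gene CDS length in nt.
#' @param mean_depth Expected total reads on the gene.
#' @param dispersion NB size parameter (variance = mu + mu^2/dispersion).
#' @param seed Optional seed.
#' @param pos_mult Optional positional rate multipliers (length `length`).
#' @return Integer vector of length `length`.
#' @export
simulate_base_coverage <- function(length, mean_depth, dispersion = 10,
                                   seed = NULL, pos_mult = NULL) {
  if (length <= 0) abort("length must be positive")
  if (mean_depth <= 0) abort("mean_depth must be positive")
  mu <- rep(mean_depth / length, length)
  if (!is.null(pos_mult)) {
    stopifnot(length(pos_mult) == length, all(pos_mult > 0))
    mu <- mu * pos_mult
  }
  draw <- function() {
    if (is.infinite(dispersion)) rpois(length, mu) else {
      rnbinom(length, size = dispersion, mu = mu)
    }
  }
  if (is.null(seed)) as.integer(draw()) else as.integer(with_seed(seed, draw()))
}

#' Simulate the full coverage set for a strain pair
#'
#' Draws per-base 5'-end counts for every gene x strain x assay x replicate.
#' Positional multipliers (log-normal, `pos_sigma`) are drawn once per
#' ortholog pair and assay, shared between strains and replicates — they model
#' sequence/protocol bias, which the resampling null is designed to absorb.
#' Planted fold changes multiply the Y strain's rate by `2^log2fc`.
#'
#' @param sim Output of [simulate_strain_pair()].
#' @param config The same [sim_config()].
#' @param assays Which assays to simulate.
#' @return Tibble (`gene_id`, `strain`, `assay`, `replicate`, `counts`), with
#'   `counts` a list-column of integer vectors.
#' @export
simulate_coverage <- function(sim, config, assays = c("mRNA", "RFP")) {
  cfg <- config
  pairs <- sim$orthologs
  lens <- setNames(nchar(sim$cds$seq), sim$cds$gene_id)
  fc <- sim$truth$fold_changes
  out <- vector("list", nrow(pairs) * length(assays) * 2 * cfg$n_replicates)
  k <- 0
  for (i in seq_len(nrow(pairs))) {
    for (assay in assays) {
      L <- unname(lens[pairs$gene_b[i]]) # ortholog lengths are equal by design
      pm <- with_seed(
        substream_seed(cfg$seed, "posmult", i, assay),
        rlnorm(L, meanlog = -cfg$pos_sigma^2 / 2, sdlog = cfg$pos_sigma)
      )
      lfc <- fc$log2fc[fc$gene == i & fc$assay == assay]
      shift <- if (length(lfc)) 2^lfc[1] else 1
      for (strain in c("B", "Y")) {
        gid <- if (strain == "B") pairs$gene_b[i] else pairs$gene_y[i]
        depth <- cfg$mean_depth * if (strain == "Y") shift else 1
        for (rep_i in seq_len(cfg$n_replicates)) {
          k <- k + 1
          out[[k]] <- tibble(
            gene_id = gid, strain = strain, assay = assay,
            replicate = rep_i,
            counts = list(simulate_base_coverage(
              L, depth, cfg$dispersion,
              seed = substream_seed(cfg$seed, "coverage", i, strain, assay, rep_i),
              pos_mult = pm
            ))
          )
        }
      }
    }
  }
  bind_rows(out)
}

#' Simulate ribosome footprint placements
#'
#' Places `n_reads` footprints on the given CDSs. A footprint's 5' end always
#' sits on a codon boundary; the probability of a start site is proportional
#' to the product of the dwell multipliers of the codons it covers at their
#' specified window positions (1..9 over the 5'-most 9 codons), uniform when
#' `dwell_spec` is empty.
#'
#' @param cds_seqs Tibble (`gene_id`, `seq`); every CDS >= `read_length` nt.
#' @param dwell_spec Tibble (`codon`, `position`, `multiplier`) or NULL.
#' @param n_reads Total number of footprints.
#' @param read_length Footprint length in nt; multiple of 3, >= 27.
#' @param seed Optional seed.
#' @return Tibble (`read_id`, `gene_id`, `codon_start`, `nt_start`, `length`),
#'   `codon_start` 0-based.
#' @export
simulate_footprints <- function(cds_seqs, dwell_spec = NULL, n_reads,
                                read_length = 27L, seed = NULL) {
  if (read_length %% 3 != 0 || read_length < 27) {
    abort("read_length must be a multiple of 3 and >= 27")
  }
  if (any(nchar(cds_seqs$seq) < read_length)) {
    abort("every CDS must be at least read_length nt")
  }
  dw <- dwell_spec %||%
    tibble(codon = character(), position = integer(), multiplier = numeric())
  if (nrow(dw) > 0 && !all(is_sense_codon(dw$codon))) {
    abort("dwell_spec contains a non-sense codon")
  }
  read_codons <- read_length / 3
  span <- min(9L, read_codons) # dwell positions defined on the 5'-most 9 codons
  sites <- purrr::map2_dfr(cds_seqs$gene_id, cds_seqs$seq, function(gid, seq) {
    codons <- codon_split(seq)
    nstart <- length(codons) - read_codons + 1
    w <- rep(1, nstart)
    if (nrow(dw) > 0) {
      for (r in seq_len(nrow(dw))) {
        if (dw$position[r] > span) next
        hits <- which(codons == dw$codon[r]) - (dw$position[r] - 1)
        hits <- hits[hits >= 1 & hits <= nstart]
        w[hits] <- w[hits] * dw$multiplier[r]
      }
    }
    tibble(gene_id = gid, codon_start = seq_len(nstart) - 1L, w = w)
  })
  draw <- function() {
    if (n_reads == 0) {
      return(tibble(
        read_id = character(), gene_id = character(),
        codon_start = integer(), nt_start = integer(), length = integer()
      ))
    }
    idx <- sample.int(nrow(sites), n_reads, replace = TRUE, prob = sites$w)
    tibble(
      read_id = sprintf("fp%07d", seq_len(n_reads)),
      gene_id = sites$gene_id[idx],
      codon_start = sites$codon_start[idx],
      nt_start = 3L * sites$codon_start[idx],
      length = as.integer(read_length)
    )
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Emit raw footprint read sequences
#'
#' Turns placements from [simulate_footprints()] into read sequences, appending
#' 0-3 spurious 3' adenines (as ribosome-profiling library prep does) so the
#' iterative 3'-trimming aligner has something to trim.
#'
#' @param footprints Placement tibble from [simulate_footprints()].
#' @param cds_seqs Tibble (`gene_id`, `seq`).
#' @param max_extra_a Maximum number of spurious adenines (0-3 uniform).
#' @param seed Optional seed.
#' @return Tibble (`read_id`, `gene_id`, `seq`, `extra_a`).
#' @export
footprint_reads <- function(footprints, cds_seqs, max_extra_a = 3L, seed = NULL) {
  seqs <- setNames(cds_seqs$seq, cds_seqs$gene_id)
  draw <- function() {
    extra <- sample(0:max_extra_a, nrow(footprints), replace = TRUE)
    tibble(
      read_id = footprints$read_id,
      gene_id = footprints$gene_id,
      seq = paste0(
        substring(
          seqs[footprints$gene_id], footprints$nt_start + 1,
          footprints$nt_start + footprints$length
        ),
        strrep("A", extra)
      ),
      extra_a = extra
    )
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
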