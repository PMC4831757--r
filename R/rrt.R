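# Ribosome residence time (RRT). For each sense codon, every 17-codon window
# in which that codon occurs uniquely at the middle gives a 9-vector of
# footprint counts: a >= 27 nt in-frame footprint covers 9 codons, so the
# central codon can sit at 9 positions (17 - 9 + 1) of the footprint.
# RF normalises each window's counts to frequencies; RRT compares the
# across-window mean RF to the uniform expectation 1/9.

RRT_WINDOW_CODONS <- 17L
RRT_READ_CODONS <- 9L

#' Number of eligible codon positions per footprint window
#'
#' A minimum-length in-frame footprint (27 nt = 9 codons) sliding inside a
#' 17-codon window can place the central codon at `17 - 9 + 1` positions.
#'
#' @param window_codons Window width in codons (17).
#' @param read_codons Codons covered by a footprint (9).
#' @return Integer number of eligible positions.
#' @export
rrt_window_positions <- function(window_codons = RRT_WINDOW_CODONS,
                                 read_codons = RRT_READ_CODONS) {
  as.integer(window_codons - read_codons + 1L)
}

#' Expected relative frequency under the uniform null
#'
#' With no codon preference, footprints fall uniformly over the eligible
#' positions, so the expected RF at any one position is `1 / n_positions`.
#'
#' @param n_positions Number of eligible positions per window.
#' @param percent Return a percentage instead of a fraction.
#' @return Expected RF (fraction, or percentage if `percent = TRUE`).
#' @export
uniform_null_rf <- function(n_positions = rrt_window_positions(),
                            percent = FALSE) {
  rf <- 1 / n_positions
  if (percent) 100 * rf else rf
}

#' Retain in-frame footprints in codon coordinates
#'
#' Keeps feature-assigned alignments of length >= `min_len` whose 5'-most
#' nucleotide coincides with the first base of a codon, and emits the codon
#' index of that 5' end.
#'
#' @param assigned Output of [assign_to_feature()] (needs `cds_pos`, `length`).
#' @param min_len Minimum aligned length in nt (27).
#' @return Tibble (`gene_id`, `codon_start`), `codon_start` 0-based.
#' @export
in_frame_footprints <- function(assigned, min_len = 27L) {
  assigned %>%
    filter(
      .data$feature == "CDS", !is.na(.data$cds_pos),
      .data$length >= min_len, .data$cds_pos %% 3 == 0
    ) %>%
    transmute(.data$gene_id, codon_start = as.integer(.data$cds_pos %/% 3))
}

#' Enumerate eligible codon windows
#'
#' All 17-codon windows fully inside a CDS whose middle codon equals `codon`
#' and which contain no other occurrence of it.
#'
#' @param cds_seqs Tibble (`gene_id`, `seq`).
#' @param codon The query codon.
#' @return Tibble (`gene_id`, `center`): 0-based codon index of the middle.
#' @export
build_windows <- function(cds_seqs, codon) {
  half <- (RRT_WINDOW_CODONS - 1L) / 2L
  purrr::map2_dfr(cds_seqs$gene_id, cds_seqs$seq, function(gid, seq) {
    codons <- codon_split(seq)
    n <- length(codons)
    occ <- which(codons == codon) # 1-based
    if (length(occ) == 0 || n < RRT_WINDOW_CODONS) {
      return(tibble(gene_id = character(), center = integer()))
    }
    cand <- occ[occ - 1 >= half & occ - 1 <= n - 1 - half]
    keep <- vapply(cand, function(i) {
      sum(occ >= i - half & occ <= i + half) == 1
    }, logical(1))
    tibble(gene_id = gid, center = as.integer(cand[keep] - 1L))
  })
}

# per-codon window count matrix: rows = windows, cols = positions 1..9.
# position p means the central codon is the p-th codon of the footprint,
# i.e. the footprint starts at codon center - (p - 1).
window_count_matrix <- function(cds_seqs, footprints, codon) {
  win <- build_windows(cds_seqs, codon)
  if (nrow(win) == 0) {
    return(matrix(0, nrow = 0, ncol = RRT_READ_CODONS))
  }
  lens <- setNames(nchar(cds_seqs$seq) %/% 3L, cds_seqs$gene_id)
  starts <- footprints %>%
    group_by(.data$gene_id) %>%
    summarise(tab = list(tabulate(.data$codon_start + 1L,
      nbins = lens[first(.data$gene_id)]
    )), .groups = "drop")
  tabs <- setNames(starts$tab, starts$gene_id)
  counts <- matrix(0, nrow = nrow(win), ncol = RRT_READ_CODONS)
  for (w in seq_len(nrow(win))) {
    tab <- tabs[[win$gene_id[w]]]
    if (is.null(tab)) next
    idx <- win$center[w] - (seq_len(RRT_READ_CODONS) - 1L) + 1L # 1-based starts
    counts[w, ] <- tab[idx]
  }
  counts
}

#' Permutation null of the across-window mean RF
#'
#' Each permutation independently shuffles the 9 position labels within every
#' window and records the across-window mean RF vector.
#'
#' @param counts Window x position count matrix (zero rows are dropped).
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return `n_perm` x 9 matrix of null mean RFs.
#' @export
permute_window_rf <- function(counts, n_perm = 10000L, seed = NULL) {
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(counts) == 0) abort("no windows with footprints")
  rf <- counts / rowSums(counts)
  draw <- function() permute_mean_rf_cpp(rf, as.integer(n_perm))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

site_flag <- function(position) {
  case_when(position == 6 ~ "A", position == 5 ~ "P", position == 4 ~ "E",
    .default = NA_character_
  )
}

#' Ribosome residence time table
#'
#' For every queried codon: the across-window mean RF per position, RRT
#' (mean RF divided by the uniform expectation 1/9), the number of windows
#' with footprints, and a two-sided permutation P value per position.
#' Codons with no usable window get NA rows (RRT undefined, not 0).
#'
#' @param cds_seqs Tibble (`gene_id`, `seq`), CDSs in transcript orientation.
#' @param footprints Tibble (`gene_id`, `codon_start`) of in-frame footprint
#'   placements ([in_frame_footprints()] or [simulate_footprints()]).
#' @param codons Codons to evaluate (default all 61 sense codons).
#' @param n_perm Permutations per codon (10,000).
#' @param seed Seed (per-codon substreams derive from it).
#' @return An `rp_rrt` object; `tidy()` gives the codon x position table.
#' @export
rrt_table <- function(cds_seqs, footprints, codons = sense_codons(),
                      n_perm = 10000L, seed = 1L) {
  rows <- purrr::map_dfr(codons, function(cod) {
    counts <- window_count_matrix(cds_seqs, footprints, cod)
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    if (nrow(counts) == 0) {
      return(tibble(
        codon = cod, position = 1:RRT_READ_CODONS, n_windows = 0L,
        mean_rf = NA_real_, rrt = NA_real_, p = NA_real_
      ))
    }
    rf <- counts / rowSums(counts)
    mean_rf <- colMeans(rf)
    null <- permute_window_rf(counts, n_perm,
      seed = substream_seed(seed, "rrtperm", cod)
    )
    p <- vapply(
      seq_len(RRT_READ_CODONS),
      function(j) empirical_p_two_sided(mean_rf[j], null[, j]), numeric(1)
    )
    tibble(
      codon = cod, position = 1:RRT_READ_CODONS, n_windows = nrow(counts),
      mean_rf = mean_rf, rrt = mean_rf * RRT_READ_CODONS, p = p
    )
  })
  rows <- rows %>% mutate(site = site_flag(.data$position))
  structure(list(results = rows, n_perm = n_perm, seed = seed),
    class = "rp_rrt"
  )
}

#' Significant ribosome stalling calls
#'
#' Flags codon-position pairs where the dwell effect is strong in either
#' direction (`max(RRT, 1/RRT) >= rrt_thresh`), the permutation P passes, and
#' enough windows support the codon.
#'
#' @param rrt An `rp_rrt` object or its tidied tibble.
#' @param rrt_thresh Effect threshold on the RRT ratio (1.2).
#' @param p_thresh Permutation P threshold (1e-4).
#' @param min_windows Minimum windows per codon (300).
#' @return Tibble of calls with `direction` ("over" or "under").
#' @export
significant_stalling <- function(rrt, rrt_thresh = 1.2, p_thresh = 1e-4,
                                 min_windows = 300L) {
  tab <- if (inherits(rrt, "rp_rrt")) rrt$results else rrt
  tab %>%
    filter(
      !is.na(.data$rrt),
      pmax(.data$rrt, 1 / .data$rrt) >= rrt_thresh,
      .data$p <= p_thresh,
      .data$n_windows >= min_windows
    ) %>%
    mutate(direction = if_else(.data$rrt >= 1, "over", "under"))
}

#' Between-strain RRT ratio test
#'
#' Compares per-codon-position RRT between two strains. Each permutation
#' shuffles window labels within both strains and records the log2 ratio of
#' the permuted mean RFs (first strain over second); the observed log2 ratio
#' is scored against that null. Significance uses the stalling criteria on
#' the ratio: `max(ratio, 1/ratio) >= rrt_thresh`, `P <= p_thresh`, and at
#' least `min_windows` windows in both strains.
#'
#' @param cds_1,cds_2 CDS sequence tibbles for the two strains.
#' @param fp_1,fp_2 Footprint placement tibbles for the two strains.
#' @param strain_names Labels for the two strains, used to key the
#'   permutation streams (so swapping data together with labels inverts every
#'   ratio with unchanged P).
#' @param codons Codons to evaluate.
#' @param n_perm Permutations (10,000).
#' @param seed Seed.
#' @inheritParams significant_stalling
#' @return Tibble (`codon`, `position`, `rrt_1`, `rrt_2`, `log2_ratio`, `p`,
#'   `n_windows_1`, `n_windows_2`, `called`, `site`).
#' @export
strain_rrt_ratio_test <- function(cds_1, fp_1, cds_2, fp_2,
                                  strain_names = c("B", "Y"),
                                  codons = sense_codons(), n_perm = 10000L,
                                  seed = 1L, rrt_thresh = 1.2,
                                  p_thresh = 1e-4, min_windows = 300L) {
  purrr::map_dfr(codons, function(cod) {
    c1 <- window_count_matrix(cds_1, fp_1, cod)
    c1 <- c1[rowSums(c1) > 0, , drop = FALSE]
    c2 <- window_count_matrix(cds_2, fp_2, cod)
    c2 <- c2[rowSums(c2) > 0, , drop = FALSE]
    if (nrow(c1) == 0 || nrow(c2) == 0) {
      return(tibble(
        codon = cod, position = 1:RRT_READ_CODONS,
        rrt_1 = NA_real_, rrt_2 = NA_real_, log2_ratio = NA_real_,
        p = NA_real_, n_windows_1 = nrow(c1), n_windows_2 = nrow(c2),
        called = FALSE, site = site_flag(1:RRT_READ_CODONS)
      ))
    }
    m1 <- colMeans(c1 / rowSums(c1))
    m2 <- colMeans(c2 / rowSums(c2))
    null1 <- permute_window_rf(c1, n_perm,
      seed = substream_seed(seed, "rrtratio", strain_names[1], cod)
    )
    null2 <- permute_window_rf(c2, n_perm,
      seed = substream_seed(seed, "rrtratio", strain_names[2], cod)
    )
    obs <- log2(m1 / m2)
    null <- log2(null1 / null2)
    p <- vapply(
      seq_len(RRT_READ_CODONS),
      function(j) empirical_p_two_sided(obs[j], null[, j]), numeric(1)
    )
    ratio <- m1 / m2
    tibble(
      codon = cod, position = 1:RRT_READ_CODONS,
      rrt_1 = m1 * RRT_READ_CODONS, rrt_2 = m2 * RRT_READ_CODONS,
      log2_ratio = obs, p = p,
      n_windows_1 = nrow(c1), n_windows_2 = nrow(c2),
      called = pmax(ratio, 1 / ratio) >= rrt_thresh & p <= p_thresh &
        nrow(c1) >= min_windows & nrow(c2) >= min_windows,
      site = site_flag(1:RRT_READ_CODONS)
    )
  })
}
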