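# quadratic window oracle: scan every possible center of every CDS
oracle_windows <- function(cds_seqs, codon) {
  out <- list()
  for (i in seq_len(nrow(cds_seqs))) {
    s <- cds_seqs$seq[i]
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    n <- length(codons)
    if (n < 17) next
    for (c0 in 9:(n - 8)) {
      win <- codons[(c0 - 8):(c0 + 8)]
      if (win[9] == codon && sum(win == codon) == 1) {
        out[[length(out) + 1]] <- tibble::tibble(
          gene_id = cds_seqs$gene_id[i], center = c0 - 1L
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_id = character(), center = integer()))
  }
  dplyr::bind_rows(out)
}

test_that("window geometry gives 9 eligible positions and an 11% uniform RF", {
  expect_equal(rrt_window_positions(), 9L)
  expect_equal(rrt_window_positions(17, 9), 9L)
  expect_equal(uniform_null_rf(), 1 / 9)
  expect_equal(round(uniform_null_rf(percent = TRUE)), 11)
})

test_that("in-frame footprint retention follows length and frame rules", {
  asn <- tibble::tibble(
    gene_id = "g", feature = c("CDS", "CDS", "CDS", "5UTR"),
    cds_pos = c(27L, 26L, 30L, 12L), length = c(27L, 27L, 26L, 27L)
  )
  kept <- in_frame_footprints(asn)
  # 26 nt read dropped; codon-internal 5' end dropped; UTR read dropped
  expect_equal(nrow(kept), 1)
  expect_equal(kept$codon_start, 9L)
})

test_that("in-frame counts agree with a brute-force per-frame tally", {
  withr::with_seed(51, {
    cds_pos <- sample(0:299, 500, replace = TRUE)
    len <- sample(25:30, 500, replace = TRUE)
  })
  asn <- tibble::tibble(
    gene_id = "g", feature = "CDS", cds_pos = as.integer(cds_pos),
    length = as.integer(len)
  )
  kept <- in_frame_footprints(asn)
  expect_equal(nrow(kept), sum(len >= 27 & cds_pos %% 3 == 0))
  expect_equal(
    sort(kept$codon_start),
    sort(cds_pos[len >= 27 & cds_pos %% 3 == 0] %/% 3)
  )
})

test_that("window extraction requires a unique central codon", {
  # 17-codon CDS with the query only in the middle: exactly one window
  body <- rep("GCT", 17)
  body[9] <- "CAA"
  cds1 <- tibble::tibble(gene_id = "g1", seq = paste(body, collapse = ""))
  w <- build_windows(cds1, "CAA")
  expect_equal(nrow(w), 1)
  expect_equal(w$center, 8L)
  # a second occurrence inside the window excludes it
  body[3] <- "CAA"
  cds2 <- tibble::tibble(gene_id = "g1", seq = paste(body, collapse = ""))
  expect_equal(nrow(build_windows(cds2, "CAA")), 0)
})

test_that("window extraction matches the quadratic oracle on 50 random CDSs", {
  withr::with_seed(52, {
    cds <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:50),
      seq = vapply(1:50, function(i) random_cds(sample(20:80, 1)), character(1))
    )
  })
  for (codon in c("CCA", "GAA", "TGG")) {
    got <- build_windows(cds, codon) |> dplyr::arrange(gene_id, center)
    want <- oracle_windows(cds, codon) |> dplyr::arrange(gene_id, center)
    expect_equal(got, want)
  }
})

test_that("uniform counts give RF 1/9 and RRT 1; RF normalisation holds", {
  body <- rep("GCT", 40)
  body[c(15, 30)] <- "CAA"
  cds <- tibble::tibble(gene_id = "g1", seq = paste(body, collapse = ""))
  fp <- tidyr::crossing(gene_id = "g1", codon_start = 0:31) |>
    dplyr::slice(rep(1:32, 3)) # 3 footprints at every start site
  rt <- rrt_table(cds, fp, codons = "CAA", n_perm = 200, seed = 1)
  r <- tidy(rt)
  expect_equal(r$mean_rf, rep(1 / 9, 9))
  expect_equal(r$rrt, rep(1, 9))
  expect_equal(sum(r$mean_rf), 1)
  expect_equal(sum(r$rrt), 9)
  expect_equal(r$site[r$position %in% 4:6], c("E", "P", "A"))
})

test_that("a mean RF of 2/9 corresponds to RRT 2", {
  body <- rep("GCT", 17)
  body[9] <- "CAA"
  cds <- tibble::tibble(gene_id = "g1", seq = paste(body, collapse = ""))
  # position p corresponds to footprint start 9 - p (0-based): double the
  # count at p = 5, drop p = 9, single read elsewhere -> RF(5) = 2/9
  starts <- c(rep(4L, 2), 8L, 7L, 6L, 5L, 3L, 2L, 1L)
  fp <- tibble::tibble(gene_id = "g1", codon_start = starts)
  r <- tidy(rrt_table(cds, fp, codons = "CAA", n_perm = 100, seed = 9))
  expect_equal(r$mean_rf[r$position == 5], 2 / 9)
  expect_equal(r$rrt[r$position == 5], 2)
})

test_that("codons without usable windows report missing RRT, not zero", {
  cds <- tibble::tibble(gene_id = "g1", seq = random_cds(30, seed = 53))
  fp <- tibble::tibble(gene_id = "g1", codon_start = 0L)
  # TGG absent from this CDS by construction? force it: use a codon not present
  codons <- substring(cds$seq, seq(1, nchar(cds$seq), 3), seq(3, nchar(cds$seq), 3))
  absent <- setdiff(sense_codons(), codons)[1]
  r <- tidy(rrt_table(cds, fp, codons = absent, n_perm = 100, seed = 2))
  expect_true(all(is.na(r$rrt)))
  expect_equal(r$n_windows, rep(0L, 9))
})

test_that("degenerate one-window permutation P hits the attainable floor", {
  counts <- matrix(0, nrow = 1, ncol = 9)
  counts[1, 5] <- 10
  null <- permute_window_rf(counts, n_perm = 1000, seed = 3)
  obs <- counts / sum(counts)
  p5 <- empirical_p_two_sided(obs[5], null[, 5])
  # all mass on one label: observed RF 1 at position 5 is matched by a random
  # permutation with probability 1/9
  expect_lt(p5, 0.5)
  expect_gt(p5, 2 / 1001 - 1e-12)
  # fixed seed reproducibility
  expect_identical(
    permute_window_rf(counts, 500, seed = 4),
    permute_window_rf(counts, 500, seed = 4)
  )
})

test_that("planted dwell multipliers are recovered at the planted position", {
  withr::with_seed(54, {
    cds <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:40),
      seq = vapply(1:40, function(i) random_cds(250), character(1))
    )
  })
  dw <- tibble::tibble(codon = "CCA", position = 5L, multiplier = 1.5)
  fp <- simulate_footprints(cds, dw, n_reads = 80000, seed = 55)
  rt <- tidy(rrt_table(cds, fp, codons = "CCA", n_perm = 500, seed = 5))
  # closed-form expectation under the placement model: RRT = 9m / (8 + m)
  expected <- 9 * 1.5 / (8 + 1.5)
  expect_equal(rt$rrt[rt$position == 5], expected, tolerance = 0.1)
  expect_true(all(rt$rrt[rt$position != 5] < expected))
})

test_that("stalling filter enforces all three printed thresholds", {
  tab <- tibble::tibble(
    codon = c("AAA", "CCA", "CCG", "CAT", "GGT"),
    position = 5L,
    n_windows = c(500L, 299L, 300L, 500L, 500L),
    mean_rf = 1 / 9,
    rrt = c(1.19, 1.5, 1.5, 1 / 1.25, 1.05),
    p = c(1e-6, 1e-5, 1e-5, 1e-6, 1e-9),
    site = "P"
  )
  calls <- significant_stalling(tab)
  # 1.19 fails the effect bound; 299 windows fails support; weak RRT fails
  expect_equal(sort(calls$codon), c("CAT", "CCG"))
  expect_equal(calls$direction[calls$codon == "CCG"], "over")
  expect_equal(calls$direction[calls$codon == "CAT"], "under")
})

test_that("identical strains yield unit RRT ratios and no calls", {
  withr::with_seed(56, {
    cds <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:20),
      seq = vapply(1:20, function(i) random_cds(150), character(1))
    )
  })
  fp <- simulate_footprints(cds, NULL, n_reads = 20000, seed = 57)
  rr <- strain_rrt_ratio_test(cds, fp, cds, fp,
    codons = c("CCA", "GAA"),
    n_perm = 300, seed = 6, min_windows = 1L
  )
  expect_equal(rr$log2_ratio, rep(0, nrow(rr)))
  expect_false(any(rr$called))
})

test_that("swapping strain data and labels inverts ratios with unchanged P", {
  withr::with_seed(58, {
    cds1 <- tibble::tibble(
      gene_id = sprintf("a%02d", 1:15),
      seq = vapply(1:15, function(i) random_cds(150), character(1))
    )
    cds2 <- tibble::tibble(
      gene_id = sprintf("b%02d", 1:15),
      seq = vapply(1:15, function(i) random_cds(150), character(1))
    )
  })
  dw <- tibble::tibble(codon = "GGT", position = 5L, multiplier = 1.6)
  fp1 <- simulate_footprints(cds1, dw, n_reads = 15000, seed = 59)
  fp2 <- simulate_footprints(cds2, NULL, n_reads = 15000, seed = 60)
  r12 <- strain_rrt_ratio_test(cds1, fp1, cds2, fp2,
    strain_names = c("B", "Y"),
    codons = "GGT", n_perm = 400, seed = 7, min_windows = 1L
  )
  r21 <- strain_rrt_ratio_test(cds2, fp2, cds1, fp1,
    strain_names = c("Y", "B"),
    codons = "GGT", n_perm = 400, seed = 7, min_windows = 1L
  )
  expect_equal(r21$log2_ratio, -r12$log2_ratio)
  expect_equal(r21$p, r12$p)
})
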