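# brute-force two-sided empirical P by explicit counting
oracle_emp_p <- function(obs, null) {
  lo <- 0
  hi <- 0
  for (v in null) {
    if (v <= obs) lo <- lo + 1
    if (v >= obs) hi <- hi + 1
  }
  min(1, 2 * min(lo + 1, hi + 1) / (length(null) + 1))
}

# BH from the rank definition: q_(k) = min_{j >= k} p_(j) * n / j
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  for (k in seq_len(n)) {
    q[k] <- min(ps[k:n] * n / (k:n), 1)
  }
  out <- numeric(n)
  out[ord] <- q
  out
}

test_that("constant coverage makes the stratified bootstrap total exact", {
  seq <- random_cds(40, seed = 31)
  counts <- rep(3L, nchar(seq))
  for (pi in list(c(0.25, 0.25, 0.25, 0.25), c(0.4, 0.1, 0.3, 0.2))) {
    tot <- stratified_resample_total(counts, seq, 90L, pi, n_rep = 5, seed = 1)
    expect_equal(tot, rep(90 * 3, 5))
  }
})

test_that("a one-class composition reduces to a plain bootstrap", {
  seq <- strrep("A", 50)
  withr::with_seed(32, counts <- rpois(50, 4))
  tot <- stratified_resample_total(counts, seq, 80L, c(1, 0, 0, 0),
    n_rep = 10000, seed = 2
  )
  # bootstrap expectation: L_target x mean per-base count, within 3 SE
  expect_equal(mean(tot), 80 * mean(counts),
    tolerance = 3 * sd(tot) / sqrt(10000) / (80 * mean(counts))
  )
})

test_that("quota reallocation handles base classes absent from the source", {
  seq <- paste0(strrep("A", 30), strrep("C", 30)) # no G, no T in source
  counts <- rep(2L, 60)
  tot <- stratified_resample_total(counts, seq, 60L, c(0.25, 0.25, 0.25, 0.25),
    n_rep = 3, seed = 3
  )
  expect_equal(tot, rep(120, 3)) # all 60 draws still happen
  expect_error(
    stratified_resample_total(rep(1L, 10), strrep("A", 10), 10L, c(0, 1, 0, 0)),
    "base class"
  )
  expect_error(
    stratified_resample_total(integer(0), "", 10L, c(1, 0, 0, 0)),
    "empty"
  )
})

test_that("null log2 distribution degenerates for constant coverage and centres near 0", {
  seq <- random_cds(40, seed = 33)
  oc <- make_oc_simple(seq, seq, rep(2L, 120), rep(2L, 120))
  null <- null_log2_distribution(oc, "t01_B", "t01_Y", "mRNA", 1,
    source = "B", n = 200, seed = 4
  )
  expect_equal(length(null), 200)
  expect_equal(sd(null), 0)
  expect_equal(null[1], 0, tolerance = 0.02) # 0.5 pseudocount only
})

test_that("two independent null samples agree in distribution (KS)", {
  withr::with_seed(34, {
    seq <- random_cds(80, seed = 35)
    counts <- rpois(240, 2)
  })
  oc <- make_oc_simple(seq, seq, counts, counts)
  n1 <- null_log2_distribution(oc, "t01_B", "t01_Y", "mRNA", 1, "B", 10000, seed = 5)
  n2 <- null_log2_distribution(oc, "t01_B", "t01_Y", "mRNA", 1, "B", 10000, seed = 6)
  ks <- suppressWarnings(stats::ks.test(n1, n2))
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical P matches the exhaustive counting oracle", {
  withr::with_seed(36, {
    for (rep_i in 1:20) {
      null <- rnorm(sample(10:200, 1))
      obs <- rnorm(1)
      expect_equal(empirical_p_two_sided(obs, null), oracle_emp_p(obs, null))
      # with ties
      nullt <- sample(-3:3, 50, TRUE)
      obst <- sample(-3:3, 1)
      expect_equal(empirical_p_two_sided(obst, nullt), oracle_emp_p(obst, nullt))
    }
  })
})

test_that("BH adjustment matches the rank-definition oracle and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  withr::with_seed(37, {
    for (rep_i in 1:200) {
      p <- runif(sample(1:12, 1))
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p))
      expect_true(all(q >= p - 1e-12))
      expect_equal(order(q[order(p)]), seq_along(p)) # order-preserving
    }
  })
})

test_that("identical strains are never significant", {
  seq <- random_cds(60, seed = 38)
  withr::with_seed(39, counts <- rpois(180, 3))
  oc <- make_oc_simple(seq, seq, counts, counts)
  d <- divergence_test(oc, "mRNA", n_resamples = 500, seed = 7)
  r <- tidy(d)
  expect_equal(r$log2_mean, 0)
  expect_gt(r$p_max, 0.5)
  expect_false(r$significant)
})

test_that("genes under the CDS-read filter are skipped with a reason", {
  seq <- random_cds(60, seed = 40)
  oc <- make_oc_simple(seq, seq, rep(0L, 180), rep(1L, 180))
  d <- divergence_test(oc, "mRNA", n_resamples = 200, min_cds_reads = 50, seed = 8)
  r <- tidy(d)
  expect_true(is.na(r$p_max))
  expect_match(r$skip_reason, "50 CDS reads")
  # missing replicate is an error, not a silent skip
  oc2 <- make_oc_simple(seq, seq, rep(2L, 180), rep(2L, 180))
  oc2$coverage <- oc2$coverage[!(oc2$coverage$replicate == 2 &
    oc2$coverage$strain == "Y"), ]
  expect_error(divergence_test(oc2, "mRNA", n_resamples = 200, seed = 8), "replicate")
})

test_that("strain label swap negates observed and null log2 with unchanged P", {
  withr::with_seed(41, {
    seqs <- vapply(1:4, function(i) random_cds(70), character(1))
    cov_b <- lapply(1:4, function(i) list(mRNA = list(rpois(210, 3), rpois(210, 3))))
    cov_y <- lapply(1:4, function(i) list(mRNA = list(rpois(210, 2), rpois(210, 2))))
  })
  oc <- make_oc(seqs, seqs, cov_b, cov_y)
  ocs <- swap_roles(oc)
  d1 <- divergence_test(oc, "mRNA", n_resamples = 400, seed = 9)
  d2 <- divergence_test(ocs, "mRNA", n_resamples = 400, seed = 9)
  r1 <- tidy(d1)
  r2 <- tidy(d2)
  expect_equal(r2$log2_mean, -r1$log2_mean)
  expect_equal(r2$p_max, r1$p_max)
  expect_equal(
    unname(unlist(r2$log2_obs)), -unname(unlist(r1$log2_obs))
  )
  # null itself is negated under the swap
  # same source gene (t01_B) seen from both orientations
  n1 <- null_log2_distribution(oc, "t01_B", "t01_Y", "mRNA", 1, "B", 400, seed = 9)
  n2 <- null_log2_distribution(ocs, "t01_Y", "t01_B", "mRNA", 1, "Y", 400, seed = 9)
  expect_equal(n2, -n1)
})

test_that("pure transcriptional shifts are TE-null, opposite replicate signs kill TE calls", {
  withr::with_seed(42, {
    seq <- random_cds(80, seed = 43)
    base <- rpois(240, 3)
  })
  # equal 4x shift in both assays: TE must be null
  cov_b <- list(list(
    mRNA = list(base, pmax(base - 1L, 0L)),
    RFP = list(base, pmax(base - 1L, 0L))
  ))
  cov_y <- list(list(
    mRNA = list(base * 4L, pmax(base - 1L, 0L) * 4L),
    RFP = list(base * 4L, pmax(base - 1L, 0L) * 4L)
  ))
  lib <- tidyr::crossing(
    strain = c("B", "Y"), assay = c("mRNA", "RFP"), replicate = 1:2
  )
  lib$lib_size <- 1e5
  oc <- make_oc(seq, seq, cov_b, cov_y)
  oc$lib <- lib
  te <- te_test(oc, n_resamples = 400, seed = 10)
  expect_false(tidy(te)$significant)
  # discordant TE direction across replicates: non-significant by fiat
  cov_y2 <- list(list(
    mRNA = list(base, base),
    RFP = list(base * 4L, pmax(base %/% 4L, 0L))
  ))
  oc2 <- make_oc(seq, seq, cov_b, cov_y2)
  oc2$lib <- lib
  te2 <- te_test(oc2, n_resamples = 400, seed = 11)
  r2 <- tidy(te2)
  expect_false(r2$agree)
  expect_equal(r2$p_max, 1)
  expect_false(r2$significant)
})

test_that("regulatory categories are a pure function of the two flags", {
  expect_equal(
    classify_regulation(
      c(TRUE, FALSE, TRUE, FALSE),
      c(FALSE, TRUE, TRUE, FALSE)
    ),
    c("mRNA-only", "TE-only", "both", "neither")
  )
})
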