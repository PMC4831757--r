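# shared constants and small numerical helpers

DNA_BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons
#'
#' @return Character vector of the 61 codons that encode amino acids,
#'   alphabetically ordered.
#' @export
sense_codons <- function() {
  all <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  sort(setdiff(all, STOP_CODONS))
}

is_sense_codon <- function(x) x %in% sense_codons()

# Deterministic substream seeds: every source of randomness hangs off the one
# root seed through a named stream, so stages can be regenerated independently.
# Polynomial string hash mod (2^31 - 1); doubles stay < 2^53 throughout.
substream_seed <- function(seed, ...) {
  key <- paste(..., sep = "/")
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Largest-remainder (Hamilton) apportionment of `total` into quotas
# proportional to `weights`; ties broken by index for determinism.
largest_remainder <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  if (sum(weights) == 0) abort("all apportionment weights are zero")
  exact <- total * weights / sum(weights)
  quota <- floor(exact)
  short <- total - sum(quota)
  if (short > 0) {
    ord <- order(exact - quota, decreasing = TRUE)
    quota[ord[seq_len(short)]] <- quota[ord[seq_len(short)]] + 1
  }
  as.integer(quota)
}

#' Two-sided empirical P value
#'
#' Add-one empirical P against a resampled or permuted null:
#' `min(1, 2 * min(#(null <= obs) + 1, #(null >= obs) + 1) / (N + 1))`.
#' Never returns 0 and never exceeds 1.
#'
#' @param obs Observed statistic (scalar).
#' @param null Numeric vector of null statistics.
#' @return P value in (0, 1].
#' @export
empirical_p_two_sided <- function(obs, null) {
  stopifnot(length(obs) == 1L, is.finite(obs), length(null) >= 1L)
  lo <- sum(null <= obs) + 1
  hi <- sum(null >= obs) + 1
  min(1, 2 * min(lo, hi) / (length(null) + 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values with the usual monotonicity enforcement. Thin,
#' validating wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of P values, each in (0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    abort("P values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

# split a DNA string into codons (length must be divisible by 3)
codon_split <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) abort("sequence length is not a multiple of 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

# random DNA of given length and GC content
random_dna <- function(n, gc = 0.4) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

# sample sense codons with base composition implied by a GC fraction
random_sense_codons <- function(n, gc = 0.4) {
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codons <- sense_codons()
  w <- vapply(strsplit(codons, ""), function(b) prod(base_p[b]), numeric(1))
  sample(codons, n, replace = TRUE, prob = w / sum(w))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
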