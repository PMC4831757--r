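---
title: "Resampling tests for two-strain transcriptome and translatome divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resampling tests for two-strain transcriptome and translatome divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ribodiverge compares the transcriptome (mRNA RNA-Seq) and translatome
(ribosome footprints, RFP) of two yeast strains, ortholog by ortholog. This
vignette explains the models behind each stage, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical choices a user should know about.

## Why a resampling null

Read counts along a gene are far from exchangeable: footprint libraries are
strongly biased by local nucleotide context (A/T enrichment at the 5' base),
coverage is overdispersed, and orthologs differ in length. A parametric count
model calibrated on mRNA data transfers poorly to footprints. The package
therefore builds, for every ortholog pair, an *empirical* null that carries
the gene's own noise structure:

1. Take one ortholog's observed per-base 5'-end counts as the source.
2. Resample positions with replacement, **stratified by nucleotide**: to
   emulate the strain-B context, draw $n_b$ positions carrying base $b$,
   where $\{n_b\}$ partitions the mappable length $L_B$ proportionally to
   the composition $\pi_B$ (largest-remainder rounding); likewise for
   $(L_Y, \pi_Y)$. Summing the drawn counts gives one pseudo-total per side.
3. One null draw is the library-size-scaled ratio
   $\log_2\frac{(T^*_Y + 0.5)/s_Y}{(T^*_B + 0.5)/s_B}$.

Because both pseudo-totals come from the *same* source gene, the null
describes "no divergence beyond resampling noise, at this gene's depth,
length and composition". The observed per-replicate $\log_2(Y/B)$ is scored
against $N$ such draws with the add-one two-sided empirical estimator
$P = \min\!\big(1, 2\min(\#\{\le\} + 1, \#\{\ge\} + 1)/(N+1)\big)$, which can
never return 0. Doing this for both source strains and both replicates gives
four P values; the **maximum** is kept — a deliberately conservative
aggregation that demands agreement across replicates and source contexts —
and BH-adjusted across genes. Because the four components are not perfectly
dependent, the distribution of the max-P under the null is sub-uniform; the
per-component P values are the calibrated quantity (the test suite checks
both: component uniformity, and that the genome-wide fraction of q ≤ 0.05
calls on fully null cohorts stays below 0.07).

The translation-efficiency (TE = RFP/mRNA) test asks whether
$\log_2[\mathrm{RFP}(B/Y)]$ differs from $\log_2[\mathrm{mRNA}(B/Y)]$. Here
each strain is resampled from its *own* coverage in one assay, so the null
ratio retains that assay's true fold change; the observed ratio of the other
assay is scored against it, reciprocally, in each replicate (four component P
values). A gene is TE-divergent only if the sign of the TE shift agrees in
every replicate — otherwise its P is set to 1. Genes are then classified by
the two FDR flags into mRNA-only / TE-only / both / neither.

### Library-size normalisation

The resampling machinery operates on raw base-level counts; ratios
across libraries are only meaningful after depth scaling, so totals are
divided by the library size (total CDS-assigned reads per strain × assay ×
replicate) by default; pass an explicit `lib_sizes` table to
`ortholog_counts()` to override (e.g. depth-matched libraries). Note that
total-count scaling makes calls *relative*: a planted shift on a large
fraction of the genome partially absorbs into the scaling factor, exactly as
with real sequencing depth.

## Ribosome residence time

In-frame footprints (aligned length ≥ 27 nt, 5' end on a codon boundary)
cover nine codons. Within a 17-codon window whose central codon is unique,
the central codon can appear at positions 1..9 of a footprint, so the
no-preference expectation of the relative frequency (RF) at any position is
$1/9 \approx 11\%$. Per window, the nine start-site counts are normalised to
an RF vector (windows with zero footprints are skipped — their RF does not
exist); RF vectors are averaged across windows, and
$\mathrm{RRT} = \overline{\mathrm{RF}} \cdot 9$. Reads longer than 27 nt are
positioned by their 5'-most nine codons. A-, P- and E-sites map to positions
6, 5 and 4.

Significance comes from permuting each window's nine labels independently
(the permutation preserves each window's total and count multiset, breaking
only the position association) and recomputing the across-window mean RF.
Stalling calls additionally require an effect,
$\max(\mathrm{RRT}, 1/\mathrm{RRT}) \ge 1.2$ — the symmetric form covers
under-represented codons — and ≥ 300 supporting windows. The between-strain
test permutes both strains jointly and scores the observed
$\log_2[\mathrm{RRT}_B/\mathrm{RRT}_Y]$ against the permuted ratio.

**Numerical resolution note.** The add-one two-sided P is bounded below by
$2/(N+1)$. At $N = 10{,}000$ permutations (the package default) that floor is
$2.0\times10^{-4}$, which cannot resolve the stalling threshold
$P \le 10^{-4}$; runs that apply the printed threshold should use
$N \ge 19{,}999$ (the acceptance analyses use 20,000). This is a property of
the unbiased estimator, not of the data.

## Gene-model refinement and ORF variants

Refinement compares externally predicted models (ingested as GFF3) to the
annotation: *new* genes need ≥ 50 mRNA and ≥ 50 RFP reads on the CDS and a
length ≥ 150 nt; *extensions* need ≥ 20/20 reads on the added region;
*trims* survive only with zero reads of either assay on the removed region;
every accepted model must begin with ATG and end with an in-frame stop.
"Longer than 150 bp (50 amino acids)" is internally inconsistent as printed
(150 bp = 50 aa); it is implemented as CDS ≥ 150 nt and is configurable.
Read counts over a region count alignments whose 5'-most base falls inside
it, mirroring the feature-assignment rule; predictions overlapping two
existing genes, or shifting without a length change, are reported ambiguous
and never applied.

ORF-variant discovery is purely sequence-driven: the 180 bp (60 codons)
upstream of the start codon are scanned for the 5'-most in-frame ATG with no
in-frame stop before the annotated start (maximal extension); the 180 bp
downstream of the stop are scanned for the first in-frame stop (read-through
region, old stop exclusive to new stop inclusive; an immediately adjacent
stop is a zero-length event and is not a candidate). Acceptance needs ≥ 10
reads in both assays whose 5' ends fall in the region *and* ≥ 80% of region
bases covered by the full aligned spans — span coverage, because 5'-end-only
occupancy could not reach 80% at 10 reads.

## Feature assignment windows

The 5'-end assignment offsets are implemented as one self-consistent
half-open tiling in transcript coordinates anchored at the CDS
($c = 0$ at the first CDS base, length $L$):
5'UTR $[-f_5, -16)$, CDS $[-16, L-14)$, 3'UTR $[L-14, L-1+f_3-28+1)$, and
introns $[i_0, i_1 - 8)$ in their own oriented coordinates. This reproduces
both boundary facts — 16 nt upstream of the start codon is still CDS
(initiating ribosomes protect upstream bases), 17 nt upstream is 5'UTR — and
leaves no gaps or overlaps between windows. All offsets are configuration
values (`assignment_offsets()`); since CDS-only annotations carry no UTR
extents, transcript flanks default to 60 nt on either side. Quantification
(the per-base coverage vector and the ≥ 50-read retention filter) uses 5'
ends inside the CDS proper so that the coverage vector has exactly length
$L$ and sums to the gene's read count.

## The synthetic-data generator

`simulate_strain_pair()` builds one chromosome per strain: intronless
single-interval CDSs (as is typical for budding yeast) of 300–600 nt at GC
0.40, on both strands, separated by 200–400 nt random spacers, with ~0.6%
between-strain substitutions (start/stop codons preserved; no premature
stops introduced). Counts are negative-binomial with a shared gene rate
(default depth 500 reads/gene, dispersion 10, i.e. variance
$\mu + \mu^2/10$) times log-normal positional multipliers ($\sigma = 0.3$)
drawn once per ortholog pair and assay — they model sequence/protocol bias,
which is shared between strains and replicates and which the resampling null
is designed to absorb. Planted effects multiply strain Y's rate by
$2^{\mathrm{log2fc}}$. Footprints are placed pre-aligned with probability
proportional to the product of dwell multipliers of the codons covered at
their specified positions; under a single planted multiplier $m$ at one
position the expected RRT there is $9m/(8+m)$ (1.42 for $m = 1.5$), the
closed form the recovery tests check. `footprint_reads()` optionally emits
raw sequences with 0–3 spurious 3' adenines to exercise the iterative
trimmer. All randomness flows from one root seed through named substreams,
so stages can be regenerated independently.

What the generator does **not** emulate: rRNA contamination, UTR
transcription, GC-dependent amplification bias, mitochondrial genomes, or
codon-usage-correlated expression levels. Passing tests therefore certify
the statistical machinery — calibration, power at planted effect sizes,
parameter recovery, threshold boundaries, symmetries — not the biology of
any particular real library.

## Problem sizes and design choices

The simulation-backed checks run at sizes chosen to make their guarantees
meaningful on a single CPU: 2,000 null ortholog pairs at depth 500 with
1,000 resamples for type-I calibration; 300 pairs with 200 planted 4-fold
shifts (40 up, 160 down — a split whose library masses cancel exactly, so
total-count normalisation does not dilute the planted effects) for power and
TE specificity; 110 genes of 600–900 nt at GC 0.5 (which equalises codon
frequencies, giving every codon ≥ 300 windows) with 100,000 footprints and
20,000 permutations for dwell recovery.

Other deliberate choices, in brief:

* **Coordinates** are 0-based half-open everywhere internally; GFF3 I/O is
  the only conversion boundary.
* **Mappable length** defaults to total CDS length; composition $\pi$ is
  computed over the CDS.
* **Ortholog dedup** removes pairs whose member overlaps any other gene's
  genomic footprint, strand-blind ("one ORF per chromosome location").
* **Aligner**: a naive exact scan with ≤ 2 mismatches via
  `Biostrings::matchPattern()`, intended for toy genomes; ties among
  equal-quality hits mean unmapped, and the first trim level with any hit
  decides. Real data should arrive as external alignments.
* **Degenerate compositions**: base classes absent from a resampling source
  have their quota reallocated proportionally across the remaining classes.
* **Pseudocount 0.5** on totals before logs keeps zero totals finite.
* **Label-swap exactness**: resampling substreams are keyed by the unordered
  gene pair and the source gene, and sides are drawn in a canonical order,
  so swapping the strains negates every observed and null log-ratio exactly,
  with identical P values — a property the test suite asserts, not merely
  approximates.

## Limitations

The divergence and TE tests condition on the observed coverage of each gene;
genes below 50 CDS reads are not tested. The max-P aggregation is
conservative, trading power for robustness to replicate disagreement. The
RRT procedure needs hundreds of windows per codon, i.e. genome-scale coding
sequence; on small gene sets use the configurable thresholds. TE direction
agreement is a hard gate: a gene with a real but noisy TE shift whose
replicates disagree in sign is reported non-significant by design.
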