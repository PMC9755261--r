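---
title: "Methods: salt-responsive lncRNA discovery and regulatory inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salt-responsive lncRNA discovery and regulatory inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncregnet)
```

This vignette documents the statistical procedures implemented in
`lncregnet`, the parameters that matter, and the design decisions taken
where the methodology was genuinely open. It is the package's account
of *why* the code does what it does; the README shows *how* to run it.

## Coordinates and formats

All internal coordinates are 0-based half-open (`[start, end)`), so
`length = end − start` holds everywhere and adjacent intervals share no
base. GTF input/output converts to and from that format's 1-based
inclusive convention at the boundary — a single conversion site
prevents off-by-one drift. The bundled rice DE-lncRNA table satisfies
`end − start = length` exactly for all 13 loci, which is why its
printed coordinates are treated as half-open. Coverage is exchanged as
bedGraph (text, 0-based half-open); motifs as MEME minimal format,
parsed by a reader written in-package because no pre-installed R
package handles that format. Standard parsing (GTF, FASTA, bedGraph)
delegates to rtracklayer and Biostrings.

## The discovery cascade

A transcript becomes a candidate lncRNA by surviving, in order:

1. **Class-code selection** — keep `u`, `i`, `x`, `o`. Selecting these
   codes implicitly removes transcripts matching protein-coding models
   (`=`, `j`, `c`, ...). Unknown codes are preserved by the I/O layer
   and excluded only here.
2. **Expression** — FPKM must reach an exon-dependent threshold
   (0.5 multi-exon, 2.0 single-exon; boundaries inclusive, per the
   printed "≥") in **at least two samples**. Single-exon models are
   less reliable assemblies, hence the higher bar.
3. **Small-RNA removal** — any 1-bp exonic overlap with a small-RNA
   annotation removes the transcript. The rule is strand-agnostic by
   default (the strictest simple reading; `ignore_strand = FALSE`
   relaxes it).
4. **Length** — spliced length (sum of exon lengths, not genomic span)
   strictly greater than 200 bp. Spliced length is the standard
   notion of transcript length; for single-exon models the two
   coincide.
5. **Coding potential** — the transcript must be non-coding by *all
   three* of: a coding-potential classifier, a protein-domain search,
   and a protein-database search. The engines are external; their
   verdicts are inputs. `orf_heuristic_evidence()` is a labelled
   stand-in that calls a transcript coding when its spliced sequence
   contains an ATG-initiated open reading frame of ≥ 100 codons in any
   forward frame — deliberately crude, but sufficient to exercise the
   cascade without external tools.

Survivors are classified by class code: `u` → lincRNA, `i` → intronic,
`x` → antisense, `o` → sense. The per-transcript filters (1, 4, 5)
commute, which the test suite verifies by permutation; the cascade
reports a monotone count funnel.

## Differential expression

The package computes `log2((mean FPKM salt + ε)/(mean FPKM control +
ε))` with pseudocount ε = 0.01 (configurable). The pseudocount bounds
fold changes of zero-expression transcripts and costs < 0.01 in log2
units at baselines ≥ 10 FPKM. Calls use q ≤ 0.05 and |log2FC| ≥ 1, all
boundaries inclusive. The DE test itself is *not* re-implemented:
q-values are an input column (they come from the upstream DE engine in
real data, and from the truth manifest in simulations). When absent, a
Welch t-test on log2(FPKM + ε) with Benjamini–Hochberg correction is
substituted and the output is flagged
(`attr(, "qvalue_source") = "welch_bh_standin"`) — a stand-in, not an
equivalent. `ddct()` implements the 2^−ΔΔCt identity for qPCR
validation arithmetic.

## Cis and trans target inference

**Cis.** Candidate targets are protein-coding genes whose edge-to-edge
distance from the lncRNA is at most 100 kb (inclusive at exactly
100,000 bp), measured from interval edges rather than midpoints —
edges make "distance 0 iff overlapping" true and the window symmetric
between lncRNA and gene. Pairs are then filtered on expression
correlation across **all** samples; the default cut-off |r| ≥ 0.8 is a
package choice, exposed as a parameter, because published cis pairs
span a wide correlation range (|r| from about 0.56 to 0.97) and no
canonical threshold exists.

**Trans.** Module detection is a deliberately simplified, self-
contained WGCNA analog: unsigned adjacency `a = |r|^β` with β = 6, the
conventional soft-threshold power for unsigned networks;
average-linkage hierarchical clustering of `1 − a`; a **static** tree
cut; minimum module size 10. The default cut height is 0.9: with β =
6, members correlating at r sit at dissimilarity `1 − r^6` (≈ 0.47 at
r = 0.9, ≈ 0.22 at r = 0.96) while unrelated transcripts sit near 1.0,
so any cut between ~0.65 and ~0.99 separates the regimes; 0.9 leaves
margin on both sides. (A cut at the eigengene-merging convention of
0.25 would split genuine r = 0.9 modules and was rejected.) The module
summary profile is the first principal-axis projection of members'
standardized expression, sign-oriented to correlate positively with
the members' mean profile — the "eigengene" analog. lncRNA–module
association reports `r²` against the summary profile with a
permutation p-value (≥ 10,000 sample shuffles; plus-one corrected, so
the smallest attainable p is 1/(n_perm + 1) ≈ 1e-4 at the default),
avoiding t-distribution assumptions at n = 12 samples. Enrichment of
module members uses the one-sided hypergeometric upper tail with BH
correction, the universe being all expressed transcripts supplied.

## Chromatin accessibility

For a query interval the package compares its mean per-base coverage
with 50 random regions of identical length (configurable upward for
more stable p-values), sampled uniformly over all (chromosome, start)
placements — chromosomes weighted by how many placements they can host
— excluding only the query itself (null regions may overlap genes or
other lncRNAs; the null is "random genomic position", nothing more).
Reported are a z-score against the null sample, the plus-one-corrected
one-sided empirical p `(1 + #{null ≥ observed})/(n_null + 1)` (never
exactly 0, exactly uniform under the null), a one-sample t-test p of
the null means against the observed value for star-style annotation,
and stars at p < 0.05 / 0.01 / 0.001. The alternative is one-sided
("more accessible than random") throughout. A constant track gives
p = 1 with an undefined z (zero null SD), handled explicitly.

## In-silico mutagenesis

The engine takes any predictor satisfying a two-field contract —
`predict(window) → bounded scalar`, fixed `window_length`,
deterministic — so a trained sequence-to-accessibility network can be
plugged in unchanged. `extract_tss_window()` produces the fixed-length
input (default 196,698 nt in the plug-in convention; desk-scale runs
use ~2–20 knt) with the TSS at index `floor(length/2)`, `N`-padding
past chromosome ends, and reverse complementation for minus-strand
TSSs.

`isms_scan()` slides a window (default 1000 nt) in steps of `stride`,
replaces its content with one uniform-random draw, and records
`|f(modified) − f(reference)|`. Each offset's draw is seeded from
`(seed, offset)`, so a stride-s profile is exactly the stride-1 profile
subsampled — changing resolution never reshuffles randomness. One draw
per offset is the default; `replicates` averages several for variance
reduction. z-scores standardize the profile by its own mean and SD (no
external baseline exists), and peaks are maximal runs of z ≥ 3. The
threshold direction is a deliberate reading: high ISMS marks
disruptive windows, so peaks are *high*-z runs; the opposite reading
would mark everything except the signal. A zero-spread profile yields
no peaks, with a warning.

Single-base mutagenesis substitutes each of the three alternative
bases at every position of a region and reports the signed per-base
extrema: gain = max Δf, loss = min Δf. Both are signed, so gain ≥ loss
always, and a predictor-invisible position has gain = loss = 0.

The built-in `toy_predictor()` scores a window as the sum of
forward-strand PWM log-odds above a match threshold within a centered
receptive field, squashed through a logistic to (0, 1) (baseline 0.5
with no matches). Forward-strand-only scanning is a simplicity choice,
documented here; the predictor exists to make planted-motif ground
truth recoverable, not to model chromatin.

## Motif scanning

Log-odds scores use base-2 logs with motif probabilities floored at
1e-4 (preventing −∞ for zero entries); an `N` contributes the
background-expected score 0. Exact p-values come from dynamic
programming: per-position score histograms discretized at 1e-3
log-odds units are convolved into the full null distribution under iid
background, and the p-value is the upper tail at the (binned) observed
score. The discretization moves any word's score by at most one bin
per position; the test suite checks DP tails against exhaustive 4^L
enumeration within that slack for all motif lengths ≤ 6. Scores above
the maximum achievable are clamped to the top bin, keeping p > 0.
p-values are per-position/per-strand with no multiple-testing
correction (FIMO convention) and the default threshold 1e-10 is
applied raw. The scanning background defaults to the scanned
sequence's own composition (overridable); minus-strand hits are scored
on the reverse complement and reported in plus-strand coordinates.
Note that an information-rich motif must be ≥ 17 positions long for
even its consensus to clear 1e-10 under uniform background — shorter
motifs simply cannot produce hits at that stringency.

## miRNA target mimicry

Duplexes are scored by banded global alignment of the miRNA (5'→3')
against the reversed target site (antiparallel pairing), allowing at
most two unpaired bases per strand. Penalties: Watson–Crick 0, G:U
wobble 0.5, mismatch 1.0, gap 2.0, all doubled at miRNA positions
2–13 — a reconstruction of the cited screening tool's documented
scheme (the thresholds, expectation ≤ 5 and < 4 mismatches, are the
only published facts; every penalty is exposed as a parameter). G:U
wobbles are penalized but not counted as mismatches. The multiplier
for a gap between miRNA positions p and p+1 is that of the 3'-ward
flanking position (clamped to the miRNA); ties in the traceback
resolve pair > miRNA-gap > site-gap. Two consequences worth noting:
the unpairing-energy filter of the original tool (UPE ≤ 25) requires
RNA secondary-structure prediction and is intentionally out of scope
(the column is reported as not evaluated); and because G:U pairing and
the seed weighting are strand-asymmetric, duplex scores are *not*
invariant under exchanging the two molecules' roles except for perfect
complements — the test suite asserts exactly that scoped property.
`screen_mimics()` evaluates every offset with a single DP vectorised
across site end positions (cell-for-cell identical to the scalar
scorer, which the tests verify), keeping the best site length per
offset and flagging the best site per (miRNA, lncRNA) pair.

## The synthetic data generator

`simulate_dataset()` emulates the statistical structure the pipeline
assumes: a 2-genotype × 2-condition × 3-replicate design (12 samples),
a 2 × 100 kb genome, and 200 transcripts of which 30 are true lncRNAs
and the rest are engineered to fail exactly one filter each (wrong
class code, short, small-RNA overlap, coding, under-expressed).
Defaults mirror the study design the package targets: three biological
replicates, planted salt-response log2 fold changes of ±1.3–1.8 (the
four effect sizes reported for the tolerant genotype), a planted
module of 50 co-expressed transcripts at target correlation r = 0.96
driven by one lncRNA, accessible regions elevated 10× over background
on DE-lncRNA loci, two planted 18-bp PWM instances-in-genome, and
three miRNAs with perfect complementary sites inside lncRNAs.

Numerical choices: FPKM noise is log-normal multiplicative (σ = 0.2 by
default; positive support and heavy-ish tails are typical of FPKM; σ =
0 gives exact planted values for recovery tests). Module correlation
is induced by a single shared latent factor on the log scale with
loading √r, which makes member pairs correlate at exactly r in log
space — members therefore receive no additional independent noise,
otherwise the calibration would be diluted (and for r close to 1 could
not be achieved at all). Coverage background is Gamma(4, 4) (mean 1,
continuous, so rank-based p-values are tie-free). All randomness flows
from the single config seed through an isolated RNG scope; generation
is byte-identical across runs of the same config.

What the generator does **not** emulate: realistic genome composition,
read-level noise, assembly artefacts, correlated filter failures,
length-dependent expression biases, or any secondary structure.
Passing tests on this data demonstrate that the algorithms recover
what they are defined to recover — not that the pipeline's thresholds
are well-calibrated for real rice data.

## Problem sizes used in validation

The test suite and the acceptance script run the generator at
desk scale (2 × 40–100 kb genomes, 90–200 transcripts), mutagenesis on
2001-nt windows with a 1001-nt receptive field (stride 20, swap window
100), 500-simulation null-calibration for the accessibility p, 20-seed
Monte-Carlo suites for peak recall and module co-assignment, and
exhaustive enumeration oracles (4^L words for L ≤ 6; all banded duplex
pairings for ≤ 25-nt sites). These sizes are the package's own
validation design: large enough for the Monte-Carlo bounds asserted,
small enough to run everywhere.

## Known limitations

* Cuffdiff-style DE statistics, coding-potential engines, liftover and
  GO/KEGG services are consumed as inputs or replaced by labelled
  stand-ins; the package does not reproduce them.
* The WGCNA simplification (static cut, no topological overlap, no
  scale-free fit diagnostics) is adequate for planted-block recovery
  but will fragment subtle modules in real data.
* The mimicry scoring scheme is a documented reconstruction; absolute
  expectation values need not match the original web tool, though the
  thresholds behave comparably.
* The toy predictor is a testing device. Conclusions about real
  regulatory sequence require plugging in a trained model through the
  predictor contract.
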