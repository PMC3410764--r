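---
title: "Methods: identifying miRNA cleavage targets from degradome libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying miRNA cleavage targets from degradome libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biological model

Most plant miRNAs silence their targets by guiding Argonaute-mediated
slicing of the mRNA precisely between the bases pairing the tenth and
eleventh nucleotides of the miRNA (counted from its 5' end). The 3'
cleavage fragment retains a free 5' monophosphate, which makes it -- and
essentially nothing else in the cell -- ligatable to an RNA adapter.
Degradome (PARE) sequencing exploits this: sequenced 20--21 nt tags mark, at
single-nucleotide resolution, 5' ends of decay fragments, and a pile-up of
tag 5' ends at the position pairing miRNA nt 10 of a complementary site is
direct evidence of miRNA-guided cleavage.

`degradomeR` implements the full desk-scale analysis: read filtering,
exact-match mapping to transcript models, plant-style complementarity
search, CleaveLand-style 0--4 classification of the cleavage signature,
library-size normalisation (TP100M), an empirical shuffle-null p-value,
tissue-partition set logic across libraries, and annotation-set comparison
between datasets.

## Coordinates and alphabets

All coordinates are 1-based and inclusive. The cleavage coordinate
(`C.Site`) is the transcript position of the 5'-most nucleotide of the 3'
cleavage fragment -- the base pairing miRNA nt 10; for a gap-free duplex
ending at transcript position `e` this is `e - 9`. Internally every sequence
lives on the DNA alphabet (`U -> T` on input, restored on FASTA output of
miRNAs); one alphabet means one pairing table and exact string matching,
with no change to the biology.

## Read filtering and mapping

Only 20--21 nt reads with mean Phred quality >= 20 are analysed (the length
window is what an MmeI-based degradome protocol produces; the exact quality
criterion used historically is unstated, so mean-Q >= 20 is the exposed
default). Reads are collapsed to distinct sequences with multiplicities,
then matched *exactly*, sense-strand only, against the transcript set; a
read contributes its multiplicity at every matching locus of every matching
transcript. Multi-mapping is deliberate: paralogous gene families share
target sites, and the published analyses report all family members, leaving
disambiguation to downstream experiments. Antisense matches are never
counted -- a degradome signature is by construction a sense-strand 5' end.
Reads containing `N` never match.

## Duplex scoring

The historical pipeline states only a gate: "alignments with scores up to 7
and no mismatches at the cleavage site". The penalty scheme here is the
standard plant target-prediction scheme of that pipeline's lineage:

| event | penalty |
|---|---|
| Watson-Crick pair | 0 |
| G:U wobble | 0.5 |
| mismatch | 1 |
| each gapped position | 1 |
| any of the above at miRNA positions 2--13 | doubled |

Every penalty, the core interval and its multiplier are configurable
(`duplex_penalties()`); whether the original analysis doubled the core or
capped G:U pairs is unknowable from the text, so the defaults are documented
rather than claimed historical.

The search enumerates every gap-free antiparallel window exhaustively, plus
variants with at most one single-nucleotide bulge on either strand. Larger
internal loops are vanishingly rare in validated plant targets and are not
searched. A bulge is never placed between miRNA positions 10 and 11, and
"no mismatches at the cleavage site" is enforced as: the transcript bases
pairing miRNA nt 10 *and* nt 11 must be paired (WC or G:U) -- both flanks of
the scissile bond. For one window, the minimum-score pairing is kept (ties:
fewer gaps, then fewer G:U); all qualifying windows are reported.
For bulge doubling, a transcript-side bulge between miRNA positions `j` and
`j+1` is treated as inside the core when `2 <= j <= 12`; this sub-case is a
package convention, exposed in the same config.

`call_targets()` needs candidate sites only at read-covered positions (a
call requires at least one tag at the cleavage coordinate), so it uses an
anchored variant of the same search restricted to covered positions. This is
an exact optimisation -- property-tested against the exhaustive
enumeration -- and is what makes the 500-replicate null calibration and
larger transcript sets tractable.

## Categories

Signatures at candidate sites are classified by abundance relative to the
rest of the transcript:

* **4** -- the site carries exactly one read (checked first: a 1-read
  signature is "very low abundance" even when it is the transcript maximum);
* **0** -- site count equals the transcript maximum, and that maximum is
  attained at exactly one position;
* **1** -- site count equals a maximum attained at more than one position;
* **2** -- above the median;
* **3** -- at or below the median.

The median is taken over positions carrying >= 1 read, with the site
included. This convention matters: including the zeros of every uncovered
position would make "above the median" true for any covered site and
category 2 vacuous. Sites with zero reads are never called.

## TP100M

`TP100M = site_count * 1e8 / total_mapped`, with `total_mapped` the
library's transcriptome-matched read count. The name reads "tags per 100
million"; the magnitudes printed in the published tables are consistent with
this scale against the library sizes of the published run (whether the
historical denominator was genome- or transcriptome-matched totals is
unstated; transcriptome-matched is the natural choice for a
transcript-mapping pipeline and is the documented convention here).

## Empirical p-value

The published tables print p-values without a construction. The convention
implemented here is the established degradome one: `n` composition-preserving
mononucleotide shuffles of the miRNA are re-scored against the entire
transcript set; `k` counts shuffles achieving, anywhere, a candidate
alignment with score at most the observed score whose cleavage coordinate
carries evidence of category at most the observed category; with add-one
correction `p = (1 + k) / (1 + n)`, so `p >= 1/(n+1)` and `p` is never 0.
The shuffle stream is seeded and reproducible; shuffles are shared across
calls of the same (library, miRNA), which changes nothing statistically and
saves most of the compute. These p-values are *not* claimed numerically
identical to the published ones.

A calibration caveat, verified by the acceptance suite: at the published
gate (7), a random 21-nt miRNA essentially never has a candidate site on
random sequence (the expected penalty of a random window is ~23), so a pure
null produces no calls at all and "calibration" would be vacuous. The
calibration experiment therefore relaxes the gate to 18 so that chance-level
sites are called, and checks that at most 10% of those null calls reach
p <= 0.05. Conversely, a perfect complementary site yields a small p-value
*by sequence alone* -- the p-value measures how unusual the complementarity
is given the evidence, not transcript-level expression.

## The synthetic generator

`simulate_library()` states a world rather than offering dials to chase
tests with: random transcripts (default 10 of 0.8--2 kb, GC 0.42, roughly
soybean-transcript-like), planted targets as exact reverse complements of
their miRNAs at recorded loci, `Poisson(lambda_signal = 50)` signal reads
whose 5' ends sit exactly at the canonical cleavage coordinate, uniform
`Poisson(0.01/position)` background decay starts, read lengths 20 or 21 with
equal weight, constant Q40 qualities, everything reproducible from a
mandatory seed. It emulates the *signature geometry* of a degradome library.
It does not emulate adapter chemistry, PCR duplication, quality decay,
positional 5'-bias of real decay, paralogous gene families, or expression
heterogeneity -- so a green recovery test establishes the pipeline's
correctness on the stated signal model, not robustness to those artefacts.
Quality filtering is exercised separately with crafted low-quality reads.

## Set logic

Tissue specificity is defined on distinct (miRNA, target-transcript) pairs
pooled across all libraries of a tissue, regardless of stage; transcript ids
are compared in full, isoform suffix included, because the published tables
list isoforms as distinct targets. A miRNA is "shared" iff it has at least
one call in each tissue. Annotation groups are compared case-insensitively
after whitespace collapse and trailing-punctuation stripping, preserving
original spellings in the output -- the published comparison table mixes
capitalisations of the same group.

## Numerical and degenerate-input choices

* Identical read sequences are collapsed before matching; counts are
  multiplied back, so profiles are independent of read order (tested
  bitwise).
* Alignments sharing a cleavage coordinate on one transcript are collapsed
  to the best-scoring one in `call_targets()` (the call's identity is the
  coordinate); distinct coordinates are never collapsed.
* Transcripts shorter than the miRNA yield an empty candidate set with a
  warning, not an error.
* A library with no qualities skips the quality filter with a notice.
* `total_mapped = 0` makes TP100M undefined; it is a hard error rather than
  a silent 0/0.
* Planting a site too close to the transcript 3' end for a 21-nt tag is a
  configuration error at simulation time.

## Known limitations

No genome-level (spliced) mapping, no mismatch-tolerant mapping, no
thermodynamic duplex evaluation, no FDR control across calls (raw p-values,
as published), no transcript-abundance adjustment, and no GO enrichment.
Targets silenced by translational repression rather than slicing are
invisible to degradome data by construction.
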