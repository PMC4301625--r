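---
title: "Methods and design of marscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of marscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Matrix attachment regions (MARs, also called S/MARs) are the genomic
segments that remain bound to the nuclear matrix — the salt- and
nuclease-resistant nucleo-proteinaceous scaffold of the nucleus — after
chromatin extraction. They are thought to anchor the bases of chromatin
loops and to colocalize with regulatory elements such as replication
origins and promoter-proximal paused RNA polymerase II. A genome-wide MAR
map is typically produced by sequencing a MAR-DNA preparation in
replicates, calling peaks per replicate, and characterizing the
reconciled peak set. marscan implements that characterization step for
the *Drosophila*-style setting: ~120 Mb of euchromatin, thousands of
short (median ~0.4 kb) AT-leaning intervals, and a standard battery of
sequence and context analyses.

## Replicate reconciliation

Two replicate peak sets are reconciled into *common peaks*: the
bipartite overlap graph with an edge wherever a peak from one replicate
overlaps a peak from the other by at least `min_overlap` bp (default
50), and one output interval per connected group. We report the **union
span** of each group — this preserves the full supported region and is
consistent with final MAR sizes of up to ~3 kb — and record the
intersection of the two per-replicate group spans as metadata, so either
convention can be recovered. Duplicate identical peaks are collapsed
first.

Two subtleties are worth stating because they shaped the test suite:

* The number of output *groups* is **not** monotone in `min_overlap`:
  raising the threshold can split one chained group (peak A1–B–A2) into
  several, increasing the count. The number of *participating peaks* is
  monotone, and that is the property we assert; the full semantics is
  pinned by equivalence with an all-pairs brute-force reconciler on 200
  random instances.
* When reporting "~70% of peaks overlap", the denominator matters. The
  report emits the common-peak count as a fraction of each replicate and
  of the union, so all three readings are available.

Replicate agreement at the read level is measured as the Pearson
correlation of per-window tag counts: each chromosome is tiled with
consecutive non-overlapping windows (500 bp default) anchored at
coordinate 0, the trailing partial window included; a tag belongs to the
window containing its start, strand ignored.

## Coordinates and interval statistics

All coordinates are 0-based half-open (BED convention) throughout. The
midpoint of an interval is `floor((start+end)/2)`; inter-MAR distances
are midpoint-to-midpoint between *consecutive MARs on the same
chromosome arm* (no cross-arm distances), a proxy for chromatin loop
size. The density table reports kb of DNA per MAR and genes per MAR per
arm plus a totals row; arms with zero MARs yield `NA` ratios rather than
errors.

## Sequence-signature scanners

* **ATC rule**: one strand carries ≥ 20 consecutive bases from {A,T,C}
  with no intervening G. On the scanned strand this is a maximal
  {A,T,C} run (plus sense) or a maximal {A,T,G} run (the same signal on
  the complementary strand). The two senses are reported separately.
  One consequence worth knowing: a poly-G tract *satisfies* the rule,
  because its complement is poly-C.
* **ORI motifs**: every occurrence of ATTA, ATTTA, ATTTTA and of their
  reverse complements, overlaps included; assessed on both strands
  because strandedness of the original assessment is unknown.
* **AT-rich**: maximal regions covered by any 100 bp window with A+T
  fraction ≥ 0.70.
* **Curved / kinked DNA, topoisomerase II, BUR**: the literature that
  defines the classic MAR signal set does not print the exact patterns,
  so marscan ships a configurable registry
  (`feature_registry()`) holding the classic rule-based-predictor
  choices: curved = AAAA-N7-AAAA-N7-AAAA (and its reverse complement),
  kinked = TA/TG/CA dinucleotide blocks in any order with N3 spacers,
  topo II = the in-vitro *Drosophila* consensus GTNWAYATTNATNNR, BUR = a
  short AT-tract unwinding-element core (flagged as a caveat: fixed
  patterns capture base-unpairing regions poorly, and both BUR and
  topo II sites are expected to be rare in fly MAR sets). Users can
  amend the registry; every hit-level result records which pattern
  matched.
* N (and any non-ACGT input character) matches no pattern symbol and
  breaks every run.

"Contains feature" at the MAR level means ≥ 1 hit anywhere in the
interval; the enrichment table reports the fraction of MARs per feature,
not hit counts.

## SSR canonicalization and scanning

A repeat unit is canonicalized to the lexicographically smallest string
among all rotations of the unit and of its reverse complement; units
that are whole-number repetitions of shorter units are excluded. This
yields 2/4/10/33/102/350 classes for unit lengths 1–6 — 501 in total.
The scanner reports maximal *perfect* tandem tracts of ≥ 12 bp (at least
two full units); imperfect repeats are deliberately not detected — the
published hexamer examples "resembling poly-A with one mismatch"
describe motif similarity, not scanner tolerance. A tract is attributed
to the period of its primitive unit only (a poly-A run is never also an
AA-class locus); by the Fine–Wilf periodicity bound, a ≥ 12 bp tract
with a primitive unit of length ≤ 6 has that unit length as its minimal
period, so the attribution is unambiguous. In the rare case of two
same-class tracts overlapping, the leftmost is kept.

Fold enrichment is not defined in the source literature; marscan defines
it as (fraction of the class's loci overlapping MARs) / (MAR fraction of
the euchromatic genome), which is 1.0 under uniform random placement.
Both ≥ 1 bp-overlap and fully-contained association modes are available;
classes with ≤ 100 genomic loci are suppressed.

## TE association

MAR sequences are aligned to canonical TE sequences by affine-gap local
alignment (Smith–Waterman via Biostrings), MAR on both strands against
the TE plus strand. Defaults emulate legacy blastn-style bl2seq scoring
(match +1, mismatch −2, gap open 5, gap extend 2) because the original
tool is named but its parameters are not. A hit requires identity
≥ 0.90 over ≥ 100 aligned columns; identity counts gap columns in the
denominator (conservative). Note that the *optimal* alignment of a
perfectly planted fragment may extend a few columns into flanking
sequence, trading one extra mismatch for several matches, so recovered
identities can sit marginally below 1.0. The per-family summary reports
the percentage of genomic copies overlapping MARs over all copies and
over full-length copies (≥ 95% of canonical length) separately, because
the denominator convention in published tables is ambiguous.

## Genomic context

Classification is midpoint-based against the annotation with precedence
5'UTR > 3'UTR > exon > intron when features overlap (isoforms pooled per
gene); a midpoint in no gene span is intergenic. "Non-coding" totals are
emitted both including and excluding UTR categories. TSS profiles bin
strand-oriented midpoint offsets within ±1 kb of each TSS (50 bp bins, a
granularity chosen since the original figure's is unstated); a midpoint
within range of several TSSs contributes to each by default, with a
unique-nearest mode available. Raw counts are used, with optional
density normalization. Promoter (TSS ± 300 bp, labeled stalled/active)
and boundary overlaps use the ≥ 1 bp rule, reported in both directions.
Expression tiers are consumed as input labels; tiering is not computed.

## The synthetic universe

`generate_universe()` builds a fully self-contained test world from one
RNG stream: its defaults are the stated conditions of the mapped MAR set
— log-normal sizes with median 400 bp and σ(log) = 0.3164 so that ~90%
fall below 600 bp, truncated to 100–3000 bp; 200 MARs over three 300 kb
chromosomes; 90% placed outside gene spans; a 70% replicate-overlap
fraction with ≤ ±25 bp peak jitter; per-feature planting probabilities
mirroring the published enrichment fractions (ATC 0.94, ORI 0.95; the
unanchored features get fixed, realistic defaults). SSR tracts and TE
fragments are planted both inside MARs and in the background at counts
that clear the > 100-locus reporting threshold.

The generator's central guarantee is *closure*: a MAR carries a
scanner-detectable feature exactly when the generator planted it. MAR
background sequence is drawn at 50% AT with forced G/C breakers every
17 bp (so no ATC-rule run can arise spontaneously on either sense) and
then *scrubbed*: every unplanted feature hit and unplanted SSR tract is
eliminated by targeted point substitutions outside protected planted
spans, iterating to a fixed point. Kinked-DNA hits are removed by a
greedy local descent (naive single-letter rules can complete a new
TA/TG/CA block and oscillate). Planting instances were chosen — and are
verified by tests — to trigger exactly their own scanner: e.g. the
AT-rich instance is an aperiodic 15-mer at 80% AT repeated 8 times,
because a plain (AT)n tile would itself be an SSR tract and an ATC run.

What the synthetic world does *not* emulate: mappability artifacts,
sequencing error, color-space read structure, heterochromatin, copy
number, or realistic AT-content correlation between MARs and their
flanks (scrubbed MAR background is deliberately feature-free, which real
AT-rich MARs are not). A green closure test therefore establishes that
the pipeline recovers what was planted under its own stated rules — not
that it would call the same peaks from raw reads.

Determinism: one global RNG stream seeded from `config$seed`; identical
seeds give byte-identical outputs, and the seed is recorded in the
emitted metadata.

## Numerical and degenerate-input choices

* Pearson correlation over windows with zero variance in either
  replicate is an error, not NA.
* `size_stats` on an empty set is an error; empty overlap results are
  valid zeros.
* Even-length interval midpoints round down.
* The trailing partial window of each chromosome is counted.
* Same-class SSR tract overlaps resolve to the leftmost tract.
* Alignment identity uses gap-inclusive denominators; score ties are
  resolved by the underlying dynamic program (first-optimum).

## Known limitations

* The curved/kinked/topoII patterns are a documented, configurable guess
  at an unpublished signal set; only the ATC-rule and ORI fractions have
  published anchors.
* The reconciliation of the published peak counts (13,471/13,360 →
  9,215 common → 7,353 euchromatic) cannot be reproduced offline because
  the replicate peak sets and the supplementary BED are not
  redistributable inside this package; the pipeline reproduces the
  corresponding quantities on its synthetic world, and the
  per-arm density arithmetic is reproduced from the published count
  table shipped in `inst/extdata/`.
* Windowed tag correlation in the synthetic world saturates below the
  published 0.975 at the default tag depth, because non-shared peaks cap
  the achievable agreement; the property tested is its monotone rise
  with tag depth, not the raw value.
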