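---
title: "Finding and annotating plant bidirectional promoters"
author: "BidiProm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and annotating plant bidirectional promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BidiProm)
```

## The screen

A bidirectional promoter is a single intergenic region from which two
adjacent genes on opposite strands are transcribed divergently. In
Arabidopsis, characterized seed-expressed examples share three features
that this package turns into a screen: a short TSS-to-TSS spacing, an
outward (head-to-head) orientation, and multiple copies of the G-box ABRE
(the palindromic hexamer CACGTG) in the shared region, sometimes coupled
to other ABA/stress elements (DRE/CRT with a CCGAC core; CE3 coupling
elements).

The pipeline has three stages, each an exported function:

1. `findDivergentPairs()` — geometric scan of an annotation;
2. `buildCandidateTable()` — sequence extraction plus cis-element filter;
3. downstream summaries (`elementSpacing()`, `summarizeLocalizations()`,
   `coexpressionScore()`, `motifDepletionStat()`).

## Coordinate and distance conventions

All coordinates are 1-based inclusive (the GFF3 convention); the only
conversion to 0-based half-open happens in BED export. The strand-aware
TSS of a minus-strand transcript is its annotated *end* coordinate.

The TSS distance is the **exclusive interior length**,
`len = tss_fw − tss_rv − 1`: the number of bases strictly between the two
start sites, so the "promoter" contains no transcribed base. Published
tables of this kind do not always state their ±1 convention (one
published pair prints 264 bp between TSSs but 518 bp between ORFs, which
no single convention reconciles without the archived annotation), so the
exclusive convention is applied uniformly and symmetrically: the
start-codon distance `startCodonDistance()` uses the same exclusive rule
between the strand-aware 5' CDS ends. The default window is
100–600 bp, inclusive at both edges.

Two orientation decisions are deliberate:

* **Outward transcription is required** (`tss_rv < tss_fw`). Convergent
  or overlapping opposite-strand arrangements whose TSSs happen to fall
  within the window are not bidirectional promoters and are rejected.
* **Intervening transcripts veto a pair** by default: if any other
  transcript's span touches the interior interval, the two flanking genes
  do not share a promoter. Known paralogous pairs separated by two
  intervening genes are exactly the case this excludes. Setting
  `requireNoIntervening = FALSE` reproduces a purely distance-based scan.

Isoform combinations collapse to one row per gene pair, keeping the
smallest TSS distance — the most conservative promoter span — with ties
broken lexicographically by transcript id, so output order is a pure
function of the input.

## Motif scanning

`scanMotif()` implements position-level IUPAC matching: every start
offset is tested, overlapping occurrences all count, and under the
default `strandPolicy = "both"` the reverse complement of the pattern is
scanned as well, with minus-strand hits reported at the forward offset of
their leftmost base. A palindromic pattern (CACGTG equals its own reverse
complement) is reported once per offset with strand `+` — offset-level
counting is the only unambiguous reading of "copies", and for the G-box
the strand question is moot. For non-palindromes such as the DRE core it
is not, which is why strand policy is part of each `MotifCatalog` entry.

`N` in a subject sequence matches nothing by default (conservative:
an ambiguous base is never evidence for an element), switchable to
`nPolicy = "any"`. Flanks of width 2 are reported with every hit —
flanking nucleotides are known determinants of ACGT-element specificity —
and are clipped at sequence ends, never padded.

The CE3 consensus is a configurable catalog entry, defaulting to the
barley *HVA1* CE3 (`ACGCGTGTCCTC`); CE3 definitions vary between studies
and the element is scanned like any other pattern. `elementSpacing()`
reports, for each downstream element, the nearest upstream partner and
the bases strictly between them (negative values flag overlap), which is
how the "CE3 five bases downstream of a G-box" geometry is measured.

## The depletion model

`motifDepletionStat()` makes the "this element is under-represented"
statement explicit. Under an independent-base background with frequencies
q, a pattern of length k matches one slot with probability
p = Π_j Σ_{b ∈ allowed_j} q_b; with n = L − k + 1 slots the count is
modelled Binomial(n, p) and the lower tail P(X ≤ x) is reported.
Dependence between overlapping slots is deliberately ignored — a
documented approximation, accurate for short non-self-overlapping
elements at genomic scales. The arithmetic is anchored in tests by a
constructed case with n·p = 1 exactly and by binomial tails frozen from
an exact arbitrary-precision evaluation.

## The synthetic genome generator

`generateSyntheticGenome()` emulates what the scan assumes about a
compact plant genome: multi-chromosome sequence with single-exon gene
models on both strands, qualifying divergent pairs planted at controlled
TSS spacings and motif layouts, and one decoy class per failure mode —
TSS gap below or above the window, same-strand arrangement, convergent
orientation, a single G-box, and an intervening gene.

Choices that matter for interpreting the tests:

* **Sanitized intergenic regions.** Each planted region is
  rejection-sampled (bounded at 10,000 redraws, then a clear generation
  error) until it contains no G-box/DRE/CE3 occurrence beyond the planted
  ones, so manifest comparisons are exact. The ubiquitous ACGT core is
  not sanitized: every G-box contains one, and chance ACGTs carry no
  weight in any filter. Gene bodies and buffers are unconstrained
  background — the pipeline never scans them.
* **Buffers wider than the window.** Units are separated by more than
  `maxGap` bases so no cross-unit TSS pair can satisfy the distance
  predicate; every accepted pair is attributable to one planted unit.
* **Decoys that fail for exactly one reason.** The intervening-gene
  decoy's inner gene sits on the minus strand so that it cannot itself
  form a qualifying pair with the planted G-boxes on its left; its own
  divergent pairing with the downstream gene sees only motif-free
  sequence and falls to the element filter. The convergent decoy uses
  short (120 bp) gene models so its TSS spacing lands inside the window
  and only the orientation predicate rejects it.
* **Defaults as study conditions.** Three qualifying pairs per genome;
  the first carries three G-boxes plus a DRE and a CE3 placed 5 bp
  downstream of a G-box — the coupled-element geometry of the
  characterized 411 bp/three-G-box and CE3-bearing exemplars — and later
  pairs alternate two/three G-boxes. TSS gaps are drawn uniformly from
  the 100–600 bp window; gene models are 300–500 bp with a 50 bp 5' UTR
  so the TSS- and ATG-distance conventions are distinguishable; the
  background is uniform by default with an AT-rich preset
  (A = T = 0.32, C = G = 0.18) matching Arabidopsis intergenic
  composition. Chromosomes are 9 kb × 3 — small enough that a full
  multi-seed sweep (the suite uses 20–25 seeds) runs in seconds, large
  enough to host every unit class.
* **Determinism.** One integer seed drives everything; identical spec
  and seed give byte-identical FASTA/GFF3/JSON, which the suite asserts.

`verifyGroundTruth()` closes the loop by re-scanning every manifest
region, confirming each planted literal at its offset, the absence of
unplanted catalog motifs, and TSS agreement between manifest and gene
models.

What passing on synthetic data does **not** show: real annotations have
multi-exon, multi-isoform gene models with UTR uncertainty, TSSs known
only to annotation precision, ambiguity bases, and motif-dense intergenic
backgrounds. The generator exercises the pipeline's logic, not the
biology of any particular assembly.

## The packaged 70-pair table

The genome-wide Arabidopsis screen behind this package (100–600 bp TSS
window, ≥2 G-boxes) produced 70 gene pairs; a transcription ships in
`inst/extdata/arabidopsis_70_pairs.tsv` and loads via
`loadTable1Fixture()` with integrity checks (row count, column schema,
y/blank flag dialect). Intergenic lengths span 129–595 bp and exactly one
pair — AT3G03150/AT3G03160, 264 bp — carries both a DRE and a CE3.
G-box/ACGT counts were not printed in the source table and load as `NA`.
One annotation string contained a corrupted glyph in the available text
and is transcribed without it; one localization field prints the literal
label "NA" (a pseudogene) and is kept verbatim rather than treated as
missing.

`summarizeLocalizations()` reports counts and proportions by verbatim
label; published percentage summaries of such tables typically group
labels (endomembrane/secretory, "other") by rules that are not fully
specified, so grouping here is a user-supplied map, not code, and no
particular grouped percentages are asserted.

## Transmission genetics

`transmissionEfficiency()` is the standard resistant/sensitive × 100
ratio per gamete direction, taking raw F1 counts (so it is testable on
toy data) and refusing a zero sensitive count rather than returning
infinity. `selfingGenotypeExpectation()` converts relative transmission
(m, f) into expected selfed-progeny genotype fractions, optionally
removing the homozygous-insert class (zygotic lethality) and
renormalizing. It is interpretation support: observed segregation ratios
in real lines fold in viability and scoring effects the model does not
represent, so no particular observed ratio is asserted as a prediction.

## Numerical and degenerate-input behaviour

* Window bounds inclusive; `minDist > maxDist` is a configuration error.
* Adjacent TSSs (`len = 0`) give an empty interior and empty sequence,
  not an error; missing CDS makes the start-codon distance `NA`, not an
  error.
* FASTA letters outside A/C/G/T/N map to N with a warning; duplicate
  chromosome names and empty records are errors; GFF3 bodies with a wrong
  column count fail naming the line; strandless transcripts are rejected
  by id.
* Background frequencies must sum to 1 within 1e-9; zero-variance
  expression vectors yield an `NA` co-expression score with a warning.

## Scope and limitations

The scan is transcript-annotation-driven: it does not refine TSSs from
CAGE/EST evidence, model tandem same-strand shared promoters, or analyze
convergent terminator pairs. Motif handling is exact-pattern (IUPAC), not
position-weight-matrix scoring, and no motif discovery is attempted. The
localization and expression inputs are user-supplied tables; no
prediction tools or expression atlases are queried.
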