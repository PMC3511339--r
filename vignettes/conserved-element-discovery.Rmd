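---
title: "Conserved noncoding element discovery with CNEscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved noncoding element discovery with CNEscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CNEscan)
```

## The problem and the model

Enhancers and other *cis*-regulatory elements are not transcribed and carry
no reading frame, so they cannot be found by gene-prediction methods.
What they do show, often, is unusual sequence conservation: a functional
element resists the neutral drift that erodes the noncoding DNA around it.
CNEscan operationalizes this as a purely identity-based criterion on a
pairwise alignment of orthologous loci: a **conserved region (CR)** is a
maximal run of sliding windows in which the two species agree at more than
`minIdentity` percent of alignment columns, at least `minSpan` baseline bp
long. Each region is scored

$$\mathrm{score} = \mathrm{percent\ identity} + \mathrm{length}/60,$$

which rewards both fidelity and extent: at 60 bp of extra length buying one
identity point, a 715 bp region at 78 % identity (score 89.92) outranks a
604 bp region at 79 % (89.07). Candidates are ranked by this score and the
top regions are then examined for transcription factor binding sites
(TFBSs) conserved between the species.

This is deliberately simpler than phylogenetic conservation models
(phastCons/phyloP): no tree, no rate model, one baseline species and one
target at a time. Multiple targets are handled as independent
baseline-vs-target pairs; we do not attempt a sum-of-pairs multiple
alignment, because every downstream step (window identity, projection,
TFBS pairing) is defined against the baseline frame.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `minIdentity` | 70 | % | strict lower bound for a window to pass |
| `window` | 100 | baseline bp | sliding-window width |
| `minSpan` | 100 | baseline bp | minimum merged-region length |
| `step` | 1 | baseline bp | window stride |
| match / mismatch | +1 / −1 | score | aligner substitution scores |
| gap open / extend | 4 / 1 | score | a gap of length $k$ costs $4 + k$ |
| matrix threshold | 0.85 | fraction | matrix-similarity cutoff for PWM hits |
| `minOverlap` | 0.5 | fraction | reciprocal overlap for TFBS pairing |

The identity thresholds follow the standard "> 70 % identity over a 100 bp
span" criterion for calling candidate elements; the strict inequality is a
literal reading of that rule, and `minSpan` uses ≥. The aligner scores are
our own defaults — whole-locus anchored aligners used for this task at
genome scale do not publish a single parameter set — and are visible and
overridable through `alignParams()` rather than hard-coded.

## Coordinate and counting conventions

All intervals are 1-based closed `IRanges`, the native Bioconductor
convention, so the "From–to" rendering of report tables is the identity and
conversion to 0-based half-open happens only when writing BED. Three
counting rules deserve emphasis:

* **Window identity is computed over alignment columns** spanned by the
  window's baseline residues. Columns where either species has a gap, and
  columns containing N, count in the denominator and never as matches, so
  indels register as non-conservation.
* **Span and region length are measured in baseline residues**, not
  alignment columns: reported lengths are ungapped per-species lengths.
* **Region identity is recomputed over the merged region's full column
  span**, not averaged over its windows (window averages double-count
  overlapping columns). A merged run that fails `minIdentity` after
  recomputation is dropped, so every emitted region satisfies its own
  thresholds.

## Alignment engine

`alignPair()` is a global affine-gap (Gotoh) dynamic program in C++, with
an optional diagonal band for long, colinear sequences; a band narrower
than the length difference is rejected with an explicit error rather than
silently truncated. Traceback ties are broken deterministically
(match/mismatch over gap-in-target over gap-in-baseline), so identical
inputs always give byte-identical output. At desk scale this replaces the
anchored whole-locus aligners used on ~100 kb loci; for large inputs an
external alignment can be imported (`importAlignment()`, aligned FASTA or
MAF) and fed to the identical downstream computation. The test suite checks
the engine three independent ways: exhaustive enumeration of all alignments
on short pairs, equality of banded and unbanded scores, and agreement with
`Biostrings::pairwiseAlignment` under the same penalties.

## Motif model

Motifs are IUPAC consensus words or 4×w position-count matrices, each with
a designated **core** — the most informative contiguous positions, rendered
upper-case in reports (e.g. `tgACTCa`). Matrix scanning scores a window as
(sum of observed-base counts) / (sum of per-position maxima), a transparent
surrogate for proprietary matrix-similarity scores; the default threshold
0.85 is configurable per motif. Consensus scanning is exactly the
threshold-1.0 special case of the indicator matrix, and both strands are
always scanned, with hits reported in plus-strand coordinates (minus-strand
table rows print the word as read on the minus strand, recoverable via
`revcompIupac()`). Overlapping hits of the same motif are all reported —
near-palindromic sites such as the AP-1 heptamer TGASTCA legitimately
appear on both strands at one locus. The degenerate-code rule is
conservative: the code N matches any base, but an observed N in the
sequence never satisfies a more specific code.

`deleteCore()` and `disruptedSites()` support the in-silico counterparts of
mutagenesis experiments: excising a site's core and asking whether a rescan
still finds the motif, and intersecting a variant (e.g. a small deletion
seen in one cell line) with hit cores to ask whether it can change TFBS
content at all.

## Cross-species TFBS conservation

A binding site is called conserved when hits of the *same matrix* in the
two species occupy the *same aligned position*: the target hit is projected
through the alignment onto the baseline and paired with the baseline hit of
greatest reciprocal overlap (≥ `minOverlap`, same strand by default),
greedily, each hit joining at most one pair. Positional overlap, not
sequence identity of the site, is the criterion — the motif match itself
already enforces sequence agreement. The report format is the conventional
five-column table (`Family, Matrix, From-to, Str., Sequence`) plus machine
columns with absolute coordinates, overlap fraction and scores.

## What the simulator emulates — and what it does not

`simulateOrthologPair()` generates a uniform-random baseline, then derives
the target by per-base substitution at rate $1 - \mathrm{identity}$
(uniform over the three alternatives) with geometric-length indels at a
per-base rate, identity being elevated inside planted blocks. Planted motif
words are written verbatim into both species and kept indel-free so truth
coordinates stay exact. A single RNG stream seeded once drives everything,
making FASTA outputs byte-identical across runs.

Identity, not evolutionary distance, is the controlled quantity, because
the detection criterion is raw percent identity; the substitution model is
therefore Jukes–Cantor-like and deliberately ignores transition/transversion
bias, CpG hypermutability, GC content, repeats and rearrangements. Default
conditions — 3 kb baseline, background identity 0.5 (mid neutral-divergence
range for mammal-to-mammal noncoding DNA), indel rate 0.02 with mean length
2, blocks of 300/250/400 bp at identities 0.85/0.90/0.80, AP-1 words
TGACTCA and TGAGTCA plus an NFκB decamer planted in the first block — were
fixed once as a realistic detection regime. Passing the benchmark shows the
pipeline recovers planted identity structure through its own alignment; it
does not show robustness to repeat content, assembly gaps, or alignment
ambiguity in real genomes, where imported alignments from an anchored
aligner are the recommended input.

## Numerical and degenerate-input choices

* Alignment scores are floating point; traceback preference comparisons use
  a $10^{-9}$ tolerance so exact ties resolve by the stated priority rather
  than accumulation order.
* An empty motif library, an empty hit set, or an empty region set all
  propagate as empty-but-well-formed outputs (header-only tables), never
  errors; a pipeline stage failure is reported with the stage name.
* A projected interval with zero aligned residues returns an explicit empty
  projection (coverage 0) rather than a zero-width range.
* `evaluateRecovery()` with no calls reports recall 0 and undefined (NA)
  precision, distinguishing "nothing called" from "wrong calls".

## Design decisions that were genuinely open

* **Masking vs excision in the pipeline.** `extractNoncoding()` implements
  strict excision (complement of merged coding intervals) and is exported
  for callers that want the pieces; `runPipeline()` instead masks coding
  residues to N before aligning. Masking keeps one coordinate frame for the
  whole locus — no stitching of per-segment alignments — while N columns
  can neither count as identity matches nor carry motif hits, so coding
  sequence still cannot seed a conserved region. Strand of the annotation
  is ignored: coding is masked on both strands.
* **Per-CR conservation percentages are pairwise.** Published per-region
  "conservation" figures are sometimes computed across many species at
  once; this package defines and labels them as pairwise-vs-baseline, and
  window identity is likewise pairwise. The multiple-species case is run as
  several baseline-target pairs.
* **Soft-masked (lower-case) input.** Whether repeat-masked residues should
  be excluded is corpus-dependent; input is upper-cased on load and treated
  as sequence. Callers wanting repeat exclusion should N-mask repeats in
  the input FASTA.
* **Report-table sorting.** Conserved-TFBS tables are always sorted by
  baseline start. Printed tables of this kind occasionally contain
  out-of-order rows; we treat that as presentation, not contract, and sort
  unconditionally.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: enumeration-oracle
alignment on pairs up to 6 bp (all ~9 × 10³ alignments per pair);
conservation oracles on 200 random gapped alignments up to 300 columns;
and the full simulate → align → call → evaluate pipeline on twenty 3 kb
ortholog pairs, which completes in well under a minute. These sizes were
chosen so the whole suite documents the method's behavior quickly on any
machine; nothing in the implementation is specific to them, and the aligner
handles multi-kb loci directly (quadratic memory for traceback, banded if
needed).

## Known limitations

* Global alignment assumes colinear, orthologous input without
  rearrangements or inversions; it will force an alignment of
  non-homologous sequence rather than refuse.
* The identity criterion cannot distinguish conservation from regional
  mutation-rate variation; candidates are hypotheses for experimental
  validation, not verdicts.
* The matrix-similarity score is a transparent surrogate, not a calibrated
  reimplementation of any proprietary scanner; hit counts at a given
  threshold are not comparable to published MatInspector-style counts.
* TFBS pairing is pairwise; three-way (or deeper) site conservation is out
  of scope.

## A compact end-to-end run

```{r demo, eval = FALSE}
library(CNEscan)
report <- runDemo(tempfile("demo_"), seed = 1)
report$metrics$recall        # 1.0: all three planted blocks recovered
report$counts$conservedTfbs  # 5: both AP-1 sites (both strands) + NFkB
head(report$pairs)
```
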