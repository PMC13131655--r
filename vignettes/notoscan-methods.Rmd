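---
title: "Methods: quantifying haplotype variation, transposon dynamics and conserved elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying haplotype variation, transposon dynamics and conserved elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notoscan)
```

## Scope and design

`notoscan` implements the interval-level quantification machinery used in
comparative genomics of the notothenioid (Antarctic fish) radiation: calling
heterozygous transposable-element (TE) insertions between the two haplotypes
of a phased assembly, testing what predicts where structural variants (SVs)
land, dating repeat activity through time, measuring genome gain and loss per
branch of a dated species tree, classifying conserved elements (CEs) by the
lineage in which they arose, filtering gene trees for selection scans, and
dissecting the tandem structure of antifreeze-glycoprotein (*afgp*) loci.

The package is deliberately genome-free: every analysis consumes plain
interval tables (BED/GFF3/TSV), and a synthetic-data module generates all of
them with known planted truth. All coordinates are 0-based half-open
internally; GFF3 is converted at I/O. Every user-facing function takes a data
frame first and returns a tibble, so stages compose with the pipe.

## The interval engine

All downstream rules reduce to a handful of primitives whose exact semantics
matter, so they are implemented once and tested base-by-base against
brute-force oracles:

* **Reciprocal overlap.** Two intervals match when each is covered by the
  other over at least a fraction *t* of its own length. The threshold is
  *inclusive* (`>= 0.75` passes at exactly 75%), reading "at least 75%"
  literally.
* **Strict-gap merging.** "Closer than *N* bp" merges at gap `< N` (gap 99
  merges under *N* = 100; gap 100 does not). An optional group key (e.g. an
  ancestral event id) restricts merging to fragments of the same event.
* **Score-based overlap resolution.** Flattening a repeat annotation keeps,
  at every base, the hit with the higher alignment score; ties break by
  earlier start, then input order. A deterministic rule is fixed here because
  upstream tools leave it unspecified; lower-scoring hits may survive as
  truncated fragments.
* **Coverage fractions** are of the *union* of the annotation, and windows
  are clipped at chromosome ends with the clipped length as denominator.
* **Shuffled controls.** `shuffle_intervals()` preserves each interval's
  length and places it uniformly over permitted positions. By default
  placement is genome-wide excluding assembly gaps and does not preserve the
  chromosome; a `preserve_chrom` flag is provided, since published pipelines
  differ and the choice is rarely stated.

## Heterozygous TE insertions and the SV association model

Insertions and deletions between haplotypes (reported as full intervals on
the haplotype that carries the sequence) are intersected with the repeat
annotation of that same haplotype under the reciprocal 0.75 rule; an indel
matching several hits keeps the highest-overlap one. Recent insertions are
expected to show lower divergence from their family consensus, tested with a
one-sided Wilcoxon rank-sum test (exact null for `min(n, m) <= 8` without
ties, otherwise a tie-corrected normal approximation with continuity
correction; fully tied data returns p = 0.5 with a warning rather than an
error).

The association stage contrasts observed SVs (response 1) with an equal
number of shuffled controls (response 0) in a binomial GLMM with chromosome
as a random intercept (lme4, Laplace approximation; a fixed-effect `glm`
fallback is available and flagged in the output). Predictors are distance to
the nearest chromosome end, distance to the closest assembly gap, SV length,
and the fraction of TE, tandem-repeat, LINE and gene bases in 50-kb windows
flanking the SV midpoint.

One numerical choice deserves emphasis: predictors are standardized using the
**control-group** mean and SD rather than the pooled sample. The shuffled
controls estimate the genomic background distribution, so coefficients are
log-odds per background-SD — a scale that does not shrink or stretch with the
strength of the enrichment being estimated. Pooled standardization would
inflate the scale whenever cases are strongly shifted, biasing a planted
log-odds of 1 upward by ~10% at the effect sizes tested here. Odds ratios and
95% intervals are `exp(beta +- 1.96 SE)` (Wald). SV length is kept as a
predictor even though controls inherit case lengths (making it uninformative
marginally); with correlated covariates it can still absorb conditional
signal, and dropping it is a flag away. On chromosomes without an assembly
gap, gap distance is imputed as the maximum observed distance; a layout with
no gaps at all drops the predictor and records that in the output.

## Dated repeat landscapes

Per-copy CpG-corrected Kimura divergence *K* (%) converts to age as
`age = (K/100) / divisor` with a neutral rate of 3.2e-3
substitutions/site/MY. Both `divisor = 2r` (divergence accrues on both the
copy and consensus lineages; the default) and `divisor = r` exist in the
literature, and the convention used upstream of a given table is often
unstated — so it is an explicit flag, not a guess. Landscapes bin each copy's
full bp length by age (1-MY bins for class-level profiles, 0.5-MY for
family-level ones); total bp is conserved exactly, and ages past the last bin
accumulate in an overflow bin rather than being dropped.

## Branch-wise gain/loss and TE attribution

Per branch of a dated tree, net gain is insertion bp minus deletion bp, and
the rate divides by branch duration (Mb/MY). Lifted insertion intervals are
typically fragmented; fragments sharing an ancestral event id and closer than
100 bp are merged per branch, and the merged interval length (not the
fragment sum) is what the reciprocal 0.75 rule sees for TE attribution —
matching the intent of counting genuine TE insertions once. Deletions are not
lifted or merged; their bp comes from the mutation table directly. The
per-lineage rate curve is piecewise constant over `[parent age, child age)`
on the root-to-leaf path; smoothing is off by default, and when requested the
moving-average window is recorded in the output.

## Conserved elements

CEs closer than 5 bp merge (strict). Ancestry is classified from per-species
alignment-depth tracks treated as presence/absence: *ancestral* iff every
species covers at least 75% of the element (inclusive), *clade-specific* iff
every focal-clade member reaches 75% while at least one outside species
falls below, *other* otherwise. Genomic-feature assignment is decided at the
element midpoint with priority exon > promoter > TTS > intron > intergenic;
the promoter window is 2,000 bp upstream + 200 bp downstream of the TSS
(strand-aware) and the TTS window ±200 bp. These windows mirror common
annotation-tool defaults since the original parameters are not recorded; all
are arguments. Gene association is nearest-gene by default (ties report all
equidistant genes; a distance cap is available) because a window mode would
require a threshold the source pipelines do not state.

## Gene-tree filtering

A gene tree is kept when its unrooted topology contains a bipartition
separating exactly the focal clade *and* one separating clade + sister.
The conservative both-conditions reading was chosen because the prose it
derives from is grammatically ambiguous; an either/or mode is exposed. The
test re-roots at a leaf outside the query set, making the decision invariant
to input rooting; with multiple gene copies per species, strict mode requires
all copies inside the bipartition. Background subtraction of
temperate-lineage hits is a plain set difference — idempotent and monotone.

## Antifreeze-locus analytics

A plain *afgp* gene is functional iff it has the exon-1 signal peptide, an
intact exon-2 reading frame, and the AARG terminal motif; a chimeric
*afgp/tlp* gene additionally needs the XLF spacer and its *tlp*-derived
exons. Loss of the *tlp* exons is encoded as a pseudogene reason, following
the treatment of the large-deletion chimeric copy as a pseudogene. Checks may
be supplied as flags or derived from exon sequences (the spacer is matched as
a tripeptide with `X` as a wildcard, since only the motif name is fixed).

Haplotype comparison matches gene copies positionally within strand runs
between the `hsl`/`tomm40` anchors — appropriate when the two haplotypes are
structurally near-identical, which is the regime this analytic targets; exon-2
length differences report `frame_preserving = (|delta| mod 3 == 0)`.
Alternating-orientation arrays are maximal runs of strictly alternating
strand with length >= 4 (`floor(len/4)` pairs-of-pairs), and the duplication
motif detector searches the token sequence (gene tokens carry type and
strand, repeat tokens their family) for the tandem repeat `U^k` maximizing
copies × unit length, requiring at least two gene tokens per unit, with ties
preferring more copies then the earlier start.

## The synthetic-data generator

Every generator is a deterministic function of its parameters and a single
seed (child streams per component, so adding a generator never perturbs
another), and every planted truth is recoverable by the corresponding stage
at noiseless settings. What the generators emulate — and what they do not:

* **Diploid SV datasets** plant het indels with a matching repeat hit at
  reciprocal overlap exactly `1 - jitter` (jitter moves the breakpoints as a
  rigid shift — a breakpoint-placement error — rather than resizing, so at
  20% jitter every copy still clears 0.75 and recall stays 1); non-TE indels
  are rejection-sampled never to reach reciprocal 0.7 with any repeat.
  Rearrangement midpoints are drawn by exponential tilting
  `P(x) ∝ exp(sum beta_j z_j)` over a uniform candidate pool, with densities
  computed on the same 50-kb flanks the association stage uses and
  standardized by pool moments — exactly the scale on which the model
  estimates, making the planted log-odds identifiable.
* **Branch mutations** use Poisson event counts with mean
  `rate × duration / event_bp` and fixed event length, fragmented into up to
  3 pieces with gaps of 10–90 bp sharing one event id; TE events carry a
  repeat hit spanning the merged interval. Events occupy disjoint genomic
  slots, so cross-event interference is impossible by construction.
* **Depth tracks** place covered subintervals so planted labels sit on the
  requested side of the 75% boundary; `margin = 0` puts them exactly on it
  (ceiling/floor rounding keeps inclusive/strict sides honest).
* **Repeat divergences** invert the dating formula from a truncated-normal
  age mixture (defaults: equal-weight components at 2 and 9 MY, the shape of
  a two-burst activity history).
* **Afgp loci** are token-level: units of four alternating-strand *afgp*
  genes plus a TE motif, two chimeric genes, anchored by *hsl*/*tomm40*.

None of the generators simulate nucleotide sequence, read error, alignment
artefacts, or real SV length/density distributions. Passing tests therefore
demonstrate that the *quantification rules* are implemented exactly and that
the statistical machinery is calibrated — not that the pipeline is robust to
assembly error or annotation noise in real genomes.

## Problem sizes and numerical checks

The test suite runs the interval oracles on ~1,000 random instances per
primitive (coordinates up to 10 kb so per-base bitmaps stay cheap), recovery
of 500 + 500 planted indels, association calibration and recovery over 50
replicates each (500 + 500 controls on 10 × 2 Mb chromosomes for the null;
2,000 + 2,000 on 20 × 5 Mb with a planted tandem log-odds of 1 for
recovery), 20-replicate Poisson moment checks for branch rates, and
exhaustive enumerations for the 6-leaf tree filter, small-sample rank-sum
test, and tandem-unit detector (unit lengths 2–6, 2–5 copies). These sizes
were chosen as the smallest at which the binomial/Poisson tolerances quoted
in the tests are meaningful.

Degenerate inputs are rejected early (`start >= end`, negative lengths,
unknown vocabularies, zero-length branches), distance queries on chromosomes
without targets return `NA` rather than erroring, and separation in the
association model is an error naming the predictor rather than a silently
huge coefficient.

## Known limitations

Positional gene matching across haplotypes assumes collinear loci; a
best-identity fallback would be needed for rearranged loci. The GLMM reports
Wald intervals, adequate at the tested sample sizes but optimistic for rare
predictors. The duplication-motif detector is exact-token (`O(n^3)`), suited
to loci of hundreds of tokens, and does not model degenerate unit copies.
Depth tracks are binary per species; graded alignment depth is collapsed to
presence/absence.
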