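---
title: "Multipartite mitogenome architecture and isoform stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipartite mitogenome architecture and isoform stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoforms)
```

## The model

Flowering-plant mitochondrial genomes are rarely single circles. Large
direct repeats recombine frequently enough that the genome exists as a pool
of alternative circular DNA molecules — *isoforms* — interconverting through
repeat-mediated homologous recombination. A *master circle* carries both
copies of a recombinationally active repeat and can split into two
*subgenomes*; the reverse fusion regenerates it.

`mitoforms` models this situation combinatorially. The genome is reduced to
its minimal unbreakable units, the *segments*: an assembly-graph edge is cut
at every boundary of an active repeat copy, and all genomic copies of one
repeat collapse to a single segment id. Observed adjacencies between
oriented segment ends are *junctions*; a junction and its strand-flip
describe the same molecule, so one canonical writing is stored (the
byte-order-smaller of the two, with forward sorting before reverse). An
isoform is then a circular walk over oriented segments in which every
adjacent pair (including the wrap-around) is a junction and no junction is
used twice.

Junction-simplicity is the package's operational definition of a "main
genome isoform". It is the weakest combinatorial rule that reproduces the
published eight-isoform pool on the nine-segment reference architecture
while automatically excluding dimeric and larger circles, whose existence
the source assembly cannot rule out but which reuse junctions. The
enumeration is a depth-first search over junction-simple walks, with
circles deduplicated under rotation and reverse complement; an independent
test oracle enumerates junction subsets and searches each subset for closed
arrangements, and the two agree on randomized multigraphs and on the
reference architecture.

## The nine-segment reference architecture

`zm9_fixture()` builds the architecture the package is calibrated on: nine
segments `a`–`i`, two recombinationally active direct repeats (`d` = Rep1,
4,845 bp; `b` = Rep2, 3,695 bp), twelve junctions, and eight isoforms —
master circles `iso1` (184,709 bp), `iso2`, `iso1*` and subgenomes
`isoI`–`isoV`. The three assembly edges sum to 149,304 + 35,405 + 2,339 =
187,048 bp.

The published letter-to-coordinate assignment is not fully recoverable from
text, so the fixture is a constructive reconstruction satisfying every
stated constraint simultaneously: the segment order `c-d-e-b-c` is unique
to `isoI`, `g-d-e-b-c` is unique to `iso1*`, masters contain `a` and `e`
exactly once, and the reaction network closes (iso1 splits into
{isoI, isoV} via Rep2 and {isoIII, isoIV} via Rep1; iso2 splits into
{isoI, isoII} via Rep2). The free segment lengths default to values that
reproduce the printed edge sums and are overridable, with violations
rejected.

One published number is deliberately not reproduced: the stated `iso2`
length of 156,143 bp exceeds the edge arithmetic (149,304 + 2,339 =
151,643) by 4,500 bp, and no accounting for the difference is given. The
fixture reports the arithmetic value and carries the discrepancy in
`$iso2_note` rather than forcing agreement.

## Repeat detection

`find_repeat_pairs()` self-compares the genome under an ungapped diagonal
model: candidate diagonals come from shared k-mer seeds (or all diagonals
in `method = "exhaustive"`), and on each diagonal maximal exact runs of at
least `word_size` matches are extended in both directions under a +1/−μ
score with an X-drop stop, μ = `min_identity/(1 − min_identity)` so that a
segment scores non-negatively exactly when its identity reaches the
threshold. Extension is trimmed back to the maximum-score ends, so a
planted perfect repeat is reported at its exact boundaries with identity
1.0 rather than padded with random flank until the windowed average decays
to the threshold — the failure mode of a "longest window above identity"
definition. Defaults follow the study parameters: minimum length 50 bp,
identity 0.80, copy separation 2,000 bp. The model is ungapped because the
package's divergence model is substitution-only; indel-diverged repeat
copies would split across adjacent diagonals and be reported as fragments.

Circular genomes are scanned on a doubled linearization; wrapped hits are
mapped back modulo the length, copy order is canonicalized, and fragments
of a pair split at the artificial origin are pruned by circular
containment.

## Recombination activity

For each repeat pair, four references are built, each `1,000 bp left flank
+ repeat unit + 1,000 bp right flank`: `M1`/`M2` carry the parental flank
compositions of the two copies, `R1`/`R2` the two recombined compositions.
A long read is assigned to the unique reference on which its best local
alignment reaches 80% identity and covers at least 80% of both flank
windows; reads qualifying on several references are discarded as ambiguous
and tallied. Activity is `(R1 + R2) / (M1 + M2 + R1 + R2)`.

The matcher is a seeded anchor-and-extend: shared 13-mers vote for a
diagonal, and the best ungapped local segment on the modal diagonal
(vectorized maximum-sum subarray) supplies span and identity. Flank
coverage is measured over that local segment, not the geometric overlap —
a parental read aligned end-to-end against a recombined reference still
matches the shared flank plus unit at ~89% overall identity, and only the
local-segment rule separates the two hypotheses.

Classification bands: activity ≥ 0.05 is *active* (observed active repeats
sit near 0.5), exactly 0 is *inactive*, below 0.02 is *substoichiometric*,
and the remainder is reported as *indeterminate* rather than forced — the
source study states no numeric threshold, so the band boundaries are
package defaults and configurable.

## Long-read junction support and isoform confirmation

Reads are projected onto segment paths by aligning against each isoform
sequence (doubled, so wrap-around spans stay contiguous) and converting the
best single span into the ordered oriented segments it traverses. A read
supports a junction when its alignment covers at least 60% of each 500 bp
window around the junction point, the study's support rule. An isoform is
confirmed by a read containing one of its *unique subpaths* — a contiguous
walk fragment (up to one full turn plus one segment) occurring in no other
isoform on either strand. The minimal confirming read length counts
internal segments in full plus 1 bp into each terminal segment; this
convention is declared rather than inferred, since the published minimal
lengths depend on unpublished true coordinates. Isoforms whose minimal
length exceeds the longest available read are flagged `requires longer
reads` instead of being counted as absent.

## Segment copy number from short reads

Per-position depth over the unique-segment reference is combined from two
linearizations with distinct break points by per-position maximum,
removing the break-point coverage artifact. Positions shared with nuclear
or plastid sequence (NUMT/mtptDNA) are masked — either by the internal
exact-seed homology scanner (adequate for the synthetic planted NUMTs; 85%
identity, minimum interval 200 bp in place of an engine-specific e-value)
or by importing a precomputed mask BED. Copy number per segment is the
median of unmasked depths divided by the per-sample *target coverage*: the
mean coverage of single-copy nuclear genes divided by two for diploidy.
The median of an even count is the lower middle value, a deterministic
convention. Samples are kept only if the raw median depth of segment `b`
(the smaller repeat, hence the highest-copy segment) reaches 40×, and
cohorts flagged for segmental duplication are excluded regardless of
depth. `duplication_scan()` reports windows exceeding 1.5× their segment's
median; a duplication spanning a *whole* segment inflates that median too,
so an optional external baseline (expected per-segment depth) is accepted
for that case.

## Stoichiometry algebra

Short-read depth cannot tell which reversible reactions are open, so copy
numbers are expressed in a *fixed representation*: isoIV′ is set to zero,
after which isoI′ = copy(`e`), isoII′ = copy(`i`), isoV′ = copy(`g`), and
isoIII′ is measurable three independent ways — `h − g`, `c − e`, `a − f`.
For any mixture of the five subgenomes the three formulations agree
exactly (the package verifies this identity over randomized
stoichiometries), so their disagreement on real data diagnoses molecules
outside the five-subgenome pool, such as partially overlapping linear
forms. Negative values arising from noise are flagged, not clipped, to
keep cohort statistics unbiased. Equal subgenome stoichiometry yields
2:1:0:0:2; the *balanced representation* transfers half of
`min(isoI′, isoV′)` from each of isoI′/isoV′ into isoIII/isoIV under the
equal-pairs assumption, giving 1:1:1:1:1.

Cohort comparisons use each sample's copy vector divided by its mean over
the nine segments as the "relative copy number" (the source plots relative
values without printing a normalizer). "Nonoverlapping distributions" is
operationalized as an empty intersection of per-group [min, max] ranges; a
rank-sum p-value is reported alongside but is not the flag.

## What the synthetic data do and do not emulate

The generators draw uniform-alphabet segment sequences, perfect repeat
copies, reads with truncated-normal lengths and substitution-only errors,
and Poisson per-position depth whose mean is target × membership-weighted
stoichiometry, plus diploid single-copy nuclear genes at mean 2 × target.
They deliberately do not model PacBio error profiles (indels dominate real
CLR error), GC-dependent coverage bias, chimeric reads, or imperfect
repeat copies. Passing tests therefore demonstrate correctness of the
combinatorics and estimators under the declared contracts
(identity/coverage thresholds, Poisson noise), not robustness to every
artifact of real sequencing; on real data the alignment and masking steps
would come from standard aligners via the import paths.

Problem sizes used by the test suite and acceptance checks are the
package's own choices for a desk-scale run: activity estimation at n = 200
reads per condition, copy-number recovery at 50× target over the full
178.5 kb reference, 100 random multigraphs for the enumeration oracle, and
quadratic-oracle scan comparisons on sequences below 5 kb.

## Numerical choices and degenerate inputs

* Junction canonicalization and all signature sorts use byte-order (radix)
  comparisons, independent of session locale.
* Identity thresholds are applied with a 1e-9 slack so that windows whose
  identity equals the threshold exactly are kept despite floating-point
  rounding (identities are rationals spaced far above 1e-9).
* Kadane tie-breaks: first maximal end, then earliest start (longest
  segment for that end).
* `flank = 0` in reference construction is rejected (the four references
  collapse); identical flank compositions trigger an
  "indistinguishable" warning since M/R states cannot be separated.
* A fully masked segment yields `NA` copy number with a QC flag, never a
  silent drop; `target = 0` is an error.
* Zero-activity denominators return `NA` activity with class `no_data`.

## Known limitations

* The scanner and matcher are ungapped; indel-rich divergence needs an
  external aligner feeding the same contracts.
* Reaction kinetics are not modeled; the reaction network states which
  interconversions exist, not their rates or equilibrium.
* Enumeration cost grows with junction count (it is exponential in the
  worst case); the intended regime is small organelle multigraphs, not
  general assembly graphs.
* Substoichiometric-form composition is reported only through the
  formulation-consistency diagnostics, not inferred.
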