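---
title: "Genotyping and phasing complex variants with customized alignment scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping and phasing complex variants with customized alignment scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Some clinically important variants hide from standard short-read pipelines.
The motivating example is the *CBS* locus on chromosome 21: the pathogenic
SNV c.833T>C (chr21:44,483,184 A>G on the plus strand of GRCh37/hg19) very
often occurs in cis with a benign 68 bp insertion, c.844_845ins68, which is
a near-perfect tandem duplication of the last 52 bases of intron 7 and the
first 16 bases of exon 8.  Clinical meaning depends entirely on phase: the
SNV in cis with the insertion is spliced out and benign, while the SNV on a
chromosome without the insertion is pathogenic.  Because the inserted copy
is ~96% identical to the adjacent reference sequence, reads carrying it
map poorly to a single linear reference: they soft-clip around the
breakpoints, the variant allele fraction at the SNV collapses, and callers
either drop the variant or miscall its zygosity (reference bias).

The package implements the customized-scaffolds answer to this problem, as
a complete, testable pipeline:

1. **`reference_model`** -- build a wild-type scaffold (`CBS_WT`, the
   unmodified 5000 bp region) and a mutant scaffold (`CBS_MU`, the same
   region plus the insertion allele) with an *engineered marker base*;
2. **`simulate_reads`** -- generate diploid paired-end reads for any
   genotype/phase combination;
3. **`align`** -- place every read on both scaffolds with a seed-and-extend
   affine-gap aligner that soft-clips;
4. **`genotype`** -- classify pairs competitively, pile up three
   informative sites, and resolve genotype and phase through a decision
   table;
5. **`cohort_stats`** -- carrier rates and Fisher's exact tests for the
   cohort comparison.

Throughout the package the CBS geometry is reproduced on a *synthetic*
5000 bp sequence (`cbs_synthetic_reference()`): the coordinates (duplicated
segment 3173--3240, insertion before 3173, SNV at 3184, marker at mutant
position 3210, cis readout at 3252 = 3184 + 68) and the forced bases at the
informative sites are those of the real locus; the rest of the base
composition is random with a fixed internal seed.  Real sequence can be
substituted through `build_scaffolds()`.

## Scaffold design

The mutant scaffold is `WT[1..3172] + copy + WT[3173..5000]`, where `copy`
is the duplication template with the allele's divergent bases applied and
one additional engineered change: the **marker**, at insertion offset 38
(mutant position 3210).  The natural base there (G) is conserved, so every
real insertion-bearing read covering the offset mismatches the scaffold
base (C) -- a predetermined variant call that cleanly flags the insertion.
Of the two tandem arrangements consistent with the endpoint coordinates,
only placing the divergent copy *first* puts the cis image of the SNV at
mutant position 3252 and the marker inside the inserted copy, so that
arrangement is fixed.

The exact offsets of the divergent bases of the real alleles are not
machine-readable from the source material, so the fixture parameterizes
them: the common allele diverges at insertion offsets {5, 30, 60}, the rare
allele adds {45}.  They are configuration, not constants -- real allele
sequences drop in without code changes.  Coordinates are 1-based, closed
intervals, plus strand everywhere; transcript-style (minus strand)
nomenclature appears only in documentation.

Insertions inside repeats admit several (position, sequence) descriptions;
`equivalent_insertion_descriptions()` resolves equivalence by applying both
descriptions and comparing the resulting allele strings, which is the
entire semantic content of the question.

## Alignment model

The aligner is deliberately small: an exact k-mer index (k = 15), seed
votes per diagonal, diagonal clusters extended by banded affine-gap local
DP (Gotoh) with free terminal soft clips, and deterministic tie-breaks
(higher score, lower reference start, smaller left clip, forward strand
preferred).  The production aligner behind the original workflow is
proprietary with unpublished parameters; the scheme here is chosen so the
*qualitative* behaviour that the method depends on is guaranteed:

* match +1, mismatch -4, gap open -6, gap extend -1, so a 68 bp gap costs
  -73 while four mismatches cost -16.  A read without the insertion never
  profits from opening the insertion-length gap; it aligns contiguously or
  clips.
* soft clips are free but clipped bases score 0, so junction-spanning reads
  clip at the breakpoints on the wild-type scaffold and align full length
  on the mutant scaffold -- the score difference that drives the
  competitive classification.
* the band half-width is `max(16, expected_indel) + 4` (72 when the
  expected indel is the 68 bp insertion).  This is wide enough that a
  single banded pass spans both copies of the duplicated segment and the
  full-length deletion path between them, which is what makes the banded
  score provably equal to the exhaustive full-matrix score in the test
  comparisons rather than merely close.
* placements aligning fewer than `min_anchor = 25` read bases are treated
  as unmapped.

Equal-best placements break ties to the lowest start deterministically; a
random non-specific assignment would also work because the downstream
pileup policy only consumes *cross-scaffold* score differences, but
determinism makes every result reproducible bit for bit.

A full-matrix, unseeded, unbanded reference implementation
(`align_full_score()`) ships alongside the heuristic; the test suite checks
the heuristic against it on reads drawn from both scaffolds and checks the
reference path itself against an independent external DP implementation.

## Pair classification and the pileup policy

Pairs are classified by summed mate scores: `MU_STRICT` iff
`score(MU) - score(WT) >= 1` (unmapped = -Inf), `WT_STRICT` symmetrically,
otherwise `TIE`.  Since the two scaffolds are identical outside the
insertion, a pair is strictly mutant exactly when it carries
insertion-specific evidence: a junction or a divergent base.  Because the
read length (150 bp) exceeds the insertion length (68 bp), every
insertion-allele read covering the marker necessarily spans a junction and
is strictly mutant -- the lemma the suite verifies over exhaustive start
positions.

Pileups at the three informative sites follow a competition policy:

* **Mutant sites (3210, 3252):** only strictly mutant pairs contribute,
  from their mutant-scaffold placements.  Consequently the marker fraction
  is exactly 1 whenever any haplotype carries the insertion (every
  strictly mutant read is an insertion read, and all of them carry the
  natural G against the scaffold C), and the marker depth is 0 otherwise.
  This is why a *heterozygous* marker state is anomalous by construction
  and yields `NO_CALL`.
* **Wild-type SNV site (3184):** every pair's wild-type placement
  contributes.
* In all policies, bases under soft clips are never counted, and a counted
  base must lie at least `edge_margin = 12` aligned bases from *both* ends
  of the read's aligned segment -- soft-clip edges and plain read termini
  alike.

The tail filter is the load-bearing design choice, so its derivation is
worth recording.  12 is the distance from the insertion breakpoint to the
SNV.  Reads from an insertion-bearing haplotype can deposit a base on
position 3184 of the wild-type scaffold in two ways: through the *first*
(inserted) copy -- those bases are reference-like (A) and sit deep inside
long aligned segments -- or through placements whose aligned segment starts
at the breakpoint image, where the cis G lands within 11 bases of the
segment edge.  An exhaustive windowed-coverage enumeration of 150 bp read
start positions shows that a 12-base end-distance filter removes *every*
junction-adjacent G while retaining the reference-like leak, so for
homozygous complex carriers the alternate fraction at 3184 is 0 (up to
sequencing error) and for the trans configurations it is 1/2.  A simpler
read-level filter (discard any placement clipped by 12 or more) was
evaluated first and rejected: the same enumeration gives an alternate
fraction of 23/91 at 3184 for homozygous complex carriers -- above the 20%
heterozygous threshold, i.e. a systematic miscall of that genotype as its
trans counterpart.  Filtering on the distance between the counted base and
the alignment end is also what established pileup callers do ("minimum
distance from the read end"), so the deviation is towards, not away from,
standard practice.  Bases below Phred 13 are additionally dropped, which
guards the 20%/80% thresholds against simulated sequencing errors.

## Zygosity and the decision table

Allele fractions map to zygosity states exactly as the lookup table
defines them: HET on [0.20, 0.80), HOM at >= 0.80, ABSENT below 0.20, and
`NOCALL_LOWDEPTH` below 15 counted bases (the workflow's minimum base
coverage).  The genotype is then a pure function of the signature triple:

| WT:3184 | MU:3210 | MU:3252 | call |
|---------|---------|---------|------|
| HET/HOM | quiet   | quiet   | SNV only (zygosity from 3184) |
| ABSENT  | HOM     | ABSENT  | insertion only |
| ABSENT  | HOM     | HOM     | complex variant (cis) |
| HET     | HOM     | ABSENT  | SNV in trans with insertion |
| HET     | HOM     | HOM     | SNV in trans with complex |
| ABSENT  | HOM     | HET     | insertion in trans with complex |
| ABSENT  | quiet   | quiet   | wild-type |

("quiet" = no countable strictly-mutant evidence: ABSENT, or no coverage
at all, which at the mutant-only sites is the normal state of
insertion-free samples.)  All other signatures -- 19 of the 27 state
combinations -- return `NO_CALL` with a reason.  Two deliberate
granularity limits: insertion zygosity is *not* resolved (heterozygous and
homozygous carriers of the same configuration share a signature, exactly
the granularity of the lookup table; an optional depth-ratio heuristic was
considered and left out as unvalidated), and the SNV-only class carries
its het/hom sub-state as a label.

`call_single_reference()` is the control arm: wild-type scaffold only, all
placements counted under the same base filters.  On complex carriers it
reproduces reference bias -- the alternate fraction at 3184 falls below
the calling threshold and the variant is missed -- while the dual-scaffold
readout at 3252 is undiminished.

## What the simulator does and does not emulate

`simulate_pairs()` reproduces the study's simulation conditions as
defaults: 200-fold coverage, 2 x 150 bp pairs, fragment length
Normal(300, 100) resampled into `[read_length, haplotype length]` (never
truncated, so mates cannot run off a fragment), uniform fragment starts, a
fair coin per fragment between the two haplotypes, and uniform per-base
substitution errors at 0.1% with the matching constant Phred quality
(Q30).  A profiled instrument error model is deliberately replaced by this
uniform model: the method's decisions depend on allele identity at three
interior sites, not on an error spectrum.  Not emulated: indel and chimera
errors, quality decay along the read, PCR duplicates (the workflow's
duplicate-removal step is a no-op here), capture/enrichment bias, and
contamination.  Passing tests therefore demonstrate the *logic* of the
method under realistic coverage and noise magnitudes, not its robustness
to instrument-specific artefacts.

Haplotypes carry the *natural* insertion allele -- the engineered scaffold
base never occurs in simulated molecules, which the suite asserts by
scanning error-free simulations.

## Problem sizes and numerical choices

The test suite runs each of the 7 genotype classes through the full
pipeline over 20 fixed-seed replicates at the default conditions (about
3,400 read pairs per sample) and requires the true genotype in all 140
runs; `scripts/acceptance.R` recomputes the same quantity with seeds
derived from a user-supplied seed.  Aligner equivalence is checked on
1,000 random error-free 150-mers against the full-matrix reference path
(and that path against an external implementation on a subsample); the
marker lemma is checked over every start position covering the marker.
Fisher's exact test uses the two-sided sum-of-smaller-probabilities
convention (all tables at the observed margins with probability at most
that of the observed table, relative tolerance 1e-7) via
`stats::fisher.test`, validated against a brute-force hypergeometric
enumeration; tables with a zero margin are defined to have p = 1.  Carrier
rates are carrier counts over cohort totals with 2-decimal half-up
rounding.  The packaged cohort fixture stores the printed counts verbatim;
four printed percentages are internally inconsistent with their own
printed counts and are flagged in the fixture's `note` column, with the
counts taken as authoritative.

## Limitations

* Phasing range is bounded by the read/insert length: the method phases
  variants that co-occur within a read pair's span, by design.
* Scaffolds must be built from a known allele: breakpoints, divergent
  bases and a conserved marker position are prior knowledge, making this a
  targeted assay, not a discovery method.
* Insertion zygosity within a configuration is undetermined (above).
* Deletion-type scaffolds would be a straightforward extension but are not
  implemented or exercised.
* Marker conservation (no natural polymorphism at the marker position) is
  the designer's responsibility; the builder checks geometry, not
  population genetics.
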