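---
title: "Methods: characterizing a two-library sheep miRNAome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing a two-library sheep miRNAome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheepmir)
```

## The analysis problem

Small RNA sequencing of sheep (*Ovis aries*) left ventricle (LV) and a
pooled multi-tissue "global" library (GL) yields, after detection with a
miRDeep2-class tool, a set of candidate hairpin precursors with their 5p/3p
mature forms, per-library read counts and per-precursor read stacks. This
package implements everything that happens *after* detection: deciding which
candidates to keep, tiering the survivors by evolutionary conservation and
naming them, characterizing arm usage, library specificity, genomic
clustering and chromosome density, classifying every read into the isomiR
taxonomy, and quantifying expression differences without replicates — plus a
stem-loop qRT-PCR relative-quantification step for wet-lab validation
panels.

Detection itself (the Bayesian hairpin scoring, read-signature filters,
secondary-structure prediction) and the BLAST alignment engines are out of
scope: candidate tables and homology hit tables are *inputs*, consumed
through a canonical TSV dialect defined by this package. The real detector's
mixed HTML/CSV output is deliberately not parsed; its content maps directly
onto the canonical columns.

## Data model and conventions

All intervals are 0-based half-open; BED is emitted natively and any GFF
output would convert at the writer boundary. T and U are interchangeable on
input; sequences are stored uppercase in U-form. Read counts are per-library
nonnegative integers; totals are always derived, never stored. The precursor
table holds one row per mature form with precursor-level columns repeated; a
read-stack table holds one row per read family with a 0-based start offset
on the precursor (negative for upstream overhangs) and a semicolon-joined
`pos:base` mismatch annotation.

## Retention filters

The score cutoff is the smallest detection-score threshold whose estimated
signal-to-noise ratio strictly exceeds 10:1, taken from a supplied SNR
table. Candidates are then dropped in a fixed order, each with one
deterministic reason:

1. **low_score** — novel candidates below the cutoff (known precursors are
   exempt from this rule only, having been validated before);
2. **low_count** — no mature form reaches 10 reads *in total across
   libraries*. The source narrative does not say whether the floor was
   pooled or per-library; pooled is the default and the per-library rule is
   what the presence/expression analyses apply anyway;
3. **repeat** — more than five genome self-hits at E < 2e-08 on distinct
   genomic areas. "Distinct areas" is operationalized by parsing
   `chrom:start-end` subject ids and merging overlapping intervals;
   unparseable subject ids each count once;
4. **other_ncrna** — any Rfam/RefSeq-RNA hit at E < 2e-08 (snRNA, snoRNA,
   tRNA look-alikes). No separate threshold is stated for this screen, so
   the repeat-screen threshold is reused; both screens belong to the same
   step.

The fixed order makes the kept/dropped partition reproducible and gives
every dropped candidate exactly one reason.

## Conservation tiers and nomenclature

Candidates are tiered from miRBase homology hits: **conserved_broad** needs
hits from at least 5 species at E < 4e-09; **conserved_narrow** needs 2–4
species at E < 9e-05; **conserved_single** needs exactly one species at
E < 2e-04 (this bucket holds both distant single-species homologs and the
*Bos taurus* miR-2284/2285 family); everything else is **nonconserved**. The
narrow tier is restricted to 2–4 species so the three conserved tiers are
mutually exclusive — a plain "<5 species" reading would overlap the
single-species class.

Conserved candidates are named after their closest homolog mature. The
similarity score is an ungapped best-offset comparison weighting seed
matches (mature positions 2–8, the conventional seed window) double:
`2 x (seed matches) + (other matches)`. This scorer is deliberately simple,
documented and isolated so an alignment-based scorer could be swapped in.
Name collisions resolve deterministically: same proposed name with
*different* matures → progressive letters (a, b, …) in genomic-coordinate
order; *identical* matures from distinct precursors → `-1`, `-2` suffixes.
Nonconserved candidates get provisional `oar-miR-N1 … Nk` names in
coordinate order, with identical-mature groups sharing one number
(`oar-miR-N14-1`, `oar-miR-N14-2`). Because all tie-breaks are
coordinate-based, naming is injective and invariant under input
permutation.

Families are derived from names by stripping the species prefix, arm
suffix, duplicate `-1/-2` suffix and trailing paralog letters.

## Arm preference, specificity, clusters, density

An arm is *expressed* in a library at ≥ 10 reads. The narrative uses
"> 10 read counts" in one place and "below 10" (i.e. keep ≥ 10) in the
filtering step; the ≥ 10 reading is the default for consistency with
filtering, and a strict-greater option exists. The *dominant* arm has the
strictly greater count; an exact tie goes to 5p (documented as arbitrary;
5p is the majority product in this data set). An *arm switch* is flagged
when both libraries have a dominant arm and they differ.

A precursor is *present* in a library when any mature form reaches the
floor; present precursors partition into LV-only / GL-only / both.

Clusters chain precursors sorted by (chromosome, strand, start) while the
gap from the running envelope end to the next start is below 10 kb; maximal
chains of ≥ 2 are clusters. Measuring from the running maximum end (rather
than literally the previous row's end) makes the chains equal to the
transitive closure of the pairwise boundary-gap relation even when
precursors overlap or nest, which is what chained multi-member clusters
require; for non-overlapping precursors the two readings coincide. The gap
is boundary-to-boundary (end → start), the stricter conventional reading of
"inter-miRNA distance".

Chromosome density is miRNAs per Mbp, reported unrounded along with a
2-decimal rendering.

## IsomiR taxonomy

Every read overlapping a mature form is classified into exactly one of
eight categories. End offsets are taken relative to the mature interval; an
*extension* end is non-templated iff at least one extending base differs
from the precursor (or falls off it) — truncations and shifts within the
precursor are always templated. Internal mismatches against the precursor
body (never extension bases) are substitutions. Precedence: substitutions →
`polymorphic`; both ends variant → a both-ends category (non-templated if
*either* end is, a conservative collapse of mixed cases); one end variant →
the corresponding templated/non-templated 5'/3' category; else `reference`.
Polymorphic takes precedence so the categories are exclusive and their
fractions sum to one, matching how such distributions are reported. A read
is seed-affected iff its 5' end is shifted or a substitution falls in
positions 2–8. Loop/star-only reads are excluded from distributions and
counted separately.

Mismatches are derived by direct read-to-precursor comparison rather than
trusting the annotation column, so corrupt annotations cannot change calls;
the test suite holds an independent per-base oracle against this
implementation.

Dominant forms rank variants (unique start + sequence) by summed count
across libraries, breaking ties in favor of the reference and then the
lexicographically smallest sequence.

## Quantification

Size factors are the median-of-ratios estimator: for library *j*, the
median over all-positive features of count divided by the feature's
geometric mean across libraries — the no-replicate normalization of the
DESeq family, re-implemented here and cross-checked in the tests against
the independent reference implementation. Fold change is the ratio of
normalized counts with no pseudocount by default (a configurable one exists
for degenerate inputs); zero numerators give 0 and zero denominators are
flagged infinite. Only normalization and fold change are implemented — the
dispersion model and significance testing are out of scope because only
fold changes are reported in this design.

qRT-PCR assays are called expressed at Ct strictly below 35, and relative
quantity is `2^-dCt` against the U6 snRNA control. Only the per-assay dCt
against U6 is implemented; a per-sample mean-dCt variant is mentioned in
the source protocol but not specified enough to reproduce.

Percentage renderings deserve a note: the read-accounting percentages in
the study's tables follow truncation (52.3969% prints as 52.39), while
densities and per-chromosome means follow rounding; `percent_of()` exposes
both conventions.

## The synthetic scenario: what it emulates and what it does not

The generator is first-class, tested code. Its defaults *are* the study
conditions: 172 novel precursors split 12/76/84 across LV-only / GL-only /
both (19/115/130 matures via two-mature quotas), conservation tiers
112/10/29/21, 13 duplicate-mature pairs, 7 planted clusters holding 17
precursors, 100 known precursors (85 shared), 27 chromosomes, isomiR
proportions near the pooled observed distribution (reference 0.575,
templated 3' 0.18, non-templated 3' 0.105, polymorphic 0.085, templated 5'
0.05, rare remainder), a 90.93% fraction of mappable reads in 18–24 nt,
5p-dominance weights 0.6421 (LV) / 0.5398 (GL) with a 5/84 switch rate, and
one decoy per retention rule class (3 low-score, 3 low-count, 4
repeat-like, 6 other-ncRNA — the 4 + 6 mirroring the ten candidates the
conservation screens removed). Where the study states no value, defaults
were chosen once as field-realistic: read depths lognormal with meanlog
log(150) and sdlog 1 (floored at the presence threshold), chromosome
lengths spanning 275–40 Mb, non-templated addition alphabet weighted
A 0.5 / U 0.3 / C 0.1 / G 0.1 (3' adenylation and uridylation dominate
non-templated additions in animals), hairpins 70–90 nt with an 85%
reverse-complement bias between arms.

Reads are *forward-edited* from the reference mature (templated edits copy
precursor bases; non-templated additions draw from the alphabet excluding
the templated base; polymorphic reads substitute one internal base), so the
mismatch annotations and per-read category labels are exact by
construction and downstream recovery can be checked exactly for discrete
truth (classes, tiers, clusters, pairs, drop reasons) and within sampling
error for proportions.

What the generator does **not** emulate: sequencing error and quality
scores, adapter artifacts, multi-mapping reads, true secondary structure
(the hairpin bias is cosmetic), inter-mature count correlation structure,
and per-library isomiR proportion differences (one multinomial serves both
libraries). Passing tests therefore demonstrate correctness of the
*analysis logic* under realistic data shapes, not robustness to raw-data
artifacts that the upstream detector is responsible for absorbing.

Because arm dominance is sampled with per-precursor weights rather than
planted as a quota, the recovered 5p-dominance percentages are stochastic
with a standard deviation of several points at n ≈ 96–160 precursors; they
are reported as computed, not forced to the study's 64.21% / 53.98%.

## Problem sizes and determinism

The default scenario holds 288 candidate precursors (172 novel + 16 decoys
+ 100 known), roughly 4,000 read families carrying ~160,000 reads, and a
10,000-read length sample — large enough that multinomial fractions recover
within three standard errors, small enough that the full pipeline runs in
well under a minute on one core. Unit and property tests use a reduced
scenario (9 novel precursors) for sub-second feedback. Every random draw in
a simulation flows from the single integer seed in its configuration;
identical seeds give byte-identical output files.

## Known limitations

* Known-precursor isomiR and cluster behaviour is generated but not given
  bespoke quotas; the study's large known cluster on chromosome 18 has no
  planted counterpart.
* The naming scorer is intentionally minimal; heavily diverged homologs
  could be named after the wrong family member. It is isolated behind
  `seed_similarity()` for replacement.
* The source tables carry internal inconsistencies (a conservation
  partition whose prose and table disagree; one printed percentage that
  does not equal its own ratio). The package reproduces the table-shaped
  partitions and reports raw ratios; it does not attempt to reconcile the
  inconsistent prose figures.
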