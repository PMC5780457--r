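---
title: "Methods: mutation characterization for radiation mutagenesis cohorts"
author: "radmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation characterization for radiation mutagenesis cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmut)
```

## The analysis problem

Heavy-ion (high-LET) mutagenesis experiments in plants re-sequence small
cohorts of M2 plants — the self-pollinated progeny of irradiated material —
and characterize the induced mutations: how many per genome, of what kind
(substitutions versus deletions, insertions, complex events), in what
sequence context, and with what functional consequence.  `radmut`
implements that characterization as a tested pipeline over standard file
formats (FASTA, VCF with `AD`/`DP` genotype fields, GFF3), together with a
synthetic mutagenesis simulator that generates cohorts with known ground
truth so every stage can be validated without sequencing data.

## Filtering and zygosity model

Candidate per-sample calls are filtered with cohort-level rules that
exploit the expected allele-frequency (AF) structure of an M2 plant:

* **read support** — a candidate needs at least 3 mutant reads;
* **AF exclusion** — calls at AF ≤ 0.25 are removed as unreliable
  (`low_af` in the audit trail).  Heterozygous mutations concentrate near
  AF 0.5, so a call at or below 0.25 is more likely an artifact than a
  genuine heterozygote;
* **zygosity bands** — heterozygous for AF strictly inside (0.25, 0.80),
  homozygous for AF ≥ 0.80 (ties at 0.80 are homozygous);
* **cross-sample independence** — a genuine induced mutation is private to
  one plant; the call is excluded if any other sample shows AF ≥ 5% at the
  same site and allele (`cross_sample`);
* **background removal** — a site+allele present above 5% AF in more than
  two samples is a shared artifact or pre-existing variant and is removed
  from every sample.

Exclusion at AF ≤ 0.25 and the ">25%" lower edge of the heterozygous band
are one rule here, applied as a single inclusive threshold.  If a policy is
configured with a gap between the exclusion ceiling and the het band, calls
falling in the gap are excluded with their own `af_gap` trace rather than
silently dropped.  The cross-sample check uses the AFs present in the
cohort's call sets; sites absent from another sample's calls count as 0%
for that sample, a documented limitation when calls (rather than raw
pileups) are the input.  Note that the background rule keeps a site shared
by exactly two samples, but the cross-sample 5% rule then excludes both
calls during zygosity assignment; the two rules are deliberately distinct
stages with distinct audit traces.

All thresholds live in `filter_policy()` and can be loaded from YAML/JSON.

## Event merging and the seven categories

Calls are normalized first: shared prefix/suffix bases are trimmed (keeping
one anchor base for indels) and indels are left-aligned by iterated
shifting.  Left alignment is the VCF community convention; the context
detectors are defined so their calls do not depend on the incoming
alignment dialect.  A deletion's reported position is its first deleted
base after normalization.

Normalized calls on one chromosome of one sample are merged into a single
*complex* mutation event when their reference footprints are separated by
fewer than 10 unmutated bases (gap ≤ 9), restricted to constituents shorter
than 50 bp — a large deletion never joins a complex event.  Two or more
immediately consecutive substitutions likewise form one complex event; a
di-nucleotide substitution arriving as a single multi-base record is
classified the same way.  Runs of at least two reference-matching bases
between constituents are recorded as unmutated separators inside the event;
they describe the event's internal structure and never re-split it.  When
merged constituents disagree on zygosity the event is flagged
`mixed_zygosity` and reported heterozygous, the weaker claim.

Each event lands in one of seven categories — SBS, single-base deletion,
multi-base deletion, single-base insertion, multi-base insertion, complex,
SV — with size measured by *net* length: a 10-base deletion accompanied by
a 3-base insertion is a 7-base deletion.  Symbolic SV records pass through
unmerged and are excluded from all frequency comparisons.  Deletion sizes
bin as 1, 2–9, 10–49, ≥ 50 bp; complex events with net deletions are not
binned.

## Sequence context of indels

Three signatures are annotated on single-call indel events (complex and SV
events carry no context annotation, since no per-event rule applies to
them):

* **homopolymer** — the changed segment is a run of one base and its union
  with identical flanking reference bases reaches 3 bp; the run is counted
  including the flanks, because the biological claim is that the indel sits
  *in* a homopolymeric tract.
* **polynucleotide repeat** — a tandem run (unit 2–6 bp, ≥ 2 exact copies,
  period-1 excluded) spans a breakpoint of the indel.  Anchoring to the
  breakpoints matters: an incidental repeat buried deep inside a multi-kb
  deletion says nothing about how the ends were joined, and with a
  footprint-overlap definition essentially every large deletion would be
  flagged.  For insertions the inserted sequence is spliced in first, so a
  tandem duplication is recognized.
* **junction microhomology** — for a deletion of segment *D* with upstream
  flank *U* and downstream flank *W*, the homology length is
  max(longest common suffix of *U*,*D*; longest common prefix of *D*,*W*),
  capped at 10 bp and the segment length; insertions substitute the
  inserted sequence for *D*.  The default flagging threshold is 2 bp: at
  1 bp, random sequence flags ≈ 1 − (3/4)² ≈ 44% of junction pairs by
  chance, which would swamp the signal.  The threshold is exposed in the
  API for sensitivity analyses.

For mutually exclusive summaries a priority (homopolymer > repeat >
microhomology) defines a primary label, but the summary tables report the
homopolymer and repeat-or-microhomology columns non-exclusively, as is
conventional for this kind of table.  Single-base indels are additionally
classed as A/T- or G/C-site events.

## Gene impact

Gene models come from GFF3 (first-listed transcript per gene; pseudogenes
and transposable-element genes skipped).  Substitutions in CDS are
translated codon-wise on the gene's strand (synonymous / nonsynonymous /
stop-gain / stop-loss); CDS indels are frameshift unless the net length is
a multiple of three; a deletion spanning a gene's entire CDS deletes the
gene, one record per gene lost.  Intron/UTR/intergenic effects are all
"noncoding": the target statistic counts genes with non-synonymous
amino-acid changes, and loss-type changes (frameshift, stop-gain,
gene-deleted) are included in that count.  Per sample, a gene counts once;
a gene hit both heterozygously and homozygously is tallied under the
homozygous (stronger) state and flagged.  Group summaries are mean ±
standard error (sd/√n over samples).

## Group statistics

* **Mutation frequency** — events (SV excluded, complex events once) per bp
  of reference per sample; group mean ± SE.  Because all samples share the
  genome-length denominator, the mean of per-sample MFs equals
  total/(n·L) exactly, which the tests assert.
* **Spectrum** — the 12 directed substitutions collapse to 6
  complementary-merged classes; Ti/Tv is (G:C→A:T + A:T→G:C) over the four
  transversion classes.
* **Zygosity** — per-sample het:hom ratios; a sample with zero homozygous
  events has an undefined ratio, is flagged, and is excluded from the group
  mean (a finite summary requires finite ratios).  The Mendelian M2
  expectation is 2.0 — each M1 heterozygous mutation segregates 1:2:1 and
  the homozygous wild type is undetectable — and the group mean is tested
  against it with a one-sample t-test.
* **Comparisons** — two-sample Welch t-tests on per-sample MFs (a
  pooled-variance flag is available) and Pearson chi-squared homogeneity
  tests (no continuity correction) on category, spectrum and deletion-size
  tables, for every pair of groups; expected counts below 5 are flagged in
  the output rather than suppressed.  No multiple-testing correction is
  applied; raw p-values are reported.
* **Derived rates** — M1 frequency is 4/3 of the M2 estimate (the
  homozygous wild-type quarter of each segregating locus is invisible in
  M2), compared against a spontaneous rate of 7.1 × 10⁻⁹/bp; per-locus
  frequency from a phenotype screen is mutants/(plants × loci), scaled by
  the genome's protein-coding gene count to give expected disrupted genes
  per plant.
* **Survival fitting** — the single-hit multitarget model
  S(D) = 1 − (1 − e^(−D/D0))^n is fit by Levenberg–Marquardt least squares
  (`minpack.lm`), with starting values from a log-linear fit to the
  exponential tail (ln S ≈ ln n − D/D0) and a fallback start grid; the
  shoulder dose is Dq = D0 ln n.  The fit is exercised on synthetic
  dose–response curves; parameter recovery under 1% noise is part of the
  test suite.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` builds a reference genome (i.i.d. bases with optional
homopolymer enrichment via a copying Markov chain that preserves base
composition), writes translatable gene models into it, plants ground-truth
mutations, and emits noisy per-sample VCFs plus a truth table.

The built-in group profiles are calibrated to a carbon-ion mutagenesis
cohort of 4 groups × 6 M2 plants: per-sample expected category counts of
roughly 12–16 substitutions, 4–12 multi-base deletions and 2–3 complex
events for dry-seed-like groups versus substitution-dominated seedling-like
groups; deletion sizes drawn from the 2–9 / 10–49 / ≥ 50 bins with
dry-seed-like weights 80:40:9 and seedling-like 19:19:6; context planting
fractions of 45–50% homopolymer for single-base deletions and 43–49%
repeat-or-microhomology for multi-base deletions (76% for multi-base
insertions); and 1:2:1 Mendelian zygosity (het with probability 2/3 among
detectable genotypes), applied independently per mutation since events are
treated as unlinked.  Substitution class weights are chosen qualitatively
(G:C→A:T dominant; an elevated A:T→T:A share in the dry-seed-like profile)
because only the class ranking, not per-class counts, is printed in the
source material; they are not a quantitative target.

Read evidence is binomial: depth ~ Poisson(33) floored at 10, mutant reads
Binomial(depth, 0.5) for heterozygous and Binomial(depth, 0.98) for
homozygous calls — 0.98 rather than 1.0 so the AF ≥ 0.8 homozygous rule
retains a meaningful error margin.  Noise consists of low-AF false
positives (AF ≤ 0.25, ≥ 3 reads, ~2 per sample), optional near-threshold
false positives at AF in (0.25, 0.30] to probe the documented residual
false-positive risk just above the exclusion rule, and background artifact
sites injected into more than two samples.  All randomness flows from one
integer seed; identical seeds reproduce byte-identical truth tables and
VCFs.

Context planting is constructive: a homopolymer single-base deletion
removes a base from a real run ≥ 3; a repeat deletion removes one exact
copy of a tandem unit; a microhomology deletion is placed where the deleted
prefix matches the downstream flank.  "None" events are rejection-sampled
to carry no signature *and* zero suffix homology with the upstream flank,
so their placement is already left-aligned and the planted truth is exactly
what the detectors see after normalization — planted and recovered context
labels then correspond deterministically, and recovered fractions differ
from the profile fractions only by the planting Bernoulli noise.  Mutations
are kept ≥ ~55 bp apart across the whole cohort (complex constituents
excepted); this makes category recovery unambiguous and also avoids the
cross-sample position collisions that a sub-megabase toy genome would
otherwise produce far more often than a real 119 Mb genome.

What the simulator does **not** emulate: read mapping and alignment
artifacts, base-quality structure, depth heterogeneity along the genome,
linked mutation clusters from single particle tracks, SV breakpoint
structure, or chromatin/dose physics.  Passing recovery tests therefore
validates the pipeline's logic on calls with the assumed AF structure, not
robustness to upstream calling errors in real data.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere inside the package;
  conversions happen only at format boundaries.
* Percentages in summary tables are rounded to integers and MF is
  displayed to one decimal in units of 10⁻⁷/bp, matching the conventional
  reporting precision; raw values are always retained.
* The merge gap ("fewer than 10 bases") is merge iff gap ≤ 9 unmutated
  bases, counted strictly between reference footprints; an insertion's
  footprint is its anchor base.  Footprint distance, not point distance, is
  used for indels.
* "More than two consecutive SBSs" is read as "two or more": a
  di-nucleotide substitution is a single complex event, not two independent
  substitutions; the threshold is configurable in the policy.
* Mixed deletion+insertion records are classified by net length and are
  not re-left-aligned beyond prefix/suffix trimming (their placement is
  representation-dependent in general; none are produced by the simulator).
* Problem sizes in the test suite — 0.4–1.2 Mb genomes, cohorts of 12–24
  samples, 100 replicate cohorts for the detection-power check, 10⁵ draws
  for the Mendelian ratio — were chosen so the full suite completes in a
  few minutes while keeping Monte-Carlo error well inside the asserted
  tolerances.
* Dose–response fitting rejects degenerate input (all survival ≈ 1) rather
  than returning an unidentifiable fit.

## Known limitations

* The cross-sample 5% check sees only called sites, not pileups (above).
* Effect prediction uses one transcript per gene and ignores splice-site
  disruption; in-frame indels are called nonsynonymous without checking
  for created stops.
* Complex events receive no context annotation and net-deletion complex
  events are excluded from the deletion-size histogram.
* Repeat and microhomology definitions (unit range 2–6, ≥ 2 copies,
  ≥ 2 bp homology) are conventions exposed as parameters; published
  context proportions are reproduced as constructed-count checks, not
  re-derived from raw data.

## Reproducing the headline numbers

`scripts/acceptance.R --seed N --out results/acceptance.json` re-runs the
package's Mendelian segregation simulation (10⁵ mutations) and writes the
resulting het:hom ratio; the test suite (`testthat`) covers everything
else, from printed-table arithmetic to full-cohort recovery.
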