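---
title: "cfFrag: methods and design notes"
author: "cfFrag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfFrag: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfFrag)
```

# Scope

cfFrag extracts fragment-level features from paired-end sequencing of
cell-free DNA (cfDNA): fragment-length distributions, fragment end motifs,
per-fragment mutation-overlap categories against a priori variant loci,
stratified 96-context single-base-substitution (SBS) profiles, simplified
binned copy-number states, and descriptive alignment-file metrics. Because
real cfDNA data cannot ship with the package, it also contains a synthetic
paired-end alignment generator with exhaustive ground truth, which is how
every caller is verified.

This vignette documents the statistical model behind each module, the
default parameters and their rationale, and the known limitations.

# Fragment reconstruction

## The cfDNA fragment and why "TLEN" is not enough

A cfDNA molecule is sequenced as a read pair; the molecule's genomic
interval is reconstructed as

* start = leftmost aligned position of the **forward-strand** read,
* end = rightmost aligned position of the **reverse-strand** read,

in 1-based closed coordinates, so `length = end - start + 1`.

Short cfDNA fragments are frequently *sequenced through*: each read is
longer than the molecule and runs past the opposite end, where adapter
trimming is imperfect and a soft-clipped or aligned *overhang* can remain.
The naive "outermost aligned boundary" span (returned by
`problematicLength()` for diagnosis) then overestimates the molecule by
exactly the overhang length. The strand-aware definition above is immune
to this, because the forward read's start and the reverse read's end are
the true molecular boundaries regardless of how far each read runs past
the other end.

## QC and curation policy

`readBam()` streams a queryname-grouped view of the file in chunks
(`yieldSize` records at a time, with leftover mates carried between
chunks, so results are identical to reading the whole file at once) and
applies two ordered filter stages. Each pair is rejected by the *first*
rule it violates, which makes rejection counts well defined:

QC stage (`qcPolicy()`):

1. `UNMAPPED` — either read unmapped.
2. `MAPQ` — either read below `minMapq` (default 30).
3. `DUPLICATE` — PCR/optical duplicate flag.
4. `SECONDARY` — secondary alignment flag.
5. `SUPPLEMENTARY` — supplementary alignment flag.
6. `PROPER_PAIR` — only if `requireProperPair = TRUE`. This is **off by
   default**: aligners define "proper" against an insert-size model
   trained on genomic DNA, and genuinely short or long cfDNA fragments —
   often the biologically interesting ones — fail it.

Curation stage (`curatePairs()`):

1. `SEQNAME_DISCORDANT` — mates on different contigs.
2. `NO_STRAND` — mates on the same strand (no forward/reverse pair).
3. `NOT_INWARD` — forward read starts after the reverse read ends; no
   molecule is consistent with such a geometry.
4. `OUT_OF_BOUND` — reconstructed interval leaves the contig.

`rejectionCounts()` reports every category, `pairsIn()` the pairs seen,
and `orphanCount()` reads whose mate never appeared.

# Fragment lengths

`callLength()` tabulates curated fragment widths inside a window (default
50–450 bp, chosen to span sub-mono-nucleosomal to di-nucleosomal lengths
while excluding artifactual extremes) and reports counts, fractions, and
fractions in conventional ranges. Cohort-level helpers
(`medianLengthProfile()`) take per-sample medians so no single deep sample
dominates.

# End motifs

`callMotif()` reports k-mer tables at four anchor points, all read from
the **reference forward strand** (not the read sequence, so sequencing
errors do not leak into motif space):

* `u` — k bases upstream of the fragment start,
* `s` — first k bases of the fragment,
* `e` — last k bases of the fragment,
* `d` — k bases downstream of the fragment end.

Tables are indexed by the full lexicographic 4^k motif set; windows
containing `N` (or running off the contig) are excluded and counted in
`excludedCount()`. Fractions are computed over included fragments only.

# Mutation overlap: CO / SO / DO

For a set of a priori SNV loci, `annotateMutations()` classifies every
curated fragment that *geometrically* covers a locus:

* `CO` (concordant overlap) — both reads cover the locus and both show
  the alternate base.
* `SO` (single-read overlap) — exactly one read covers the locus and it
  shows the alternate base.
* `DO` (discordant overlap) — both reads cover the locus and they
  disagree; evidence consistent with sequencing or PCR error on one
  strand.
* `REF_ONLY` — every covering read shows the reference base.
* `NO_COVER` — the fragment spans the locus but *neither read* covers it.
  This can only happen for fragments longer than twice the read length,
  where a middle gap is never sequenced. Keeping the category explicit
  makes the classification total and keeps such fragments out of depth.

Base calls come from a CIGAR-aware walk of each read (minimum base
quality 20). `aggregateSupport()` turns per-fragment categories into
per-locus counts; discordant fragments can be included in or excluded
from the alternate count (`includeDiscordant`), which is the basis of the
signature-sharpening analysis below.

# Stratified SBS profiles

`sbsContext()` maps each variant to one of the 96 pyrimidine-centric
trinucleotide contexts (purine reference bases are reverse-complemented).
`callTrinucleotide()` accumulates context counts per stratum (`ALL`,
`CO`, `SO`, `DO`, `CO_SO`), weighting either per fragment or per locus.
`sbsSubtract()` computes count-space differences (clipped at zero), and
`cosineSimilarity()` compares profiles. The intended use: DO events are
enriched for artefactual calls, so subtracting the DO profile from the
ALL profile moves the result closer to the true mutational signature.

The pileup in `pileupMismatches()` is hand-rolled rather than delegated
to a generic pileup engine because it must be *fragment-aware*: the two
reads of one molecule are one observation. Overlapping mates that agree
are counted once (a double-count guard), and mates that disagree remove
the molecule from the mismatch numerator and denominator instead of
contributing a spurious half-error.

# Simplified copy number

`binFragments()` assigns each curated fragment to a fixed-width bin
(default 1 Mb) by its **midpoint**, so every fragment lands in exactly
one bin and counts are conserved. `gcCorrect()` computes per-bin
reference GC, groups bins into GC deciles, and rescales each decile by
(global median)/(decile median); deciles with fewer than 3 bins or a zero
median are excluded rather than corrected by an unstable factor, and
inputs with fewer than 20 usable bins are refused. `callStates()` takes
log2 ratios against the autosomal median of corrected counts and calls
`gain`/`loss` at ±0.2 (≈ one copy in a diploid background at moderate
tumor fraction, and comfortably outside Poisson noise at ≥1,000
fragments per bin).

# Alignment metrics

`summariseBam()` reports, over primary alignments only: total reads,
unmapped fraction, mitochondrial read fraction (mapped mito / mapped
primary), mean coverage (aligned bases / genome length), and mismatch
fraction from NM tags. `downsampleBam()` subsamples *pairs* (a seeded
uniform draw over unique query names, so mates are kept or dropped
together and output is byte-identical for a given seed).

# The synthetic generator

`simConfig()` + `simulateDataset()` produce a FASTA reference, a sorted
indexed BAM, and a `TruthTable` with per-fragment and per-locus ground
truth. Design choices:

* **Lengths** come from a Gaussian mixture, by default
  0.7·N(167, 10) + 0.2·N(334, 20) + 0.1·N(90, 15), clipped at 30 bp —
  mono-nucleosomal, di-nucleosomal, and short sub-nucleosomal components.
  Within each component, lengths are a **stratified quantile grid**
  (`round(qnorm((i - 0.5)/n, mean, sd))`, randomly permuted) rather than
  iid draws: the realized spectrum then matches the mixture shape to
  within one count per length, so planted features such as the 167 bp
  mode are reproduced for any seed instead of being at the mercy of
  adjacent-bin sampling noise.
* **Artifacts** (duplicates, low MAPQ, secondary, unmapped,
  discordant-chromosome, outward-facing) are planted as **exact counts**
  (`round(rate · n)`), not Bernoulli draws, so tests can assert equality
  rather than approximation. Outward pairs are emitted with diverging
  read spans, since a strand swap alone is undetectable when the two read
  intervals overlap. Discordant-chromosome mates are placed on non-mito
  contigs so the planted mitochondrial fraction stays exact.
* **Mito fraction** is an exact fragment count on `chrM`.
* **Motif bias** uses rejection sampling of fragment start positions
  against the reference base, so the planted start-base distribution is
  the stated multinomial.
* **Variant spikes** choose carriers as an exact count among
  *read-covering* fragments (`round(vaf · n_covering)`), and discordant
  carriers as an exact count among both-read-covering carriers; the truth
  table records the planted CO/SO/DO/REF_ONLY/NO_COVER category per
  fragment × locus.
* **CNV regions** multiply placement weight inside the region.
* **Sequencing errors** are iid substitutions at `substitutionErrorRate`
  on read bases outside spiked loci.
* Reference synthesis, fragment simulation, and read emission use
  separate child seeds derived from the master seed, so each stage is
  independently reproducible.

Problem sizes in the test-suite (e.g. 50,000 fragments for length-mode
recovery, 80,000 for variant depth ≥ 200 per locus, 100,000 over a 50 Mb
contig for CNV) are the package's own choices, made so that statistical
assertions sit several standard deviations away from their thresholds.

## Generator realism limits

The generator is a verification instrument, not a cfDNA simulator:
reference sequence is iid with a target GC (no repeats, no mappability
structure); placement is uniform outside CNV regions (no nucleosome
positioning); base qualities are constant; duplicates are flag-planted
rather than re-sampled molecules; and no indels, clips (other than
overhang), or structural variants are emitted.

# Numerical conventions

* Coordinates are 1-based closed internally (GRanges convention);
  `readFragTSV()` ingests 0-based half-open tables and converts.
* Statistical test tolerances in the test-suite are 3 binomial standard
  deviations of the planted proportion — wide enough to be stable across
  seeds, tight enough to catch systematic errors.
* Motif and SBS tables are always full-length (4^k and 96) with explicit
  zeros, so profiles are directly comparable across samples.
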