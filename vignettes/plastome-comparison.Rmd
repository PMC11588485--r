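---
title: "Methods: comparative plastome analysis with plastcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis with plastcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcompare)
```

plastcompare implements the standard comparative workflow for annotated
chloroplast genomes: quadripartite structure and junction comparison, perfect
microsatellite (SSR) mining, codon usage and RSCU, alignment-based diversity
statistics including a sequence-variability (SV) hotspot index, and a
SNP-based distance phylogeny.  This vignette is the package's account of the
methods: the models and conventions behind each stage, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices that matter for reproducibility.

## The quadripartite model and IR detection

A typical plastome is a circular molecule of roughly 120–170 kb carrying two
identical inverted-repeat copies (IRA, IRB, ~20–28 kb each) that separate a
large and a small single-copy region (LSC ~80–90 kb, SSC ~16–27 kb).
`detect_inverted_repeats()` finds the IR pair with no external annotation:

1. every k-mer of the sequence (k = 25 by default) is matched against the
   k-mers of the reverse complement; a match at positions (i, j) means the
   k-mer starting at i is the reverse complement of the one starting at j;
2. seeds from one IR pair share the anti-diagonal `(i + j) mod n`, so seeds
   are clustered per diagonal and each cluster is extended greedily outwards
   while the reverse-complement identity holds (hyper-abundant, i.e.
   low-complexity, seeds are masked; extension recovers boundaries through
   them);
3. the maximal-length disjoint pair wins; an exact tie is broken toward the
   smaller start coordinate with a warning.

The default `max_mismatch_frac = 0` demands exact reverse complements,
matching the identical IR lengths real congeneric plastomes display; a
nonzero value relaxes extension to a bounded mismatch fraction.  If no
repeat of at least `min_ir_len` (default 1000 bp) exists the function raises
a classed `no_ir_found` error rather than fabricating a partition — IR-loss
lineages exist and deserve an explicit signal.

The single-copy segment lengths decide LSC vs SSC; IRA is the copy
immediately downstream of the SSC.  Junctions are named JSA (SSC/IRA), JLA
(IRA/LSC), JLB (LSC/IRB) and JSB (IRB/SSC), and the partition is reported in
the record's own rotation — lengths, not coordinates, are rotation-invariant,
and the tests assert exactly that.  `junction_report()` gives, per junction,
the nearest gene on each side with its distance, or the spanning gene with
its two overhangs, the tabular equivalent of the usual junction figure.

## SSR mining conventions

`find_ssrs()` reports perfect tandem repeats of unit length 1–6 under four
conventions that together make the locus set well-defined (and let an
exhaustive brute-force scanner verify it exactly):

* **maximality** — a locus sits at a maximal periodic run; one more unit on
  either side breaks the tandem;
* **whole copies, left-aligned** — the locus starts where the run starts and
  spans `copies × unit_len` bases;
* **smallest period** — a run like `ATATATAT` is one dinucleotide locus,
  never a tetranucleotide one (motifs must be primitive);
* **strand-specific motifs** — `A` vs `T` runs and `AT` vs `TA` repeats are
  distinct motif types, as SSR studies conventionally count them; no locus
  spans an `N`.

The default threshold is a total tract length of 10 bp for every unit size;
combined with the whole-copy rule this yields the familiar minimum copy
numbers (10/5/4/3/2/2 for mono–hexa).  Published SSR totals depend on the
exact thresholds of the mining tool used, so absolute counts are only
comparable under identical settings — the thresholds are therefore fully
configurable.  Length bins follow the conventional ten groups 10 bp apart
(10–20, 21–30, …, 81–90, >91); as printed the groups leave 91 bp unassigned,
so the top bin is implemented as ≥91.  Context annotation assigns the region
by locus midpoint and the genic context by overlap with priority
CDS > intron > tRNA > rRNA > intergenic (rRNA is not part of the classical
four-way summary but plastomes contain rRNA genes; loci there are labelled
honestly rather than forced into a wrong class).

## Codon usage and RSCU

`count_codons()` counts frame-0 codons, including stops, across the supplied
CDS; out-of-frame tails are dropped with a warning and codons containing `N`
go to an `ambiguous` bucket.  RSCU is the observed count divided by the mean
count of the codon's synonymous family, so each family sums to its size and
averages 1.  Classification uses the conventional thresholds: RSCU > 1.6
overrepresented, > 1 high-frequency, < 0.6 underrepresented; members of a
family never observed are reported as RSCU 0 / normal, while a zero-count
codon inside an observed family is genuinely underrepresented.  The standard
genetic code is used (for plastid CDS the bacterial-style table differs only
in start-codon treatment, which does not affect counting).  Amino-acid
frequencies exclude stop codons from the denominator.  Duplicated IR genes
are counted once per distinct gene by default (`count_ir_duplicates = TRUE`
counts both copies); per-genome codon totals in the literature are not
decomposable enough to settle this, so it is a documented switch.

## Diversity statistics

All statistics work on a gapped multiple alignment (rows over A/C/G/T/N/-).

* **Pair frequencies** classify every residue pair in every column as
  identical, transitional (A–G, C–T) or transversional, reported as
  percentages of compared pairs.  Pairwise deletion is the default;
  `deletion = "complete"` restricts to columns clean in every row, since
  published values rarely state which convention their software used.
* **π (nucleotide diversity)** is the mean over sequence pairs of per-site
  differences under complete deletion (columns with any gap or N removed),
  the default behaviour of the standard polymorphism software.
* **Tajima's D** contrasts mean pairwise differences with the Watterson
  estimate from segregating sites, using the standard a1…e2 constants; with
  no segregating sites the statistic is undefined and `NA` is returned
  rather than 0.
* **Indel events**: one event per distinct maximal gap run — a run of `-` in
  one row merged with runs at identical coordinates in other rows.  The
  polymorphism literature does not print its event definition, so this rule
  is stated here and verified against an independent enumeration oracle.
* **SV** is the hotspot index
  `SV = (mutations + indel events) / (conserved sites + mutations + indel
  events) × 100`, with mutations = gap-free polymorphic columns (a 3-state
  column counts once by default; `per_mutation = TRUE` counts k−1) and
  conserved = gap-free monomorphic columns.

## Hotspot scanning

Homologous loci across genomes are matched by shared annotation-derived name
(gene symbol for CDS, flanking-gene pair for intergenic spacers), not by
sequence-similarity retrieval: for congeneric, consistently annotated
plastomes name matching is exact and deterministic, which is what a
re-runnable pipeline needs.  A locus is kept when present in all genomes at
≥ 150 bp in each (the conventional screening threshold for intergenic
spacers).  Each locus is aligned with the package's center-star progressive
aligner — pairwise global alignments with match +1, mismatch −1, gap open
−4, gap extension −1, merged on the center sequence chosen by shared-k-mer
similarity — and ranked by SV with π and then name as tie-breaks, making the
ranking invariant to genome input order.  Center-star merging left-aligns
insertions from different rows between the same pair of center bases rather
than mutually aligning them; for the percent-scale divergences the pipeline
targets this is immaterial, but it is a known simplification.

## SNP phylogeny

SNPs are alignment columns with no gaps or N and at least two states,
positioned in ungapped reference coordinates.  Distances use the Kimura
2-parameter model, `d = −½ ln((1 − 2P − Q)√(1 − 2Q))`, and the tree is built
by neighbor joining with two robustness conventions: Q-criterion ties break
by taxon-name order, and a negative branch length is clamped to zero with
the deficit moved to its sister branch so path lengths are preserved.  On an
additive matrix this recovers the generating tree exactly.  Bootstrap
supports resample SNP columns with replacement (500 replicates by
conventional default) and count, for each internal bipartition of the point
tree, the fraction of replicate trees containing it.  Because SNP-only
columns concentrate divergence, a bootstrap replicate can saturate the K2P
logarithm; such pairs fall back to their raw divergence P + Q within the
replicate, preserving the ordering NJ consumes.  A maximum-likelihood search
is deliberately out of scope: NJ over the same substitution model is
tractable, deterministic and adequate at the divergence scale of congeneric
plastomes, and the output labels the method accordingly.

## The synthetic-plastome generator

`generate_plastome()` builds the test universe: a circular genome laid out
LSC–IRB–SSC–IRA with `seq[IRA]` exactly the reverse complement of
`seq[IRB]`, annotated genes (an intron-bearing CDS, a gene nested inside
another gene's intron, duplicated IR genes, and a CDS spanning the IRB/SSC
junction), and planted SSR loci whose flanking bases are adjusted so each is
maximal in context; the bases just outside both IR ends are likewise
adjusted so the planted IR pair is the maximal one.  Defaults are a
1/10-scale model of a real plastome — LSC 8200, SSC 1700, IR 2600 bp,
GC 0.366 — so the whole cross-module truth suite runs in seconds; tests that
need other shapes pass explicit lengths.  Everything is seeded and the
manifest (`truth`) exactly describes the emitted sequence; re-running with
the same seed is byte-identical.

`mutate_plastome()` derives genomes by per-site substitutions (transition
probability `ts_tv_ratio/(ts_tv_ratio+1)`, default ratio 2) and short
indels.  Two deliberate properties: the IR copies are co-mutated (IRA is
re-synchronised from IRB), emulating the concerted evolution that keeps real
IRs identical, and indels are confined to single-copy intergenic DNA outside
planted SSRs so gene models, reading frames and SSR truth stay exact while
coordinates are remapped through the indels.  Consequently the generator
does **not** emulate: coding indels and pseudogenisation, IR
expansion/contraction, rearrangements, heteroplasmy, or realistic codon
bias (gene sequences are random DNA with valid start/stop).  Passing tests
therefore demonstrate algorithmic correctness under the stated model, not
robustness to annotation noise or structural variation in real data.

For recovery runs the study conditions are four derived genomes at
substitution rate 0.002 with one locus at 5× that rate (a planted divergence
hotspot); at these settings the expected pairwise per-site divergence is
`2r(1−r) + r²/2` (the r² term from both copies mutating with a ½ chance of
different outcomes at 2:1 transition odds), which the measured genome-wide π
matches within Monte-Carlo error over 20 seeded sets, and the planted
hotspot ranks first.

## Problem sizes, performance and limitations

The test suite and the acceptance script run entirely on generated data:
50 kb random sequences for the SSR oracle equivalence (100 of them),
~15 kb genomes for structure/recovery work, and 20-replicate seeded sets for
the statistical checks — sizes chosen so every stage's verification is exact
or statistically calibrated while the whole suite stays fast.  The built-in
aligner is quadratic in sequence length; it is comfortable for per-locus
alignments and mini-genomes, but for full-size (~150 kb) plastomes a
pre-computed whole-genome alignment should be supplied via
`run_compare(alignment =)`, which the pipeline accepts in place of computing
one.  Gene-name matching assumes consistent annotation vocabularies across
inputs; diverging annotation pipelines (synonyms, case differences) would
need harmonisation upstream.  Reported SSR totals are threshold-dependent,
and third-codon-position composition is reported but not emphasised, as
published values for it are not always internally consistent.
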