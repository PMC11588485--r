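# plastcompare

Comparative analysis of annotated chloroplast genomes (plastomes) in R, for
researchers comparing congeneric plastomes to characterise genome structure
and find candidate molecular markers. Given a set of annotated records
(GenBank flat files or in-memory objects) the package:

* detects the **quadripartite structure** — the inverted-repeat pair
  (IRA/IRB) and the large/small single-copy regions (LSC/SSC) — and reports
  the four junctions (JLA, JLB, JSA, JSB) with their flanking genes;
* mines **perfect SSRs** (microsatellites, unit length 1–6) with maximality
  and smallest-period guarantees, classifies them by motif, length group,
  region and genic context;
* computes **codon usage** over the CDS complement and the relative
  synonymous codon usage
  `RSCU(c) = n_c · |F| / Σ_{c'∈F} n_{c'}` for each synonymous family `F`,
  classifying codons as overrepresented (RSCU > 1.6), high-frequency
  (RSCU > 1) or underrepresented (RSCU < 0.6);
* measures **diversity** on multiple alignments: nucleotide-pair
  frequencies (identical / transition / transversion), nucleotide diversity
  π (mean pairwise per-site differences, complete deletion), Tajima's D,
  indel events, and the sequence-variability hotspot index
  `SV = (mutations + indels) / (conserved + mutations + indels) × 100`;
* ranks **divergence hotspots** across homologous CDS and intergenic loci
  (shared-name matching, ≥150 bp, center-star alignment, SV ranking with π
  tie-break);
* builds a **SNP-based phylogeny**: Kimura 2-parameter distances
  `d = −½ ln((1−2P−Q)√(1−2Q))`, neighbor joining, bootstrap supports over
  resampled SNP columns, Newick output;
* ships a **synthetic-plastome generator** with a ground-truth manifest
  (planted IRs, genes, SSRs, seeded substitutions/indels), so the whole
  pipeline is verifiable without downloading anything.

Everything takes and returns tidy data frames where the data are tabular;
fitted/structured results are small S3 objects with `tidy()`, `glance()`,
`autoplot()`/`plot_*()` methods.

## Worked example

Generate a seeded 4-genome study set (one ancestor, four derived genomes at
substitution rate 0.002 with a 5× divergence hotspot planted in `rbcL`) and
run the stages:

```r
library(plastcompare)

st <- generate_study_set(n_genomes = 4, sub_rate = 0.002,
                         hotspot_locus = "rbcL", hotspot_multiplier = 5,
                         seed = 42)

part <- detect_inverted_repeats(st$ancestor)
part
#> <region_partition> anc (15100 bp): LSC 8200, SSC 1700, IR 2600 x2
#>   junctions: JSA=12501 JLA=1 JLB=8201 JSB=10801
```

The detected partition recovers the generator's planted architecture
exactly: a 15.1 kb circle (a 1/10-scale plastome model) split into LSC 8200,
SSC 1700 and two exact 2600 bp IR copies.

```r
aln <- as_alignment(setNames(sapply(st$records, `[[`, "sequence"),
                             sapply(st$records, `[[`, "id")))
diversity_stats(aln)
#>   identical_pct transition_pct transversion_pct n_pairs_compared          pi
#> 1      99.52539      0.2924945        0.1821192            90600 0.004746137
#>     tajima_d        sv n_mutations n_indel_events n_conserved
#> 1 -0.8508131 0.9470199         143              0       14957
```

π ≈ 0.0047 matches the mutation model's expectation (each pair of genomes
accumulates ≈ 2 × 0.002 differences per site, plus the hotspot's excess),
and transitions outnumber transversions ≈ 2:1, the generator's ts/tv ratio.

```r
scan_hotspots(st$records, "cds", min_len = 150)
#>    rank locus kind  n_genomes length    sv      pi n_mutations ...
#> 1     1 rbcL  cds           4    570 3.33  0.0170           19
#> 2     2 atpA  cds           4    480 1.88  0.00938           9
#> 3     3 rpl16 cds           4    399 1.50  0.00752           6
```

The planted hotspot ranks first with SV 3.33 — about 4× the background loci,
as expected for a 5× local rate.

```r
plastome_phylogeny(aln, replicates = 500, seed = 42)
#> <plastome_phylo> 4 taxa, 143 SNPs, 500 bootstrap replicates
#>    ((sp1:0.0019,sp3:0.0024)51:0.00007,sp2:0.0025,sp4:0.0027)100;
```

Four independently derived genomes form a star-like radiation: the internal
edge is near zero with weak support (51%), exactly what the simulation
implies — there is no true internal structure to find.

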