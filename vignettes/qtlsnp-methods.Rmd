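---
title: "Methods: mining and validating candidate-gene SNPs around growth QTLs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and validating candidate-gene SNPs around growth QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlsnp)
```

## The problem

Aquaculture breeding programs want markers inside genes that plausibly
drive a trait.  For a flatfish such as turbot, a practical route is to
call SNPs from pooled muscle and liver RNA-seq aligned to a draft genome,
keep the SNPs that land in known growth-regulation genes, rank those
genes by physical proximity to previously mapped growth QTL markers on a
scaffold-anchored genetic map, select one technically suitable SNP per
gene for an assay panel, and finally validate the panel by genotyping an
independent population sample.  `qtlsnp` implements that chain as
composable, file-based stages plus a synthetic-data generator that makes
every stage testable against a known ground truth.

## Pileup SNP calling

The caller consumes per-site tallies (base plus Phred quality per
aligned read).  Defaults: base quality ≥ 20, quality-filtered depth ≥ 10,
minor allele count ≥ 3.  Two choices deserve comment:

* **Filter order.**  The depth threshold is applied *after* base-quality
  filtering, so low-quality bases can never support a call.  The order is
  configurable (`call_variants()` arguments) for sensitivity analysis.
* **Multi-allelic sites.**  When a third allele also reaches the
  minor-allele-count floor, the site is called as a SNP on its top two
  alleles, the extras are kept in a `note` field, and the site is
  excluded from the six-type substitution spectrum so that the
  transition/transversion partition (A/G, C/T transitions; A/C, A/T,
  C/G, G/T transversions) stays well defined.

Tallies for the same site seen in several libraries (muscle and liver)
are added before calling; pooling reads raises coverage, which is the
reason multi-tissue discovery pools are combined in practice.  The minor
allele is the second most frequent after filtering, ties broken
alphabetically.

## Region and codon-effect annotation

Gene models are strand-aware exon/CDS/UTR structures (GFF3, 1-based
inclusive).  Introns are derived as inter-exon gaps, so the five region
classes — 5' UTR, 3' UTR, synonymous exon, non-synonymous exon, intron —
partition each gene span; a property test sweeps every in-gene position
to confirm the partition.  For CDS positions the reference codon is read
in transcription order (reverse-complemented on the minus strand), the
alternate allele substituted, and both codons translated with the
standard genetic code; unequal amino acids yield labels such as
`Exon V-A` (reference amino acid first).  Intronic SNPs in
transcriptome-derived data are retained: intron retention is common in
RNA-seq and intronic variants can still be assayed.

Genes with several isoforms are classified per transcript; the reported
region comes from a canonical transcript chosen as the one with the
longest CDS.  Per-isoform detail remains available through
`classify_snp_region()`.

The ortholog scan used to place candidate transcripts is a deliberately
small seed-and-extend aligner (exact k-mer seeds, ungapped extension,
match +1 / mismatch −2, X-drop): at fixture scale it is exact enough,
and its identity/aligned-length thresholds are the implementable
equivalent of an aligner-specific e-value cut-off.  Precomputed hit
tables from a full local aligner can be supplied instead
(`place_gene(hits = ...)`).  A placement requires a unique passing
scaffold; multi-scaffold hits are rejected as ambiguous.

## QTL co-localization

Anchor markers carry both a genetic position (linkage group, cM) and a
genome position (scaffold, bp).  A scaffold inherits the LG of its
anchors; anchors from two LGs are a conflict and leave it unanchored.
Genes on unanchored scaffolds can be assigned an LG by comparative
synteny: mapped orthologs in model species vote for the LG paired with
their chromosome, and only a strict majority wins.

The gene–marker distance is measured from the nearest gene-span boundary
(zero when the marker falls inside the span).  A midpoint convention
would be equally defensible; boundary distances were chosen because the
small distances one wants to report (tens of kb) are boundary-style and
a midpoint adds half the gene length as noise.  Distances below 1 Mbp
set a *preference* flag used as a ranking bonus — deliberately not a
hard filter, since informative genes can sit several Mb from the nearest
mapped marker.  QTLs without an associated marker are represented by the
reference markers of their confidence interval (evidence tier
`closest-marker`).  Genetic and physical distance interconvert at a
constant 0.5 Mb/cM (configurable in `mb_to_cm()`).

## Panel selection

"Manual inspection" of candidate SNPs is codified as configuration
(`selection_config()`): a discovery minor-allele-fraction floor
(default 0.1 — pool frequencies below that are too likely to be noise or
rare private variants), a clean-flank requirement for primer design
(term saturating at 30 bp), a strict region priority
(non-synonymous > 5' UTR > 3' UTR > synonymous > intron) and a bonus for
within-preference QTL co-localization.  The defaults are a documented
reconstruction of common assay-design practice, not measured constants.
Scores are spaced so the region priority always dominates the bonus and
flank terms; ties break by larger flank, then smaller coordinate, making
selection fully deterministic.  One SNP is selected per gene.

## Validation statistics

Given a genotyped population sample (GENEPOP file, biallelic loci,
2-digit allele codes with `A=01, C=02, G=03, T=04`, `0000` missing),
each assay is classified as failed (more than 50% missing),
monomorphic, or polymorphic; statistics are computed for polymorphic
loci over their typed individuals.

* **Unbiased gene diversity.**  `He = n/(n−1) · (1 − Σp̂² − Ho/(2n))`
  (Nei's unbiased estimator including the observed-heterozygosity term).
  The simpler allele-count correction `2n/(2n−1) · (1 − Σp̂²)` was
  rejected because it disagrees in the third decimal on reference
  checks (e.g. 0.507 vs 0.508 for a locus with 16 heterozygotes among
  34 diploids at allele frequency ½).
* **Fixation index.**  `F_IS = 1 − Ho/He` with the He above.  It is 1
  exactly when no heterozygotes are observed at a polymorphic locus and
  negative whenever Ho exceeds He.
* **Exact Hardy–Weinberg test.**  All loci being biallelic, the test
  enumerates, conditional on the observed allele counts, every
  heterozygote count of matching parity (at most n+1 terms), computes
  the conditional probabilities with log-factorials, and sums those no
  larger than the observed configuration's probability (probability-
  ordering two-sided test).  A relative tolerance of 1e−12 treats
  floating-point-equal probabilities as ties.  A brute-force oracle that
  enumerates genotype multisets agrees exactly up to n = 8, and the
  enumeration is verified to normalize (the modal configuration has
  p-value 1).
* **Linkage disequilibrium.**  The genotypic G-test:
  `G = 2 Σ O ln(O/E)` over the genotype×genotype table of a locus pair
  (pairwise-complete individuals, zero cells skipped), with a
  permutation null obtained by shuffling one locus across individuals.
  The p-value uses the `(b+1)/(m+1)` estimator so it can never be zero;
  the smallest attainable value is `1/(m+1)`.  Permutations are seeded
  per pair, so scans are reproducible.
* **Multiple testing.**  Bonferroni, `alpha/k` over the
  `choose(n_polymorphic, 2)` pairs.

Reports round to 3 decimals (4 for HW p-values); internal values keep
full precision.

`counts_from_stats()` inverts rounded published statistics
(MAF, He, F_IS) back to genotype counts by searching the small discrete
configuration space, trying successively smaller sample sizes to
accommodate loci with missing genotypes.  Three rounded statistics
over-determine the two free counts, so the inversion is unique in
practice.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults are:

| parameter | default | meaning |
|---|---|---|
| `n_scaffolds`, `scaffold_length_bp` | 4 × 50 kb | toy draft genome |
| `n_genes` | 12 | strand-alternating gene models |
| `exons_per_gene`, `utr_lengths_bp` | 2–4, 150/250 bp | gene structure |
| `snp_density` | 1 / kb | planted biallelic SNPs |
| `genic_fraction` | 0.5 | share of variants inside genes (transcriptome discovery concentrates variants in transcribed sequence) |
| `transition_prob` | 0.574 | transition share among planted alternates, giving ts/tv ≈ 1.35 as typical of fish transcriptome SNP sets |
| `pooled_allele_freq_range` | 0.1–0.5 | pooled discovery alternate frequency |
| `mean_depth` | 50 | Poisson read depth per site |
| `qual_profile` | mostly Q37/Q30 | Phred mixture; per-base error `10^(−Q/10)` |
| `pop_n`, `pop_f`, `missing_rate` | 34, 0, 0.02 | validation population drawn from Wright equilibrium |

The discovery pool is modelled as a single pileup with a site-level
alternate frequency rather than as explicit individuals: the caller only
ever sees tallies, and per-individual allele depth inside a pooled
library is unrecoverable anyway.  The validation population of 34
diploids is drawn from `P(AA) = p² + fpq`, `P(Aa) = 2pq(1−f)`,
`P(aa) = q² + fpq`, with `f` allowed down to the feasibility bound
`max(−p/q, −q/p)` so heterozygote-excess (negative F_IS) loci can be
simulated.  Genotype simulation is the basis of two calibration checks:
observed genotype fractions converge to the closed-form probabilities,
and the mean of F_IS estimates across 200 replicates of n = 1000
recovers the simulated `f` within 0.02.

What the generator does **not** emulate: read-level artefacts
(alignment error, strand bias, PCR duplicates), indel alleles beyond a
binary non-SNP token, linked loci (validation genotypes are drawn
independently per locus), population structure, and null alleles at the
genotyping step.  Passing tests therefore demonstrate the correctness of
the statistical machinery and the internal consistency of the pipeline,
not robustness to every artefact of real sequencing data.

## Determinism and numerics

Every stochastic stage takes an explicit seed; a configuration rebuilds
byte-identical fixture files and pipeline outputs.  File coordinates are
1-based inclusive throughout; conversions are centralized in the format
codecs.  Degenerate inputs are values, not crashes: zero-depth pileup
sites carry empty tallies, a no-call is `NULL`, an all-transition
spectrum reports an undefined ratio, and monomorphic loci return HW
p = 1 while He/F_IS are reported as missing.

## Problem sizes used by the test-suite

Unit fixtures use 2–4 scaffolds of 20–50 kb with 4–12 genes; the caller
calibration uses 1,000 planted sites at depth 50; the LD type-I check
runs all 741 pairs of 39 independent loci with 199 permutations each;
the HW oracle comparison enumerates every configuration up to n = 8.
These sizes keep the whole suite within a couple of minutes on one core
while leaving the statistics enough resolution for their stated
tolerances.

## Known limitations

* The seed-and-extend scanner is ungapped; diverged orthologs with
  indels need an external aligner (supported via precomputed hit
  tables).
* Only biallelic loci are handled by the validation statistics; the
  G-test permutation scheme is a documented reconstruction of common
  practice and may differ in detail from legacy implementations.
* The panel-mean standard errors reported are plain SD/SE across loci;
  no jackknife over loci or individuals is attempted.
* Co-localization assumes marker bp positions are on the same assembly
  as the gene placements; liftover between assemblies is out of scope.
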