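---
title: "Prioritizing recessive candidate variants in family exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing recessive candidate variants in family exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famexome)
```

## The model

`famexome` targets the common design in gene discovery for autosomal
recessive disease: a small ascertained nuclear family — often just two
affected siblings and their unaffected parents — sequenced by whole-exome
capture. Under a fully penetrant recessive model, the causal genotype is
either a homozygous variant or a compound heterozygote (two different
deleterious alleles of one gene, one per parental haplotype, i.e. in
*trans*), present in every affected sibling, absent (as a full genotype)
from every unaffected relative, and essentially absent from population
databases and ethnically matched controls.

The pipeline encodes those assumptions as an ordered filtering funnel with
per-stage accounting, followed by family logic. The funnel order is fixed:
mapping quality, functional impact, database subtraction (control-exome set
first, then SNP catalogue, which mirrors how such studies report their
intermediate counts), then gene-panel restriction. Two descriptive
pre-stage counts (all carried variants, and those in coding regions) are
reported but are not part of the cascade, so monotonicity of retained counts
is guaranteed only along the true stages. Set subtraction commutes, so the
final retained set does not depend on the database order — only the
intermediate counts do.

Sibling sharing intersects the per-sample surviving variant *keys*
(`contig:pos:REF:ALT`, `chr` prefixes stripped, alleles uppercased).
Intersection precedes genotype logic: a variant must be called in every
affected sibling to survive. After sharing, a frequency catalogue (a
genomes-project-style table) is applied as a separate exclusion: this is
deliberately *not* a funnel stage, because a variant can be absent from the
funnel databases yet catalogued with a small frequency elsewhere, and that
is exactly how such variants are eliminated in practice — after they have
survived to the shared candidate list. Under the default exclusion
threshold of 0, any catalogued frequency (for example MAF 0.002) excludes;
the threshold is configurable because for a recessive gene a genuinely rare
polymorphism in the local population is not automatically benign.

### Phase and segregation

Compound-het candidacy requires the same two heterozygous variants in all
affected siblings. Whether the pair is in trans is decided against parental
genotypes by exhaustive enumeration: all phased parental diplotypes
consistent with the observed allele counts, and all transmissions producing
a double-heterozygous child, are enumerated. If every Mendelian explanation
puts the two variants on opposite parental origins, the pair is
`TRANS_CONFIRMED` (in the typical case each parent is heterozygous for
exactly one distinct variant of the pair); if every explanation puts both on
one parental haplotype, it is `CIS_REJECTED` and dropped from the causative
report (but retained in the audit output); ambiguity, Mendelian
impossibility or unsequenced parents give `PHASE_UNKNOWN`. We chose
enumeration over the simpler carrier-pattern decision table because the
table misclassifies corner cases — e.g. a parent homozygous for one variant
and heterozygous for the other *forces* a cis configuration that the
pattern rule cannot see — and enumeration makes the implementation provably
total over all 81 parental genotype combinations (a property the test suite
asserts against an independently coded oracle).

Full penetrance supplies the segregation overlay: an unaffected parent
homozygous for a putative causal allele, a child genotype not derivable from
its sequenced parents, or an unaffected sibling provably carrying the pair
in trans all mark the call `INCONSISTENT`. A single shared heterozygous
variant without a partner is reported as `SINGLE_HET_UNCERTAIN` — a real and
common outcome when parental DNA is unavailable, in which case phase is
unknowable and segregation untestable.

Sex chromosomes are accepted in input but excluded from recessive calling;
the package models autosomal recessive inheritance only. Missing genotypes
are treated as non-carrier during sharing (presence-based semantics) but
flag the resulting call, preserving auditability.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_mapping_quality` | 20 | site MQ below which a variant is removed; variants with no MQ are kept with a warning |
| `retained_impact_classes` | missense, nonsense, splice, coding indels | protein-affecting classes kept by the impact stage |
| `maf_exclusion_threshold` | 0 | catalogued MAF at or above which presence excludes; 0 means any presence excludes |
| `splice_window` | 2 bp | intronic bases next to an exon classified splice-site (the canonical donor/acceptor dinucleotide) |
| `depth_gap_threshold` | 5× | read depth below which a base is a coverage gap needing Sanger follow-up |
| `coverage_thresholds` | 1×, 10× | breadth-of-coverage fractions reported with ≥ t semantics |

"Covered to t×" is implemented uniformly as depth ≥ t; prose conventions
("more than 10×") vary between reports, and a single self-consistent rule
beats guessing a legacy tool's convention. Coverage audits of a gene extend
each exon by the splice window into the introns — a causal splice-donor
variant sits at +1, which a purely exonic audit would miss — but not past
the transcript ends, where there are no splice sites.

Annotation is gene-model-driven: coding SNVs are classified by translating
the affected codon before and after the change; splice-site variants get
HGVS-style offset labels (`c.4320+1G>A`) plus the legacy IVS alias
(`IVS11+1`, intron k following exon k in transcript order); coding indels
are frameshift when the length change is not a multiple of 3. A variant
whose reference allele contradicts the gene model's CDS is an error, not a
silent mis-annotation. Stop-gain and stop-loss are both classified
`NONSENSE` to keep the class set small. External predictor scores (SIFT,
PolyPhen-2, MUpro) and conservation flags are joined verbatim from an input
table and never computed.

## The simulator

`simulate_family()` generates the statistical structure the analysis
assumes, not sequencing reads: founders draw genotypes per site under
Hardy–Weinberg equilibrium at a per-variant MAF; children inherit one
parental haplotype per gene, so variants of a gene travel together while
genes are unlinked; phase is tracked internally but genotypes are emitted
unphased, forcing the pipeline to re-infer trans configuration from parents
honestly. A causal compound het plants one splice-donor and one missense
variant in a panel gene on opposite parental haplotypes; transmissions at
the planted genes are rejection-sampled until every affected child carries
the causal genotype and no unaffected child does — reproducing
ascertainment without a penetrance model. Three decoys exercise the
exclusion rules: a variant on the paternal causal haplotype catalogued at
MAF 0.002 (survives to sharing, falls to the frequency exclusion), a cis
pair on one paternal haplotype of a second panel gene (must be rejected by
the phase check), and a control-exome-present variant (falls inside the
funnel). Identical configurations, including the seed, produce
byte-identical output files.

Default study conditions: a quartet with two affected children; 800
segregating background sites in synthetic non-panel genes with MAF uniform
on [0.01, 0.5]; 86% of background sites present in the SNP catalogue and
95% in the control-exome set, assigned independently (the ratios observed
when such funnels are applied to real exomes, where the population-specific
control set removes far more than the catalogue alone); 5% of background
sites given MQ < 20; a 409-individual control cohort never carrying the
family-private alleles; depth tracks at mean 56× with engineered sub-5×
holes. The background count is deliberately smaller than a real exome's
~10,000 protein-affecting variants: the funnel's behaviour is scale-free
(every stage is a per-variant predicate), so 800 sites exercise the same
logic while keeping 50-replicate suites fast; the test suite states the
problem sizes it uses.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: sequencing error and genotype miscalls, linkage
disequilibrium between background variants, indels and multi-allelic sites
in the background (the decomposition path is tested on constructed records
instead), population stratification between family and databases, and
incomplete penetrance. Recovery of the planted gene in 50/50 seeded
replicates is a correctness check of the pipeline's logic under its own
model, not a sensitivity estimate for real exomes.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere internally (the VCF
  convention); only BED output is 0-based half-open, and abutting intervals
  are merged on write.
* Variant identity is exact string equality of `(contig, pos, REF, ALT)`
  after uppercasing and `chr`-stripping; indel left-normalization is
  required of the input, not performed, so database subtraction stays
  well-defined.
* Genes with three or more shared heterozygous variants emit all pairs,
  flagged; the phase check then sorts out which, if any, are in trans.
* The funnel treats `QUAL`/`FILTER` as opaque; the only site-quality filter
  is MQ, taken from `INFO/MQ`.
* Empty inputs are legal everywhere they can occur (empty VCF body, empty
  database, zero-size cohort); an empty gene panel is an error because it
  silently voids the analysis.
* `run_pipeline()` maps its outcome to a status — `confirmed` (a
  trans-confirmed compound het or consistent homozygote), `uncertain`
  (only unphaseable or single-het candidates), `none` — which the
  command-line front end turns into exit codes 0/3/4 so batch screens can
  triage families.

## Limitations

One transcript per gene (no consequence ranking across isoforms); no
X-linked, imprinting or mosaic models; no statistical burden testing — the
package decides candidacy, not significance; control carrier counting is
genotype-presence-based and assumes the cohort was genotyped at the
candidate keys (a key absent from the cohort counts 0 carriers, with a
warning). The phase check uses parental genotypes only; sibling genotypes
could in principle refine ambiguous cases but are used only for the
penetrance consistency check.
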