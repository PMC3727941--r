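# famexome

Family-based exome variant prioritization for autosomal recessive disease.

## The problem

In a small nuclear family with an autosomal recessive phenotype — the
motivating case is nonsyndromic hearing loss, where more than a hundred loci
can cause an indistinguishable clinical picture — whole-exome sequencing
yields tens of thousands of variants per individual, of which exactly one
genotype is causal. The standard clinical prioritization is a filtering
funnel followed by family logic:

1. **Quality**: keep variants with site mapping quality MQ ≥ 20.
2. **Impact**: keep missense, nonsense, splice-site and coding indel
   variants.
3. **Database subtraction**: remove variants present in a control-exome set
   and in a SNP catalogue (a causal allele for a rare fully penetrant
   recessive disease should be absent from population databases).
4. **Panel restriction**: keep variants in reported disease genes.
5. **Sibling sharing**: intersect the surviving variant sets of all affected
   siblings, then exclude anything catalogued with an appreciable minor
   allele frequency (the default excludes at any catalogued MAF, so a
   variant at MAF 0.002 is removed).
6. **Recessive calling**: per gene, a variant homozygous in all affected
   siblings, or a pair of variants heterozygous in all of them (a candidate
   *compound heterozygote*).
7. **Segregation**: confirm a compound-het pair is in *trans* — one variant
   inherited from each unaffected carrier parent — by exhaustive enumeration
   of the parental diplotypes consistent with the observed genotypes; pairs
   riding a single parental haplotype (*cis*) are rejected.
8. **Controls and follow-up**: count carriers in an ethnically matched
   control cohort (`x/n`), and report low-coverage regions (read depth < 5)
   of candidate genes for orthogonal Sanger sequencing.

`famexome` implements this pipeline over plain VCF/PED/TSV inputs, plus a
seeded simulator of family exomes (Hardy–Weinberg founders, per-gene
Mendelian haplotype transmission, planted causal genotypes, decoy variants,
depth tracks and truth sets) so that every stage is testable without any
external data.

## Worked example

`sr903_example()` reconstructs a solved quartet on synthetic gene models:
two affected siblings heterozygous for a splice-donor variant (from the
mother) and a missense variant (from the father) in the same deafness gene,
a third shared variant catalogued at MAF 0.002, and assorted variants that
exercise every funnel stage.

```r
library(famexome)
ex <- sr903_example()
res <- run_pipeline(ex$vs, ex$ped, ex$genes, ex$panel, ex$funnel_dbs,
                    ex$exclusion_dbs, ex$scores, ex$domain_map,
                    ex$cohort, ex$depth)
res
#> pipeline_result: confirmed
#>   shared variants: 3 | after frequency exclusion: 2
#> MYO15A: 17:18035881:G:A + 17:18049349:G:A [COMPOUND_HET] phase=TRANS_CONFIRMED segregation=CONSISTENT

res$candidates[, c("section", "nucleotide_change", "amino_acid_change",
                   "location", "domain", "controls")]
#>              section nucleotide_change amino_acid_change location domain controls
#> 1 Pathologic variant       c.4320+1G>A           IVS11+1   Intron  Motor    0/409
#> 2 Pathologic variant         c.6437G>A          p.R2146Q  Exon 29  MyTH4    0/409

write_funnel(res$funnels, shared = length(res$shared))
#>                                            stage SR-903 SR-903B
#> 1                                 total variants     10       8
#> 2                                coding variants     10       8
#> 3                          mapping quality >= 20      9       7
#> 4  missense, nonsense, splice and indel variants      8       6
#> 5                  after control_exome filtering      7       5
#> 6                  after snp_catalogue filtering      6       4
#> 7                        variants in panel genes      5       3
#> 8                                shared variants      3       3
```

The siblings' panel candidate lists (5 and 3 variants) share 3 variants; the
frequency-catalogue exclusion removes the MAF-0.002 decoy, and the remaining
pair is called compound heterozygous and confirmed in trans, so it is
reported under "Pathologic variant" with its splice/missense labels, protein
domains and a 0/409 control carrier count. `sr285_example()` is the
contrasting case — an affected sib pair without parental DNA whose single
surviving heterozygous variant stays "uncertain" with unknown phase.

Simulated studies work the same way:

```r
sim <- simulate_family(sim_config(random_seed = 1))
res <- run_pipeline(sim$vs, sim$ped, sim$genes, sim$panel,
                    list(sim$dbs$control_exome, sim$dbs$snp_catalogue),
                    list(sim$dbs$frequency_catalogue))
res$status           # "confirmed"
sim$truth$causal_keys  # the planted pair the pipeline must recover
```

A thin command-line front end with `simulate`, `prioritize` and
`coverage-gaps` subcommands is installed under
`system.file("scripts", "famexome", package = "famexome")`; `prioritize`
exits 0 / 3 / 4 for confirmed / uncertain / no candidates.

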