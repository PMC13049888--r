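# admixmeth

Tools for dissecting the genetic architecture of DNA methylation in
naturally admixed populations, modeled on hybrid baboon study systems but
applicable to any two-taxon admixture with bisulfite-sequencing count data.

## The scientific problem

When two diverged taxa hybridize, each admixed genome is a mosaic of local
ancestry tracts. If DNA methylation is under *cis*-genetic control, the
taxon-of-origin of a chromosomal segment should predict methylation at CpG
sites in that segment, and the ancestry effect at a CpG should decompose
into the effect size of a nearby methylation quantitative trait locus
(meQTL) times the allele-frequency divergence of that locus between the
parental taxa:

    effect(ancestry) = delta * (p_anubis - p_yellow)

where `delta = m_alt - m_ref` is the per-allele meQTL effect on the
methylation-proportion scale and `p_*` are the parental alternate-allele
frequencies. The package implements this composition rule and everything
needed to test it:

- **Beta-binomial regression** (`betabinom_glm()`): methylated read counts
  out of total counts, logit link, per-site dispersion `phi` (intraclass
  correlation; `phi = 0` is the exact binomial limit). Returns a classed
  `bbfit` object with the usual `print`/`summary`/`coef`/`logLik`/`vcov`
  methods.
- **Ancestry scan** (`ancestry_scan()`): per-CpG test of local-ancestry
  dosage (0/1/2) and global ancestry, with the standard site filters (mean
  methylation within [0.1, 0.9], at least 10 individuals per ancestry
  state), a permutation-based empirical null, and q-values
  (`empirical_qvalues()`). An additivity test (`test_additivity()`)
  contrasts the additive dosage coding with a free three-level coding.
- **Species differences** (`test_species()`, `concordance()`): differential
  methylation between unadmixed parental groups, and its directional
  concordance with within-hybrid ancestry effects.
- **meQTL mapping** (`build_pairs()`, `fit_meqtl()`, `meqtl_scan()`): joint
  likelihood over the across-individual genotype effect and
  within-heterozygote allele-specific methylation for SNP–CpG pairs
  co-observed on reads (within 100 bp), with a double permutation null that
  shuffles genotypes and re-draws heterozygote read allele labels.
- **Composition** (`predict_ancestry_effect()`, `compare_composition()`):
  predicted-versus-observed ancestry effects, sign quadrants, and flagged
  discordant CpGs.
- **Variance gain** (`maf_shift()`, `sd_gain()`, `gain_vs_introgression()`):
  how admixture shifts meQTL allele frequencies and inflates methylation
  variance relative to the ancestry-homozygous subset.
- **Reporter assay** (`filter_windows()`, `normalize_reporter()`,
  `test_activity()`, `test_methylation_dependence()`): mSTARR-seq-style
  calls of regulatory activity (RNA vs DNA contrast) and
  methylation-dependent activity (condition interaction), with the
  positive-effect retention rule and subsampled permutation null.
- **Annotation** (`find_cpg_islands()`, `assign_context()`,
  `context_enrichment()`, `expression_integration()`): CpG islands/shores,
  strand-aware promoters, gene parts, enhancers, Fisher enrichment, and
  integration with gene-expression ancestry effects.
- **Synthetic cohorts** (`sim_config()`, `simulate_cohort()`,
  `simulate_reporter()`): two parental taxa under Balding–Nichols drift,
  mosaic ancestry tracts from a two-state Markov process, genotypes,
  RRBS-like overdispersed methylation reads with allele-specific counts,
  and reporter DNA/RNA replicates — all with known ground truth, so every
  stage is testable without external data.

## Worked example

The package's central arithmetic on the canonical biallelic example — an
A/T meQTL whose A allele is never methylated while the T allele is
methylated half the time, with the T allele at 25% frequency in yellow
baboons and fixed in anubis baboons:

```r
library(admixmeth)

population_mean_methylation(0, 0.5, 0.25)   # yellow background
#> [1] 0.125
population_mean_methylation(0, 0.5, 1.0)    # anubis background
#> [1] 0.5
predict_ancestry_effect(0.5, 0.25, 1.0)     # ancestry effect
#> [1] 0.375
```

A pool of yellow alleles averages 12.5% methylation, a pool of anubis
alleles 50%, so anubis ancestry raises methylation by 37.5 percentage
points — exactly the meQTL effect (50%) times the frequency difference
(75%).

End to end on a synthetic cohort:

```r
cfg <- sim_config(n_individuals = 300, n_snps = 120, n_cpgs = 100,
                  frac_meqtl = 0.5, admix_alpha = 0.4, seed = 42)
coh <- simulate_cohort(cfg)
sites <- filter_sites(coh$counts, coh$panel)
scan <- ancestry_scan(coh$counts, coh$panel, n_perm = 10, seed = 42,
                      sites = sites)
built <- build_pairs(coh$genotypes, coh$counts, coh$layout$pairs)
meqtl <- meqtl_scan(built, n_perm = 10, seed = 42)
```

`run_pipeline(pipeline_config(...), out_dir)` orchestrates all stages and
writes TSV outputs plus a provenance manifest; identical seeds give
byte-identical outputs.

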