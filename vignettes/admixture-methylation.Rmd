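---
title: "Models and methods: ancestry, meQTL, and methylation in admixed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ancestry, meQTL, and methylation in admixed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixmeth)
```

## Overview

`admixmeth` analyses DNA methylation in admixed populations where each
genome is a mosaic of local-ancestry tracts from two diverged parental
taxa (referred to throughout as "yellow" and "anubis", after the baboon
hybrid systems that motivate the design). The package's scientific core is
a composition rule: if methylation is controlled in *cis* by meQTL whose
effect sizes are shared between the taxa, the effect of local ancestry at a
CpG equals the per-allele meQTL effect times the parental allele-frequency
difference,

$$\text{effect}_{\text{ancestry}} = \delta \cdot (p_A - p_Y),
\qquad \delta = m_{\text{alt}} - m_{\text{ref}},$$

with everything on the methylation-proportion scale. The modules around
this rule — the count model, the scans, the permutation FDR machinery, the
variance analysis, the reporter-assay calls, the annotation layer, and the
synthetic-data generator — are described below with their assumptions and
defaults.

## The count model

Bisulfite sequencing yields, per individual and CpG site, a number of
methylated reads out of a total. `betabinom_glm()` models these counts with
a beta-binomial: the mean follows a logit-linear predictor and a single
per-site dispersion $\varphi$ (the intraclass correlation) absorbs
extra-binomial variation from individual-level effects. The mixing
distribution is $\mathrm{Beta}(\mu(1-\varphi)/\varphi,
(1-\mu)(1-\varphi)/\varphi)$, chosen for its clean binomial limit:
$\varphi = 0$ is evaluated as an exact binomial, and values below $10^{-8}$
are evaluated on the binomial branch because the log-beta differences lose
all floating-point precision there (the likelihood is continuous across the
switch).

Fitting maximizes the likelihood jointly over coefficients and
$\mathrm{logit}(\varphi)$ by quasi-Newton iteration from a binomial-GLM
start, trying two dispersion starts (0.01 and 0.15) and keeping the better
optimum. Standard errors come from the observed information;
non-convergence or a non-invertible Hessian is reported through the
`converged` flag and such sites are excluded from FDR estimation rather
than silently dropped. Wald z-tests give per-coefficient p-values;
`lrt()` provides likelihood-ratio tests for nested comparisons.

A deliberate simplification: the reference analyses for this design use a
beta-binomial *mixed* model with a genetic-relatedness random effect. This
package substitutes fixed covariates (global ancestry, plus any
caller-supplied covariates such as genotype principal components). That
keeps the model desk-scale and fully testable, at the cost of residual
confounding by fine-scale kinship in real data; the synthetic generator
does not simulate kinship, so the test suite cannot detect that limitation
— it is inherent to the fixed-effects approximation.

## Empirical-null false discovery rates

All scans calibrate their p-values against permutation nulls rather than
theoretical ones. For the ancestry scan the local-dosage vector is shuffled
across individuals (and, separately, the global-ancestry vector), keeping
counts and covariates fixed; for the species test the species labels are
shuffled; for meQTL mapping genotypes are shuffled *and* each
heterozygote's allele-assignable reads are re-assigned to alleles uniformly
(reference totals binomial, methylated reads hypergeometric), which
preserves every individual's methylated/total marginals exactly; for the
reporter assay RNA/DNA labels are swapped within replicate pairs (activity)
or condition labels are re-assigned to replicate pairs
(methylation-dependence).

`empirical_qvalues()` converts observed and pooled permutation p-values to
q-values: $\widehat{\mathrm{FDR}}(t) = \hat\pi_0 \cdot
\frac{\#\{p_{\mathrm{perm}} \le t\}/B}{\max(1, \#\{p_{\mathrm{obs}} \le
t\})}$, with the q-value of a site the minimum over thresholds at or above
its p-value (hence monotone). $\hat\pi_0$ uses the single-$\lambda$ rule at
$\lambda = 0.5$, capped at 1 — simpler than spline smoothing and stable at
the permutation-pool sizes used here. The default number of permutations is
10 per scan, a desk-scale choice that the null-calibration suite shows is
already conservative (well under 2% of null units at $q < 0.1$); it is
configurable wherever it appears.

## The ancestry scan

Sites are filtered before testing: mean methylation (the mean over
individuals of the per-individual methylated/total ratio) must lie within
[0.10, 0.90], removing constitutively hyper- and hypomethylated sites, and
each local-ancestry state (0, 1, 2 anubis alleles) must be carried by at
least 10 individuals. The design is additive in dosage — supported by the
additivity test (`test_additivity()`), a 1-df likelihood-ratio comparison
of the additive coding against a free three-level coding — with global
ancestry always included.

Effects are reported on two scales: the logit-scale coefficient, and the
proportion-scale difference between model-predicted means at dosage 2
versus dosage 0 with covariates at their observed means
(`effect_to_proportion_scale()`). Halving the latter gives the per-allele
effect used for composition, so the ancestry and meQTL axes are
commensurable. The same predicted-mean convention is used for the species
contrast, so the two are directly comparable too.

## meQTL mapping

Only SNP–CpG pairs co-observable on a read (within 100 bp) are mapped.
Pair filters: SNP call rate at least 50%, minor allele frequency at least
0.05, CpG mean coverage at least 5 and mean methylation within [0.1, 0.9].
A SNP overlapping either base of the CpG dinucleotide is flagged
*disrupted*: the disrupting allele abolishes the CpG and forces near-zero
methylation on that allele.

`fit_meqtl()` maximizes a composite likelihood with one per-allele effect
$\beta$ shared by two components: (a) individual-level counts, whose mean
for a dosage-$d$ individual is the read mixture $((2-d) m_{\mathrm{ref}} +
d\, m_{\mathrm{alt}})/2$ with $m_{\mathrm{ref}} = \mathrm{logit}^{-1}(\mu_0)$
and $m_{\mathrm{alt}} = \mathrm{logit}^{-1}(\mu_0 + \beta)$; and (b)
within-heterozygote allele-specific counts at $m_{\mathrm{ref}}$ and
$m_{\mathrm{alt}}$. Reads that overlap the SNP contribute only to (b) and
are subtracted from the individual-level counts, so nothing is counted
twice. Either component alone identifies $\beta$ at large $n$; together
they mirror a joint individual-level/allele-specific design. The p-value is
a 1-df likelihood-ratio test of $\beta = 0$. The read-mixture mean is used
instead of a logit-additive dosage term because it is the exact mean of the
generative process (reads sample haplotypes uniformly); the two
parameterizations agree closely away from the boundaries.

## Variance consequences of admixture

`maf_shift()` compares each meQTL SNP's allele frequency between the
locally ancestry-homozygous subset (dosage 0) and the full sample. The
minor allele is defined *in the subset* and the same allele is tracked in
the full-sample estimate; re-folding at 0.5 separately in each sample would
manufacture spurious positive shifts. Paired t-tests are computed on the raw
frequencies (and on raw SDs in `sd_gain()`, not log-scaled ones — the
per-individual methylation ratio is already bounded). Under
Hardy–Weinberg equilibrium the cross-individual variance of expected
methylation at a biallelic meQTL is $2p(1-p)\,(\delta/2)^2$, which the
generator reproduces at high coverage and which links the frequency shift
to the variance gain analytically.

## Reporter-assay (mSTARR-style) calls

Counts are tabulated per 500-bp window and replicate (six DNA and six RNA
replicates per methylation condition by default). Window filters: median
DNA coverage strictly above 4 in both conditions, DNA presence in at least
half the DNA replicates of each condition, and non-zero RNA in at least
half the RNA replicates of either condition. Normalization is
median-of-ratios against a geometric-mean pseudo-reference with a 0.5
offset into log2 abundance; this is a library-composition normalization in
the same family as TMM, chosen because it is deterministic and
dependency-free. The per-condition activity statistic is the difference of
mean RNA and mean DNA abundance with a pooled variance across all four
assay-condition cells — an explicit, validated stand-in for
precision-weighted linear modeling, which may cost some power but not
validity (the null-calibration suite covers it).

Because most windows produce far more DNA than RNA, only windows with a
positive RNA-vs-DNA effect in at least one condition enter FDR estimation,
and each permutation's p-value pool is subsampled to the observed number of
positive-effect windows so the null honours the same asymmetry.
Methylation dependence is the interaction contrast (unmethylated activity
minus methylated activity) on the active set, with its own
condition-permutation null restricted to that set.

## Annotation

`find_cpg_islands()` scans 100-bp windows at 1-bp step, marking every base
covered by a window with GC fraction above 0.5 and observed/expected CpG
ratio ($n_{CpG} \cdot L / (n_C n_G)$) above 0.6; maximal marked runs longer
than 200 bp are islands and 2-kb flanks are shores (clipped at sequence
ends, never overlapping the island). The marked-run reading of the
classical criteria is validated against a brute-force position-wise oracle
in the test suite. Promoters are the 10 kb upstream of the 5'-most TSS,
strand-aware; gene windows for CpG–gene pairing span the gene plus 10 kb
per side, widened symmetrically to at least 50 kb for short genes.
Coordinates are 1-based inclusive throughout the R API (the convention of
R's ecosystem); BED output is 0-based half-open.

## The synthetic-data generator

The generator defines the study conditions under which the package is
validated:

- **Parental divergence.** Ancestral allele frequencies are uniform;
  parental frequencies follow the Balding–Nichols beta model with drift
  parameter `divergence_F = 0.28`, the middle of the range typical of the
  motivating baboon taxa. Ancestry-informative markers are flagged at a
  frequency difference of at least 0.2. Hudson's ratio-of-averages
  estimator is used for the Fst check because its expectation equals the
  drift parameter (Nei's gene-diversity Fst converges to
  $(F/2)/(1-F/2)$ instead).
- **Ancestry tracts.** Each haplotype follows a two-state Markov
  (alternating-exponential) process with stationary anubis probability
  `admix_alpha = 0.37` (a realistic hybrid-zone admixture fraction) and
  mean segment length `mean_tract_bp` (default 200 kb). Generations and
  explicit recombination are not modeled — the tract process is the
  simplest mechanism matching the tract data model.
- **Reads.** Coverage is negative-binomial (mean 20, size 8), reflecting
  the overdispersion of reduced-representation bisulfite libraries; the
  real coverage distribution of such data is not precisely specified
  anywhere, so the negative-binomial is an explicit stand-in. Each read
  samples one haplotype uniformly; its methylation state is Bernoulli with
  the haplotype allele's methylation probability perturbed by a
  beta-distributed individual effect (`bb_dispersion = 0.02`), matching the
  downstream model family. Reads co-observing a SNP within the read length
  (100 bp) are allele-assignable with probability $1 - d/100$, giving
  heterozygote allele-specific counts whose information decays with
  SNP–CpG distance, as in real read data.
- **meQTL.** A configurable fraction of CpGs (default 0.3) gets a linked
  SNP within 100 bp; allelic effects are normal on the logit scale
  (`effect_sd_logit = 1.5`); a fraction of meQTL CpGs (default 0.1) is
  CpG-disrupting, forcing the alternate allele to ~1% methylation.
- **Reporter windows.** DNA counts are negative-binomial around a
  log-normal per-window abundance; RNA counts scale the DNA expectation by
  a global RNA/DNA depth ratio below 1 (most windows show fewer RNA than
  DNA reads) times an activity multiplier; methylation-dependent windows
  are more active in the unmethylated condition for 87% of cases by
  default, matching the empirical asymmetry of methylation-dependent
  enhancers.
- Each simulated individual is sampled once; repeated samples per
  individual are handled upstream by `collapse_repeat_samples()`, which
  sums counts within individuals.

What the generator does *not* emulate — kinship structure, realistic
recombination maps, selection against introgression, sequence context
beyond the per-allele methylation probabilities, batch effects — bounds
what passing tests show about real data: they validate the estimators and
their calibration under the stated model, not robustness to those
additional structures.

## Numerical choices and degenerate inputs

- Fitted means are clamped to $[10^{-9}, 1-10^{-9}]$ inside the likelihood;
  dispersion is parameterized as $\mathrm{logit}(\varphi)$.
- Rank-deficient designs, all-zero totals, and mismatched individuals are
  errors; an all-zero-coverage simulation is a warning (degenerate output),
  not a failure.
- Fisher's exact tests use the two-sided minimum-likelihood convention of
  `stats::fisher.test()`; enrichment confidence intervals are Woolf
  (Haldane-corrected) on the log2 odds ratio.
- Ties in `empirical_qvalues()` are resolved by assigning tied p-values the
  largest rank, and q-values are forced monotone by a right-to-left
  cumulative minimum.
- All randomness derives from one root seed through fixed per-stage
  offsets, so a pipeline run is byte-identical under the same seed.

## Problem sizes used in the validation suite

The test suite validates parameter recovery on a cohort of 300 individuals
with 500 meQTL CpGs at 20x coverage, null calibration on 1,000
sites/pairs/windows with 10 permutations per scan, the reporter recovery on
5,000 windows with six replicates per assay and condition, and the island
detector against its oracle on fifty 20-kb sequences. These sizes were
chosen so the full suite runs comfortably on a single CPU while leaving the
statistical checks well-powered.

## Known limitations

- No relatedness random effect (see above): in strongly structured real
  cohorts the fixed-effects approximation can inflate the ancestry-scan
  test statistic; the permutation null absorbs exchangeable structure only.
- The composite meQTL likelihood treats the individual-level and
  allele-specific components as independent given the parameters; read-level
  correlation within an individual beyond the beta-binomial is not modeled.
- The reporter analysis uses pooled-variance contrasts, not per-window
  precision weights; with heavy-tailed replicate noise the interaction test
  loses power relative to weighted linear modeling.
- Trans-acting meQTL, imputation-based genotype expansion, and mechanistic
  attribution of composition-discordant CpGs (epistasis versus
  gene–environment interaction) are out of scope; discordant sites are
  flagged, not interpreted.
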