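Package: admixmeth
Title: Genetic Architecture of DNA Methylation in Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how admixture shapes the genetic
    architecture of DNA methylation from bisulfite sequencing read
    counts. Implements beta-binomial regression for methylated/total
    read counts, per-CpG scans for local- and global-ancestry effects
    with permutation-calibrated empirical false discovery rates,
    differential methylation between unadmixed parental taxa, meQTL
    mapping that jointly models across-individual genotype effects and
    within-heterozygote allele-specific methylation, prediction of
    ancestry effects from meQTL effect sizes and parental
    allele-frequency divergence, quantification of admixture-driven
    gains in allele frequency and methylation variance, calling of
    methylation-dependent regulatory activity from reporter-assay
    (mSTARR-seq style) DNA/RNA replicate counts, and genomic-context
    annotation including CpG-island detection. A synthetic-data
    generator produces admixed cohorts with known ground truth so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
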