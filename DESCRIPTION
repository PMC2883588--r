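Package: osteogwas
Title: Integrative GWAS Prioritization for Bone Mineral Density and Hip Geometry Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage integrative genome-wide association pipeline for
    osteoporosis-related traits: kinship-aware mixed-model association on
    standardized phenotype residuals, inverse-variance fixed-effect
    meta-analysis with Cochran's Q heterogeneity, Storey q-value based
    genome-wide significance thresholds, cis-eQTL mapping with LD surrogate
    SNPs, rule-based expression-signature classification (PTH regulation,
    osteoblast maturation ANOVA, embryo-atlas ordinal scoring, EST abundance),
    likelihood-based causality model selection (causal, reactive, independent)
    by BIC with bootstrap reliability, and rule-based candidate-gene
    prioritization with hypergeometric term enrichment. A synthetic-data
    module generates pedigrees, genotypes by gene dropping, polygenic
    phenotypes, and expression experiments with known ground truth so the
    whole pipeline is exercisable without cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
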