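Package: gleam
Title: Generalized Admixture Mapping for Quantitative and Qualitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Regression-based admixture mapping for recently admixed
    populations. Tests association between local ancestry (0/1/2 allele
    copies from a high-risk ancestral population) and continuous, binary or
    count traits through generalized linear models, scoring single loci and
    locus subsets with closed-form Bayes factors under a quadratic normal
    moment (non-local) prior with empirical-Bayes dispersion. Includes a
    two-stage scan (single-locus screen, joint subset evaluation), averaging
    over multiply-imputed local ancestries, a two-ancestry hidden Markov
    model for ancestry imputation from ancestry-informative markers,
    penalized-regression comparators, and a simulation engine for null,
    single-locus and two-locus admixture-linkage-disequilibrium experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
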