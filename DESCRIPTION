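Package: hsmapr
Title: Half-Sib Recombination Maps and Recombination-Activity Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for recombination analysis in
    paternal half-sib livestock populations genotyped with medium-density SNP
    panels. Simulates half-sib families with known parental haplotypes,
    crossovers and missing genotypes; infers transmission paths, crossover
    locations and sex-specific genetic maps with three estimator families
    (a transmission hidden Markov model with EM rate updates, a deterministic
    sliding-window multipoint method, and a pairwise two-locus maximum
    likelihood method) including confidence-score based two-run filtering;
    derives parental recombination traits (autosomal crossover count and
    intra-chromosomal allelic shuffling); and fits weighted GBLUP, bivariate
    cross-sex GBLUP and mixed-model GWAS on those traits with genomic
    relationship matrices built from the same genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    emmeans,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
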