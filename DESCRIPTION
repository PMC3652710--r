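Package: snptwin
Title: SNP-Based and Twin-Design Heritability Estimation on Simulated Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of polygenic cohorts (founder genotypes,
    assortative or random mating, monozygotic and dizygotic twin pairs,
    partial tagging of causal variants by a genotyping array) together with
    the two classical estimators of heritability applied to them: SNP-based
    restricted maximum likelihood on a genetic relationship matrix (GREML,
    average-information algorithm) and twin-design ACE model fitting
    (Falconer decomposition and bivariate-normal maximum likelihood).
    Includes readers and writers for PLINK-style genotype text and
    GCTA-format binary relationship matrices, greedy relatedness filtering,
    summaries of the pairwise genomic-similarity distribution, per-trait
    ratio tables comparing the two estimators, and a spouse-pair genomic
    similarity index with a permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
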