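Package: opqg
Title: Quantitative Genetics of Open-Pollinated Conifer Progeny Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-tree quantitative-genetic analysis for
    open-pollinated progeny trials genotyped at genome-wide SNPs.
    Builds pedigree (numerator, A) and genomic (VanRaden, G)
    relationship matrices, verifies and corrects open-pollinated
    pedigrees from SNP relatedness, derives tree-ring drought indices
    (resistance and mean sensitivity from basal area increments),
    fits univariate and multivariate individual-tree mixed models by
    EM-REML with a final average-information step for standard errors,
    and reports narrow-sense heritabilities, genetic correlations and
    cross-site (genotype-by-environment) correlations. A synthetic-data
    generator with known truth (gene dropping through simulated
    pedigrees, multivariate breeding values, ring series with a drought
    year) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
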