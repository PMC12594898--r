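Package: famprs
Title: Family-Aware Evaluation of Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes polygenic risk scores (PRS) from published weight
    files with allele harmonization against a genotype panel, evaluates the
    score within families by pairing affected women with their unaffected
    female relatives (Wilcoxon signed-rank inference with
    normal-approximation critical values), runs population-level logistic
    association and rank-based ROC analysis, and flags carriers of rare
    loss-of-function variants in candidate genes.  A built-in synthetic
    cohort generator produces multi-generation pedigrees with Mendelian
    gene dropping from Hardy-Weinberg founders and a liability-threshold
    disease model calibrated to a target prevalence, so every stage of the
    pipeline can be exercised without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
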