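Package: proteoconcord
Title: Integrated Protein-mRNA Concordance Analysis for Paired Tumor/Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Proteoconcord", "Developers", email = "proteoconcord@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for integrated proteotranscriptomic
    analysis of paired tumor and adjacent-normal cohorts: spectral-count
    filtering and median-of-ratios normalization, a regularized log
    transform, negative-binomial Wald and paired signed-rank differential
    abundance testing, within-sample and across-subject protein-mRNA
    Spearman concordance with group comparisons and robustness
    stratifications, pre-ranked (weighted Kolmogorov-Smirnov) and
    two-sample KS gene-set enrichment, proliferation metagene scoring,
    Kaplan-Meier/log-rank/Cox survival association with Efron tie
    handling, consensus non-negative matrix factorization subtyping, and
    a 3'UTR-shortening fold-change contrast.  Includes a synthetic
    paired-cohort generator with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
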