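Package: cfabtx
Title: Linking the Aging Skeletal-Muscle Transcriptome to Composite Physical Function
Version: 0.1.0
Authors@R: person("CFAB", "Transcriptomics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for relating age-associated differential gene expression in
    mouse skeletal muscle to a composite physical-function score (CFAB, the sum
    of five determinant z-scores standardized to a young reference group).
    Provides a from-scratch negative-binomial Wald differential-expression
    engine with median-of-ratios normalization and trend-shrunken dispersions,
    per-gene expression-phenotype regression screening with strength and
    direction classification, hypergeometric over-representation and preranked
    GSEA enrichment with gene-set intersection, and a negative-binomial
    count-and-phenotype simulator with known ground truth emulating a
    three-age-group, two-sequencing-run design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
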