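Package: pleioscan
Title: Cross-Trait Pleiotropy Scanning with Weakest-Link Joint Tests and
    Reciprocal Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess shared genetic liability between a binary
    disease trait and quantitative behavioural traits from GWAS summary
    statistics. Implements reciprocal polygenic risk-score prediction at
    fixed P-value thresholds with incremental and Nagelkerke R-squared,
    a per-variant weakest-link joint ("overlap") test with genomic-control
    background adjustment and Benjamini-Hochberg q-values, distance-based
    locus aggregation, SNP-to-gene mapping with flanking windows,
    cross-trait gene merging, hypergeometric pathway enrichment, and a
    permutation-based pathway crosstalk network. A seeded synthetic-data
    generator produces genotypes, pleiotropic phenotypes, per-variant
    association scans and gene/pathway/PPI annotations so the full
    pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
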