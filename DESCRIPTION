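Package: aise
Title: Allelic Imbalance and Super-Enhancer Analysis for Case-Control Epigenomics
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering allelic-imbalance (AI) variants
    in case/control chromatin-accessibility and RNA data, calling
    cell-type-restricted super-enhancers from chromHMM 15-state segmentations,
    quantifying window-based chromatin accessibility (tags per million) and CpG
    methylation across B-cell developmental stages, and testing genetic
    association (single-marker log-additive logistic models, conditional
    adjustment, two-SNP EM haplotype analysis, and linkage-disequilibrium r2).
    Includes a synthetic-data generator that emulates the statistical structure
    of the real assays (beta-binomial allelic counts, planted enhancer runs,
    stage-dependent signal trends, Hardy-Weinberg genotypes with log-additive
    disease risk) so that every stage of the pipeline is testable without any
    data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    methods
Config/testthat/edition: 3
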