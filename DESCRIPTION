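Package: increg
Title: Incremental Regulator Selection and Linear Modelling of Gene
    Expression Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the regulation of target-gene expression from
    heterogeneous candidate regulators: promoter methylation, genes of the
    same functional gene set, promoter-binding transcription factors, and
    genes (and transcription factors) of other gene sets.  Candidate
    features are organised per target gene into five nested matrices and
    screened by incremental forward feature selection with re-evaluation
    under a shared fivefold sample partition; the fold-wise consensus is
    fitted by ordinary least squares on z-scored data, with 95% confidence
    intervals deciding feature significance.  Includes alternative
    selection strategies (forward selection on all features, lasso with
    and without the incremental scheme), BIC-based strategy comparison,
    signed regulatory-network construction and export, cross-cohort model
    transfer, and a synthetic multi-omic cohort generator with planted
    regulatory truth for parameter-recovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    glmnet,
    jsonlite,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
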