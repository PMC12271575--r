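Package: metageno
Title: Chromosome-Wise Multi-Task Genomic Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a chromosome-wise multi-task framework for polygenic
    risk prediction. Genotypes read from VCF files against PGS-Catalog-style
    scoring panels are encoded as allele-state one-hot vectors, embedded with a
    shared embedding matrix plus per-SNP identity terms, contextualised by
    per-chromosome self-attention, and pooled into a 22-row chromosome-aware
    representation that feeds a sequence backbone (transformer, LSTM, GRU, CNN
    or TCN) with six disease heads (ischaemic stroke and five modifiable risk
    factors). Includes a liability-threshold genotype/phenotype simulator with
    block LD, shared cross-disease latent factors and planted epistasis; a
    balanced cross-validation training protocol; a classic weighted-sum
    polygenic score baseline; and the downstream evaluation layer: percentile
    risk stratification with Cox hazard ratios, Harrell's C-index over task
    combinations, Kaplan-Meier cumulative incidence on an age timeline, and
    per-chromosome attention reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    survival,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
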