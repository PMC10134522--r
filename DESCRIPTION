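Package: gostrat
Title: Stratifying Gene Lists by Gene Ontology Functional Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies gene lists into functionally coherent clusters using
    Gene Ontology (GO) semantic similarity. Parses OBO ontologies and GAF or
    two-column annotation files, propagates annotations by the true-path rule,
    and computes term information content. Five term-level similarity measures
    (Resnik, Lin, Rel, Jiang and Wang) and four set-level aggregation functions
    (max, avg, rcmax, BMA) build a gene-by-gene functional similarity matrix,
    which is embedded (PCA, PCoA, t-SNE, UMAP), clustered (k-means, PAM, Ward
    hierarchical, fuzzy c-means) and validated with silhouette statistics,
    including silhouette-guided selection of the number of clusters and an
    outlier-refinement pass. A synthetic-data generator produces toy ontologies
    with group-structured annotations and planted-partition geometry for
    end-to-end validation, and a command-line interface orchestrates the full
    similarity - embedding - clustering pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    Rtsne,
    testthat (>= 3.0.0),
    uwot,
    withr
Config/testthat/edition: 3
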