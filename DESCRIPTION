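Package: mirXtalk
Title: miRNA-Mediated Pathway Crosstalk Networks for Tumor Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates matched miRNA and mRNA expression across tumor
    grades to build miRNA-pathway and pathway-pathway crosstalk networks.
    Provides grade-contrast differential calling with
    Benjamini-Hochberg FDR control, inverse-correlation selection of
    signature miRNA-target pairs, cumulative hypergeometric pathway
    enrichment, a Fisher's-method pathway crosstalk statistic summed
    over protein-protein interaction edges with a gene-set-resampling
    permutation null, maximal-biclique and k-clique-percolation module
    detection, and module-based Kaplan-Meier survival stratification.
    Includes a synthetic-data generator with planted ground truth for
    end-to-end validation, readers and writers for the standard file
    formats involved, and a staged pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
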