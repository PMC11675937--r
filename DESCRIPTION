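Package: trnadapt
Title: Codon Optimality and tRNA Adaptation Analysis for tRNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links measured tRNA abundance to mRNA stability and translation
    efficiency across two cell states. Builds a collapsed isodecoder reference
    from gtRNAdb-style tRNA gene FASTA files, normalizes tRNA-seq count tables
    by the trimmed mean of M-values (TMM), aggregates isodecoders into
    isoacceptor (anticodon) pools, and computes codon-level and gene-level
    metrics: codon stabilization coefficients (CSC), tRNA adaptation index
    (tAI) with dos Reis wobble penalties, codon adaptation index (CAI),
    expression-weighted codon demand and supply/demand ratios (SDR), and
    cross-condition comparisons. Includes PCA and k-means clustering of
    amino-acid-normalized codon usage, a negative-binomial/Dirichlet synthetic
    data generator with planted ground truth for validation, and a
    configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
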