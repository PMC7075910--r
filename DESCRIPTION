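Package: chondronet
Title: Integrative miRNA-mRNA Co-Expression Network Analysis for Staged
    Differentiation Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the joint analysis of small-RNA and whole-transcriptome
    count data from staged differentiation experiments. Implements low-count
    filtering, upper-quartile and trimmed-mean-of-M-values (TMM) normalization,
    negative-binomial GLM likelihood-ratio differential expression with a
    Cox-Reid common dispersion, Pearson co-expression graphs clustered with the
    Markov Cluster algorithm, per-regulator (transcription factor and miRNA)
    Fisher exact target enrichment against co-expression clusters, gene-set
    enrichment, and STRING-style protein-protein interaction subnetwork
    analysis. A negative-binomial simulator with planted cluster and regulator
    structure makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
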