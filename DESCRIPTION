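Package: sHSPpipe
Title: Promoter, Expression and Composition Analysis of Bacterial Small
    Heat-Shock Protein Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated analysis pipeline for bacterial small
    heat-shock protein (sHSP) genes. Builds bipartite sigma-32 promoter
    models from aligned -35/-10 training sites as positional weight
    matrices with a variable spacer, scans upstream regions and reports
    per-site information content in bits; quantifies heat-shock
    induction from qRT-PCR threshold cycles by the comparative
    delta-delta-Ct method with endogenous-control normalisation and
    t-test significance calling; screens coding sequences for anomalous
    GC composition against the genome average with a Pearson chi-square
    test to flag candidate horizontal acquisitions; computes protein
    molecular weight, theoretical isoelectric point and pairwise
    identity/similarity; verifies qPCR primers by in-silico PCR; and
    ships a synthetic-data generator with known ground truth so every
    stage can be exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, MotifDiscovery, GeneExpression, qPCR,
    Transcription
RoxygenNote: 7.3.3
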