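Package: medEcotyper
Title: Entropy-Based Oligotyping and Environment-Specific Ecotype Detection
    for 16S rRNA Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for resolving closely related 16S rRNA amplicon sequence
    variants (oligotypes) by minimum entropy decomposition and for detecting
    environment-specific ecotypes among them. Implements taxon-targeted
    sequence retention filters on BLAST tabular alignments, recursive
    entropy-based partitioning of padded amplicon alignments with minimum
    substantive abundance pruning and outlier relocation, per-sample
    contamination and sequencing-depth quality control, a prevalence plus
    outgroup-quantile ecotype statistic, and sample-based rarefaction of
    oligotype richness. Includes a synthetic multi-environment amplicon
    community simulator with planted ecotypes so the full workflow can be
    exercised and validated without external sequence archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
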