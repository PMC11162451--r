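Package: voxelprot
Title: Downstream Analysis of Voxelated Spatial FFPE Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream computational analyses for voxelated spatial
    proteomics of formalin-fixed paraffin-embedded (FFPE) tissue: in-silico
    tryptic digestion and peptide-level quality control (semi-tryptic and
    miscleavage rates, lysine/arginine cleavage preference), open-search
    modification-landscape summaries with a bundled monoisotopic mass-shift
    catalog, spectral-count rank-abundance concordance, intensity-matrix
    normalization and spatial-variability filtering, soft-threshold
    co-regulation adjacency networks with topological overlap and
    seed-protein neighborhoods, term-summed spatial intensity maps rendered
    as SVG choropleths over a voxel layout, and a synthetic-data generator
    with exported ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    limma,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
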