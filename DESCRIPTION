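Package: phlatlas
Title: Backbone Curation, Classification and Template Ranking for
    Peptide-HLA Class I Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for structural analysis of peptide-HLA class I (pHLA)
    complexes. Curates and standardizes pHLA coordinate files (chain
    classification against reference sequences, resolution and occupancy
    filters, trimming of the heavy chain to the 180-residue peptide-binding
    platform, renumbering, HLA allotype typing), classifies peptides by
    anchor class from groove-frame Calpha distances, builds peptide
    backbones from internal coordinates (NeRF), and compares backbones with
    the D-score, a cyclic dihedral-angle dissimilarity over the central
    peptide positions. A greedy dominating-set procedure reduces a set of
    backbones to discrete representative conformations; sequence-bias
    analysis couples exhaustive sequence-space enumeration with
    energy-based top-fraction selection, position probability matrices and
    per-position Kullback-Leibler divergence; and a quantile-transformed
    RBF support-vector regression ranks candidate template models by
    predicted D-score with leave-one-out benchmarking and an abstention
    rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
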