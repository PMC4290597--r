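Package: rnaikit
Title: Identification and Comparative Analysis of RNA Interference Machinery Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for kingdom-wide identification and comparative
    analysis of the core RNA interference (RNAi) machinery: Argonaute,
    Dicer, and RNA-dependent RNA polymerase (RdRP) genes. Proteins are
    classified from InterPro domain annotations using configurable
    domain-architecture profiles (PAZ + Piwi for Argonaute; two RNase III
    hits plus a dsRNA-binding domain for Dicer; the eukaryotic RdRP
    domain), with recall evaluation against labeled test sets. Downstream
    stages provide per-taxon census statistics, accessory-domain analysis
    of Dicers, alignment-anchored extraction and classification of the
    Argonaute DDH catalytic triad, column conservation scoring, sequence
    logo frequency matrices, alignment-free composition-vector proteome
    distances, neighbor-joining tree construction, midpoint rooting, and
    LCA gene-tree/species-tree reconciliation with duplication and loss
    counts. Seeded generators produce synthetic proteomes with planted
    domain architectures and birth-death gene-family histories for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
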