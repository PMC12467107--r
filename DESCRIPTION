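Package: urchinNRPM
Title: Housekeeping-Gene Normalization and Expression Dynamics of
    Neurotransmitter Genes in Early Sea Urchin Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cross-species comparative analysis of neurotransmitter-system
    gene expression in early sea urchin embryos. Normalizes per-stage
    transcript abundances (RPM, FPKM or TPM) to the geometric mean of three
    housekeeping genes (GAPDH, ODC, HPRT), giving the NRPM unit that is
    comparable across datasets; calls transcripts expressed or negligible
    against an abundance threshold; harmonizes native developmental stages
    onto a unified early-cleavage-to-early-gastrula axis; classifies per-gene
    expression trajectories around the maternal-to-zygotic transition
    (maternal decline, late onset, U-shape); summarizes cross-species
    conservation per neurotransmitter system; scores single-cell cluster
    enrichment of a gene's expressing cells with a hypergeometric test; and
    generates synthetic bulk and single-cell datasets with known ground
    truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
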