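Package: pinediv
Title: Comparative Transcriptomics of Conifer Divergence from Ka/Ks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An inference chain for comparative transcriptomics in conifers:
    redundancy collapsing and cross-species orthologue pairing of transcript
    sets by global identity, reading-frame inference and protein-guided codon
    alignment, Ka/Ks estimation by Nei-Gojobori pathway counting with
    Jukes-Cantor correction, per-species-pair Ks-peak estimation,
    neighbour-joining phylogeny on Ks-peak distances with outgroup rooting,
    molecular-clock divergence dating from branch-average Ks, a Ka/Ks > 1
    positive-selection screen with annotation joining, and SSR/SNP marker
    scanning. Includes a codon-evolution simulator with known synonymous
    divergence and omega so every stage is testable against ground truth, and
    a published 13-species Ks-peak matrix as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
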