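Package: bpmpra
Title: Branch Point Utilization Analysis for Barcoded 3' Splice Site
    Minigene Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse massively parallel 3' splice
    site minigene reporter assays used to study branch point (BP) choice
    by wild-type and K700E-mutant SF3B1 spliceosomes. Includes a seeded
    generator of barcoded minigene libraries with degenerate regions
    flanking a weak splice acceptor, a generative model of acceptor
    competition in which the mutant condition tolerates mismatches at the
    -1 position of the U2 snRNA-branch point duplex, paired-end read
    emission and barcode/junction demultiplexing, per-6-mer odds-ratio
    enhancer statistics with condition contrasts, a hierarchical branch
    point motif classifier, a nearest-neighbor model of U2-BP duplex free
    energy, and a reproducible end-to-end pipeline with a rendered
    summary report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
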