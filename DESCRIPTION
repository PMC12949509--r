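Package: rdm2dpo
Title: Double-Pushout Reaction Rules and Atom-to-Atom Maps from KEGG RCLASS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts KEGG RCLASS/RDM reaction-class descriptions together with
    reactant and product molecule structures (MDL MOL or KEGG KCF) into explicit
    double-pushout (DPO) graph transformation rules and complete atom-to-atom
    maps. RDM codes are expanded into pattern graphs via a bundled dictionary of
    the 68 KEGG atom types (including all documented alternative
    interpretations), embedded into the molecules by labelled subgraph matching,
    and merged into reaction rules whose application regenerates the products.
    All solutions consistent with the input data are enumerated exhaustively.
    Includes a self-contained chemical DPO rewriting engine, imaginary
    transition state (ITS) graph machinery, and a synthetic fixture generator
    for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
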