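Package: septinevo
Title: Evolution of Opisthokont Septin Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying the evolution of septin paralog families
    across animals, fungi and their protist relatives. Implements
    motif-based septin identification from domain annotations and G-box
    scans, paralog-Group assignment by anchor taxa, duplication-loss
    reconciliation of gene trees with a species tree (including
    support-based polytomy rearrangement and per-branch copy-number
    profiles), maximum-likelihood Mk ancestral-state reconstruction of
    Group presence/absence with proportional likelihoods and a Wilks
    likelihood-ratio test, Jensen-Shannon conservation scoring of
    alignment columns mapped onto a reference septin coordinate system,
    and probe-style detection of inter-chain residue contacts in dimer
    structures with cross-taxon consensus calling of G- and NC-interface
    positions. Seeded synthetic-data generators for every input type make
    the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
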