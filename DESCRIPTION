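Package: boxbind
Title: Quantitative Analysis of Clathrin-Box Adaptor Binding
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis chain for studying short-linear-motif mediated binding
    of yeast clathrin adaptors to the clathrin heavy-chain N-terminal domain:
    disorder-aware clathrin-binding-motif scanning over protein sequences,
    apparent dissociation-constant estimation from nanoDSF thermal-shift
    titrations with a two-state ligand-coupled stability model, native mass
    spectrometry occupancy statistics with an independent-identical-sites
    null model and two-ligand one-site competition solving, acceptor
    photobleaching FRET efficiency statistics with Yuen trimmed-mean tests
    and Holm correction, and Kabsch C-alpha superposition of crystal
    structures. Seeded synthetic-data generators emulate every input so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Biostrings,
    bio3d,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
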