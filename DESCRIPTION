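Package: agamtools
Title: Codon Usage Scoring, Codon Optimization, and Cloning Simulation for
    Anopheles gambiae Transgenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools supporting the design of transgenes for the malaria mosquito
    Anopheles gambiae. Builds codon usage tables from sets of coding sequences,
    scores heterologous coding sequences with a translation penalty index (rare
    codons per 1000 codons), and rewrites coding sequences toward a target codon
    usage while preserving the encoded protein and avoiding forbidden motifs such
    as BsaI sites. Also simulates the sequence-level cloning logic used in
    docking-site transgenesis: type IIS (BsaI) GoldenGate restriction-ligation
    assembly, phiC31 attB x attP integration, Cre/loxP cassette excision and
    inversion, and exact-match diagnostic PCR. Deterministic synthetic-fixture
    generators allow the whole toolkit to be exercised and tested without any
    sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
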