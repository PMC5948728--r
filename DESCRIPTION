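Package: starcutter
Title: Simulation and Decoding of Relaxed ('Star') Restriction Recognition Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico characterization of a thermophilic Type IIS/IIG
    restriction endonuclease with a degenerate recognition sequence
    (5'-CAARCA-3') and strand-asymmetric downstream cleavage (11/9 nt,
    2-nt 3' cohesive ends) whose specificity relaxes to an effective
    ~3-bp 'site' under cofactor/DMSO conditions. Provides degenerate
    IUPAC site scanning, complete and partial digest enumeration with
    duplex-core length accounting, seeded stochastic partial digestion,
    a shotgun-library simulator (star cleavage, end blunting, blunt
    cloning, junction reads with a ground-truth manifest), a
    vector-insert junction decoder that reconstructs the responsible
    recognition hexamer, and the frequency statistics (mean recognition
    spacing, theoretical site length, mismatch spectra, position
    frequency matrices with information content, insert-length
    histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
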