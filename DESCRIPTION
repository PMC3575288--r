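Package: talenforge
Title: TALEN Pair Design with Restriction-Site Screening for RFLP Readout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs transcription activator-like effector nuclease (TALEN)
    reagents from DNA sequence. Enumerates pairs of TAL effector binding
    sites matching a user-defined consensus template (a required 5' thymine,
    optional leading base constraints, free interior) over configurable
    binding-site and spacer length ranges, encodes each arm as its repeat
    variable di-residue (RVD) module string, and screens the spacer for
    restriction-enzyme recognition sites that are unique within the PCR
    amplicon so TALEN activity can be read out by restriction fragment
    length polymorphism (RFLP). Reads FASTA and GenBank flat-file input
    with exon/intron extraction and flanking sequence, parses Bairoch-style
    REBASE enzyme databases with vendor filtering and PCR-buffer
    compatibility scores, renders flat-text and CSV reports, and generates
    Golden Gate assembly pick lists with pipetting volumes from a local
    reagent-concentration table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
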