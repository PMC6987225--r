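Package: tfantenna
Title: Statistical Thermodynamics and Kinetics of Transcription Antennas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the operation of "transcription antennas": regulatory
    DNA regions dense in degenerate consensus sites that concentrate a
    transcription factor around its target gene. Implements a partition
    function model of homeodomain binding to every 6-bp window of a DNA
    duplex (specific, degenerate A/T and electrostatic nonspecific
    interaction modes, plus a position weight matrix variant), global
    fitting of the energetic parameters to dissociation constant
    titrations, a four-state kinetic model of antenna operation solved
    spectrally, motif over- and under-representation statistics over gene
    regions, fitting of fluorescence correlation spectroscopy titrations,
    and seeded synthetic-data generators that emulate the designed DNA
    constructs and gene architectures so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
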