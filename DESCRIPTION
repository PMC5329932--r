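Package: coldacc
Title: Cold-Acclimation Transcriptome Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational stages of a temperature-gradient
    transcriptome study: FPKM quantification with a sequencing-depth saturation
    diagnostic, simplified negative-binomial differential expression between
    temperature groups with cross-comparison consistency filtering,
    significance testing of GO functional groups among differentially
    expressed genes by random resampling of the expressed-gene background,
    SNP-to-IUPAC genotype matrices with neighbour-joining structure checks,
    SSR (microsatellite) detection and marker filtering, and relative qPCR
    quantification by the 2^-ddCq method. A synthetic-data generator with a
    planted truth set supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
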