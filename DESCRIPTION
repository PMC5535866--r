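Package: phageprof
Title: Protease Substrate Specificity Profiling from Phage Substrate Display
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to profile the extended substrate specificity (subsites
    P5 through P4') of proteases from phage substrate display selections and
    to predict cleavage sites in protein sequences. Models degenerate-codon
    (NNK) library composition, computes per-position binomial enrichment
    z-scores from selected peptide pools, normalizes them into position
    specific scoring matrices, scans protein sequences for candidate
    scissile bonds, restricts hits to extracellular domains of membrane
    proteins, and summarizes phage-ELISA cleavage validation. Includes a
    seeded simulator of libraries, multi-round selections, planted-site
    proteomes and ELISA readouts for end-to-end testing and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
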