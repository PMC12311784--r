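Package: histoform
Title: Top-Down Histone Proteoform Annotation and Positional-Isomer
    Quantitation
Version: 0.1.0
Authors@R:
    person("Histoform", "Developers", email = "histoform@example.org",
           role = c("aut", "cre"))
Description: Tools for annotating histone proteoforms of organisms without
    annotated genomes from deconvolved mass spectra. Explains intact-mass
    shifts as combinations of post-translational modifications or single
    amino acid variants, generates localized proteoform candidates, matches
    theoretical c/z (ECD) and b/y (CID) fragment ladders to observed peaks
    and scores candidates by sequence coverage, terminal sequence
    validation, intensity coverage and their product (MS score), quantifies
    co-isolated positional isomers from isomer-specific reporter ions,
    extracts de novo sequence tags from fragment ladders and identifies
    proteins by an ungapped high-scoring-pair homology search, and builds
    propionylation/trypsin bottom-up target lists with peptide-level
    confirmation. Includes seeded simulators for deconvolved MS1 envelopes
    and fragment spectra so the whole workflow is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
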