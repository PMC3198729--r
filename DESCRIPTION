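Package: asiRNA
Title: Design and Evaluation of Allele-Specific RNAi Effectors Targeting
    Single-Nucleotide Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for engineering RNA-interference effectors that
    discriminate between two alleles differing at a single nucleotide.
    Generates walk-through panels of guide strands with the variant aligned
    at each successive guide position, classifies guide:target mismatches
    (Watson-Crick, G:U wobble, purine:purine, pyrimidine:pyrimidine),
    enumerates secondary-mismatch variants under several placement
    strategies, assembles siRNA duplexes, U6 Pol-III short-hairpin PCR
    primers and dual-luciferase reporter inserts, simulates and maps 5'RACE
    cleavage products to guide-relative coordinates, and computes
    normalized silencing and allele-discrimination statistics from
    dual-luciferase or dual-fluorescence plate measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
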