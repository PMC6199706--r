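Package: dgrscan
Title: Detection and Analysis of Diversity-Generating Retroelements in Phage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects diversity-generating retroelement (DGR) cassettes in
    phage and prophage genomes by seed-and-extend discovery of template
    repeat / variable repeat (TR/VR) pairs near reverse-transcriptase loci,
    with adenine-specific mismatch criteria (minimum adenines in the TR,
    minimum adenine substitutions in the VR). Classifies prophage activity
    from virome read coverage (mean fold coverage with an identity filter),
    applies a lifestyle-confidence rule and a chi-square temperate-enrichment
    test, analyses cross-variant diversification (TR invariance,
    adenine-specific substitutions, variable-position census, exact sequence
    space), and estimates fractional abundance from read recruitment. A
    mutagenic-retrohoming simulator plants ground-truth cassettes and
    generates virome-like reads for end-to-end testing. Includes readers for
    FASTA, GenBank flatfiles, HMMER domain tables and SAM text, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
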