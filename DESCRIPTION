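Package: pentaplex
Title: Mixed-Motif Tandem Repeat Expansion Screening and Long-Read
    Repeat Decomposition
Version: 0.1.0
Authors@R:
    person("pentaplex", "developers", email = "pentaplex@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and characterizing complex short tandem
    repeat (STR) expansions built from multiple repeat motifs, such as the
    pentanucleotide expansions underlying familial adult myoclonic epilepsy
    (FAME). Screens short-read sequencing data for read pairs in which both
    mates are (nearly) pure repeat and jointly carry substantial tracts of
    two or more target motifs (the mixSTR evidence signature of adjacent
    expansions); decomposes targeted long reads over a repeat locus into
    ordered motif blocks, with wild-type allele filtering, strand-biased
    basecall-artifact detection, consensus repeat structures and waterfall
    summaries; and simulates diploid repeat alleles with Illumina-like read
    pairs and nanopore-like noisy long reads so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
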