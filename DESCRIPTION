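Package: scsavail
Title: Availability Scores and Rank-Frequency Statistics for Short
    Constituent Sequences in Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats protein amino-acid sequences as strings of fixed-length
    "words" (short constituent sequences, SCSs) and provides the statistics
    needed to study their usage: sparse k-mer dictionaries with corpus
    composition, expected counts under a without-replacement random-arrangement
    null, availability scores (observed over expected counts) and per-sequence
    availability profiles, Zipf/power-law rank-frequency diagnostics with
    linear-range determination and a power-law-versus-exponential discriminant,
    and motif-centric enrichment, peak-correspondence and amino-acid
    composition rank-order statistics. Includes seed-deterministic generators
    for synthetic protein databases, Zipfian word corpora and planted-motif
    fixtures, plus a command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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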