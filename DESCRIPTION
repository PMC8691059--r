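Package: svcmr
Title: Structural-Variation-Causing Mutation Rates from Mutation Accumulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and validation of structural-variation-causing
    mutation rates (svcMRs) from mutation accumulation (MA) line data.
    Classifies candidate structural variants into six categories (short
    insertions and deletions, long deletions and tandem duplications, and
    deletions and duplications at copy-number-variable sites), estimates
    per-line, per-genotype, per-population and species-wide rates with
    bootstrap confidence intervals, computes length-adjusted, net-length
    and per-gene rates, tests gene overlap against a positional resampling
    null, and validates detection pipelines by spiking known events into
    reference sequences and scoring call sets for false discovery and
    false negative rates. A synthetic-data generator emulating a
    multi-genotype Daphnia MA design provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
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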