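Package: homseg
Title: Homology Segment Analysis of Ectopic Pairing in Polytene Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies sequence homology between cytological sections of a
    chromosome as the frequency of exactly matching short DNA fragments (FMF)
    on both strands, and screens it against observed frequencies of ectopic
    contacts (FEC) with Spearman rank correlations. Implements fragment
    enumeration with a microsatellite filter, canonical two-strand match
    counting, per-10-kb FMF normalization, specific and unspecific
    correlation sets with R/P summaries, sliding distance-zone analysis,
    Mann-Whitney and two-proportion chi-square comparison layers, fragment
    ranking by occurrence number with FASTA export, and a synthetic-genome
    generator with planted satellite monomers and contact matrices coupled
    to repeat sharing for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
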