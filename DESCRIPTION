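Package: poolmap
Title: Mapping-by-Sequencing with Pooled Allele Frequencies and
    Read-Depth Deletion Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bulked-segregant mapping-by-sequencing for species with
    fragmented, genetically anchored assemblies. Computes pooled allele
    frequencies from exome-capture sequencing of phenotypic F2 bulks,
    averages them in centimorgan bins along a genetic framework to locate
    the causal locus, screens capture targets for putative deletions by
    contrasting per-base read depth between pools, and ranks candidate
    genes by genetic proximity to the allele-frequency peak. Includes
    closed-form pool genetics (map functions, expected bulk allele
    frequencies, segregation tests) and a seeded F2 bulk simulator that
    generates every input format the pipeline consumes, so the whole
    analysis is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
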