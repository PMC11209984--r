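Package: sdrscan
Title: Sex-Determining Region Discovery from Pooled and RAD Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating sex-determining regions (SDRs) in species
    with XX/XY heterogamety from population sequencing summaries. Implements
    a pooled-sequencing scan for sex-specific single-nucleotide variants
    (sites heterozygous in one sex pool and homozygous in the other) with
    sliding-window density and coverage tracks, interval calling for
    SNV-dense regions and Y-limited (hemizygous) insertions, RAD-seq
    presence/absence tile matrices with Bonferroni-corrected chi-square
    screening of sex-linked markers, and Yates-corrected chi-square
    sex-linkage statistics for genotyping assays. A seeded simulator of
    XY populations generates pooled allele counts, RAD depth matrices and
    genotype-call tables with the statistical structure these analyses
    assume, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
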