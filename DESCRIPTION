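Package: spliceshift
Title: Detection of Genotype-Dependent Shifts in pre-mRNA Splicing from RNA-seq
Version: 0.9.0
Authors@R:
    person("Splice", "Shift Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for detecting genotype-dependent changes in
    pre-mRNA splicing from bulk RNA-seq with biological replicates. Builds
    per-sample count structures from spliced alignments (per-gene unique read
    counts, average exon and intron depths, splice-junction and exon-intron
    boundary read counts), performs TMM normalization, logCPM transformation
    and length-adjusted (RPKM-scale) t-test based differential expression, and
    calls intron retention (IR), more-efficient splicing (MES), exon skipping
    (ES) and alternative 5'/3' splice-site events using chi-square homogeneity
    and Fisher exact tests under an all-replicates significance rule. Includes
    a quantifier for a three-variant reporter locus carrying a GT-AG intron
    nested inside a noncanonical AT-AC intron, and a seeded synthetic-data
    generator (gene models, negative-binomial expression, per-intron splicing
    efficiencies, injected events with known truth) so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    jsonlite
Config/testthat/edition: 3
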