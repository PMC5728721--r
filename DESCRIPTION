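Package: nucmeth
Title: Nucleosome Positioning and DNA Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the relationship between nucleosome
    positioning and cytosine DNA methylation in plant and mammalian
    genomes. Calls nucleosome peaks from MNase-seq fragment midpoint
    density, classifies positioning reliability by reciprocal overlap
    between biological replicates, anchors context-resolved (CG/CHG/CHH)
    methylation metaprofiles on nucleosome dyads, calls differentially
    methylated regions with a windowed one-sided exact test and a
    mutant-exclusivity filter, quantifies the ~10 bp rotational
    methylation periodicity with an FFT periodogram, and isolates phased
    nucleosome arrays by self-organizing-map clustering of dyad-centred
    methylation matrices. A seeded synthetic-data generator emulating
    wild-type and remodeler/linker-histone mutant methylomes makes the
    whole pipeline testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
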