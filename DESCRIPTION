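Package: lsvcompare
Title: Unified Splice-Graph Comparison of Short- and Long-Read Transcriptome Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds per-gene splice graphs that unify three sources of
    transcriptome evidence: a reference annotation (GTF), short-read splice
    junction counts (STAR SJ.out.tab plus a retained-intron table), and
    long-read transcript models (GTF with per-transcript read counts).
    Every junction and retained intron is classified by the subset of
    sources supporting it; de novo elements are further classified as
    novel splice sites, novel combinations, alternative 5'/3' splice
    sites, retained introns or new exons. Local splicing variations (LSVs)
    are quantified with a conjugate beta-binomial posterior over percent
    spliced in (PSI), including quantifiability filters, minimum-PSI
    rules and spliced distance to the transcript 3' end. Fuzzy splice-site
    matching, figure-level summary statistics, a ground-truthed synthetic
    data generator and a command-line driver complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
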