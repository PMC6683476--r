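Package: meripr
Title: MeRIP-Seq Peak Calling, Transcript Topology, and Differential
    m6A Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for m6A RNA methylomes profiled by
    MeRIP-seq (m6A-seq). Detects immunoprecipitation-enriched peaks
    against matched input libraries with transcriptome-wide false
    discovery control, forms replicate-consensus peak sets, maps peak
    summits onto a five-segment transcript anatomy (TSS, 5'UTR, CDS,
    stop-codon window, 3'UTR) with metagene profiles and
    segment-normalized enrichment, ranks hexamer motifs against an
    exonic background, calls differential methylation integrated with
    FPKM-based differential expression, and implements the bench-assay
    calculators used to validate methylome calls: 2^(-dCT)
    m6A-IP-qPCR enrichment, LC-MS/MS standard-curve m6A/A
    quantification, and Sanger bisulfite per-cytosine 5mC levels. A
    synthetic-data generator with known ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
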