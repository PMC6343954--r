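Package: lncislands
Title: Discovery of Novel Long Noncoding RNAs from Stranded RNA-Seq Coverage Islands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reference-guided discovery, reconstruction, filtering and
    classification of novel long noncoding RNA (lncRNA) gene models from
    stranded RNA-seq evidence. Coverage outside annotated gene models
    (extended by a configurable flank) is segmented into islands of
    expression, islands are clustered through filtered de-novo splice
    junctions, consensus introns are derived from junction segment
    frequencies, and boundaries are refined with a smoothed z-score
    breakpoint detector. Candidates are filtered by length, coding
    potential (ORF, Fickett TESTCODE and hexamer bias in a logistic
    model), replicate consistency and FPKM, then classified by genomic
    context (antisense, intergenic, intronic). Downstream metrics include
    the tau specificity index, Fisher-exact enrichment, TSS proximity,
    neighbour expression correlation and antisense fold-change
    concordance. A synthetic-data module generates genomes, annotations,
    stranded coverage, junction files and count matrices with planted
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
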