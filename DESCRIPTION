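Package: mproteo
Title: Desk-Scale Comparative Metaproteomics: Database Construction,
    Two-Round Search, and Consensus Annotation
Version: 0.9.0
Authors@R:
    person("OSD", "Workflows", email = "osd.workflows@example.org",
           role = c("aut", "cre"))
Description: Simulates a multi-genus microbial community (reference
    proteomes, metagenomic reads, observed tryptic peptidomes), builds four
    protein search databases from the same synthetic metagenome
    (non-assembled reads, assembled contigs, taxonomy-derived reference
    proteomes, and their merge), identifies proteins by a two-round
    target-decoy search at 1% protein-level FDR, annotates protein groups
    with lowest-common-ancestor taxonomy and consensus function names, and
    quantifies how database and fractionation choices alter taxonomic and
    functional conclusions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    stringi,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
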