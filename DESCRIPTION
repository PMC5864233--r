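Package: opsinscan
Title: Screening, Motif Annotation and Abundance Profiling of Microbial
    Rhodopsins in Metagenomic Gene Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies opsin-architecture proteins in protein sequence
    collections by Kyte-Doolittle hydropathy (seven transmembrane segments
    plus the retinal-binding lysine in the seventh), transfers the
    proteorhodopsin spectral-tuning and ion-pumping residue positions
    (97, 101, 105, 108) onto each sequence by global alignment to a
    reference frame, classifies pump type (DTE/DTD proton, NDQ sodium,
    NTQ chloride) and spectral tuning (Q blue; L/M/I green), dereplicates
    sequences by greedy identity clustering, and computes copies-per-genome
    via universal single-copy gene normalization, depth-stratified relative
    abundances, retinal-biosynthesis gene-set profiles and metatranscriptome
    transcript fractions. Includes a synthetic-data generator that plants
    known motifs, topologies, copy numbers and transcript fractions so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
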