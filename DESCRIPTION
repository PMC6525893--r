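Package: pvdreb
Title: Categorization, Genomic Mapping, Diversity and Stress-Response
    Expression of DREB Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for the genome-wide categorization of
    dehydration-responsive element-binding (DREB) transcription-factor
    genes and their downstream characterization. Classifies
    AP2/ERF-family proteins from domain annotations (single-AP2
    filtering and the valine-14/glutamate-19 residue rule), builds
    neighbor-joining phylogenies with bootstrap supports and assigns
    DREB subgroups (A-1 to A-6) from labeled references, scans peptides
    for conserved subgroup signature motifs, detects tandem gene
    duplicates and the nearest SNP marker to each transcription start
    site, calls SNP/INDEL variants from aligned sequencing panels with
    polymorphic information content, haplotype and nonsynonymous
    consequence summaries plus principal coordinate analysis, and
    estimates qPCR amplification efficiency, quantification cycles and
    efficiency-corrected relative expression with a fixed-reallocation
    randomization test. Seeded synthetic-data generators emulate every
    input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    methods,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
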